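# Shared fixtures, all generated in code.

random_matrix <- function(n_probes, n_samples, seed = 1,
                          mean = 8, sd = 1, prefix = "s") {
  set.seed(seed)
  expression_matrix(
    matrix(rnorm(n_probes * n_samples, mean, sd), n_probes, n_samples),
    probe_ids = sprintf("p%03d", seq_len(n_probes)),
    sample_ids = sprintf("%s%03d", prefix, seq_len(n_samples)))
}

# ReferenceStats with exact (population) parameters, bypassing estimation
exact_reference <- function(means, variances, n_controls = 1000L) {
  structure(list(probe_ids = names(means), means = means,
                 variances = variances,
                 variance_floor = min(variances), n_controls = n_controls),
            class = "ReferenceStats")
}

# constant-amplitude parameter helper
const_amplitude <- function(a, timepoints = c(0.5, 1, 4, 7)) {
  grid <- stats::setNames(rep(a, length(timepoints)),
                          as.character(timepoints))
  list(young = grid, aged = grid)
}

geo_fixture_lines <- function(drop_end = FALSE) {
  lines <- c(
    "!Series_title\t\"synthetic two-sample series\"",
    "!Sample_title\t\"patient one\"\t\"patient two\"",
    "!series_matrix_table_begin",
    "\"ID_REF\"\t\"GSM0001\"\t\"GSM0002\"",
    "\"probe_a\"\t7.25\t8.5",
    "\"probe_b\"\t6.0\t6.125",
    "!series_matrix_table_end")
  if (drop_end) lines <- lines[lines != "!series_matrix_table_end"]
  lines
}
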