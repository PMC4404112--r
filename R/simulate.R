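#' Simulation parameters for a synthetic trauma cohort
#'
#' The defaults encode the study conditions the analysis pipeline assumes:
#' a healthy-control baseline; a trauma response perturbing 75% of probes
#' (the "genomic storm"); an early response amplitude larger in the young
#' than the aged at days 0.5 and 1, crossing over by day 4 (aged > young)
#' as the young recover toward baseline; monotone longitudinal dropout
#' (discharge or death); and additive residual noise at one control SD.
#' Amplitudes are mean absolute probe shifts in control-SD units, fixed in
#' sign per probe so cohort centroids separate coherently.
#'
#' @param n_probes number of probe sets.
#' @param n_controls number of healthy-control samples.
#' @param n_patients_per_cell patients per (age_group x outcome_class) cell.
#' @param age_groups non-control age groups simulated.
#' @param outcome_classes outcome classes simulated per age group.
#' @param timepoints_days ordered sampling grid in days post-injury.
#' @param fraction_responsive proportion of probes perturbed by trauma.
#' @param amplitude named list `amplitude[[age_group]][[as.character(day)]]`
#'   of mean absolute shifts in control-SD units.
#' @param recovery_rate per-day exponential decay of amplitude used for
#'   timepoints beyond the amplitude grid.
#' @param dropout_hazard per-timepoint probability that a patient's later
#'   samples are missing (monotone: once missing, always missing).
#' @param noise_sd residual SD in control-SD units.
#' @param seed integer seed governing every draw.
#' @return a validated list of class `SimulationParams`.
#' @export
simulation_params <- function(n_probes = 1000L,
                              n_controls = 17L,
                              n_patients_per_cell = 17L,
                              age_groups = c("aged", "young"),
                              outcome_classes = "complicated",
                              timepoints_days = c(0.5, 1, 4, 7),
                              fraction_responsive = 0.75,
                              amplitude = NULL,
                              recovery_rate = c(aged = 0.05, young = 0.30),
                              dropout_hazard = 0.15,
                              noise_sd = 1,
                              seed = 1L) {
  if (is.null(amplitude)) {
    amplitude <- list(
      young = c("0.5" = 1.2, "1" = 1.0, "4" = 0.5, "7" = 0.25),
      aged  = c("0.5" = 0.7, "1" = 0.7, "4" = 0.9, "7" = 0.8))
  }
  p <- list(n_probes = as.integer(n_probes),
            n_controls = as.integer(n_controls),
            n_patients_per_cell = as.integer(n_patients_per_cell),
            age_groups = age_groups,
            outcome_classes = outcome_classes,
            timepoints_days = timepoints_days,
            fraction_responsive = fraction_responsive,
            amplitude = amplitude,
            recovery_rate = recovery_rate,
            dropout_hazard = dropout_hazard,
            noise_sd = noise_sd,
            seed = as.integer(seed))
  if (p$n_probes < 1L || p$n_controls < 2L) {
    stop("need n_probes >= 1 and n_controls >= 2", call. = FALSE)
  }
  if (p$n_patients_per_cell < 1L) {
    stop("n_patients_per_cell must be >= 1", call. = FALSE)
  }
  if (!(fraction_responsive > 0 && fraction_responsive <= 1)) {
    stop("fraction_responsive must be in (0, 1]", call. = FALSE)
  }
  if (dropout_hazard < 0 || dropout_hazard > 1) {
    stop("dropout_hazard must be in [0, 1]", call. = FALSE)
  }
  if (any(unlist(amplitude) < 0) || noise_sd <= 0) {
    stop("amplitudes must be >= 0 and noise_sd > 0", call. = FALSE)
  }
  structure(p, class = "SimulationParams")
}

amplitude_at <- function(params, age_group, timepoint) {
  grid <- params$amplitude[[age_group]]
  key <- as.character(timepoint)
  if (key %in% names(grid)) return(unname(grid[key]))
  # beyond the grid: decay from the last gridded amplitude
  days <- as.numeric(names(grid))
  last <- which.max(days)
  unname(grid[last] *
           exp(-params$recovery_rate[[age_group]] * (timepoint - days[last])))
}

#' Simulate an expression cohort with an age-dependent trauma response
#'
#' Controls are drawn per probe from Normal(M_i, V_i) with the baselines
#' themselves drawn from hyperpriors (M_i ~ Normal(8, 2^2) log2 units;
#' V_i ~ scaled-inverse-chi-square with mean 0.25). Each responsive probe
#' receives, in every patient of a cohort cell at timepoint t, a mean shift
#' of sign s_i (fixed per probe) and magnitude `amplitude[age][t]` times the
#' probe's control SD; non-responsive probes are unshifted. Residual noise
#' has SD `noise_sd` control SDs. Dropout removes a patient's samples from
#' some timepoint onward with per-step hazard `dropout_hazard`.
#'
#' @param params a [simulation_params()] object.
#' @return list with `matrix` (an [expression_matrix()] of controls plus all
#'   retained patient samples), `meta` (sample metadata data.frame), and
#'   `truth` -- the ground-truth record: responsive probe ids and signs, the
#'   true per-probe baseline `means`/`variances`, per (age x timepoint)
#'   expected genome-wide DFR against the true baseline, and the seed.
#' @export
simulate_cohort <- function(params = simulation_params()) {
  stopifnot(inherits(params, "SimulationParams"))
  set.seed(params$seed)
  np <- params$n_probes
  probe_ids <- sprintf("probe_%04d", seq_len(np))

  M <- stats::rnorm(np, mean = 8, sd = 2)
  nu <- 10; tau2 <- 0.25 * (nu - 2) / nu        # scaled-inv-chisq, mean 0.25
  V <- nu * tau2 / stats::rchisq(np, df = nu)
  s <- sqrt(V)

  n_resp <- round(params$fraction_responsive * np)
  responsive <- sort(sample.int(np, n_resp))
  sign_i <- integer(np)
  sign_i[responsive] <- sample(c(-1L, 1L), n_resp, replace = TRUE)

  ctrl_ids <- sprintf("ctrl_%02d", seq_len(params$n_controls))
  cols <- list()
  for (id in ctrl_ids) cols[[id]] <- stats::rnorm(np, M, s)
  meta <- data.frame(sample_id = ctrl_ids,
                     patient_id = ctrl_ids,
                     age_group = "control",
                     outcome_class = "control",
                     timepoint_days = NA_real_,
                     gender = sample(c("male", "female"),
                                     params$n_controls, replace = TRUE),
                     survived_28d = TRUE,
                     stringsAsFactors = FALSE)

  noise <- params$noise_sd * s
  expected_dfr <- list()
  for (age in params$age_groups) {
    for (tp in params$timepoints_days) {
      amp <- amplitude_at(params, age, tp)
      # E[(e - M)^2 / V] = amp^2 per responsive probe + noise_sd^2 everywhere
      expected_dfr[[paste(age, tp, sep = "@")]] <-
        np * params$noise_sd^2 + n_resp * amp^2
    }
  }

  rows <- list()
  for (age in params$age_groups) {
    for (oc in params$outcome_classes) {
      for (k in seq_len(params$n_patients_per_cell)) {
        pid <- sprintf("%s_%s_%02d", age, oc, k)
        gender <- sample(c("male", "female"), 1L)
        ais <- paste(sample.int(5L, 3L, replace = TRUE), collapse = ";")
        survived <- stats::runif(1) > 0.15
        n_tp <- length(params$timepoints_days)
        keep <- n_tp
        for (j in seq_len(n_tp - 1L)) {
          if (stats::runif(1) < params$dropout_hazard) { keep <- j; break }
        }
        for (j in seq_len(keep)) {
          tp <- params$timepoints_days[j]
          amp <- amplitude_at(params, age, tp)
          sid <- sprintf("%s_d%s", pid, gsub("\\.", "p", tp))
          shift <- sign_i * amp * s
          cols[[sid]] <- stats::rnorm(np, M + shift, noise)
          rows[[sid]] <- data.frame(
            sample_id = sid, patient_id = pid, age_group = age,
            outcome_class = oc, timepoint_days = tp, gender = gender,
            ais = ais, survived_28d = survived, stringsAsFactors = FALSE)
        }
      }
    }
  }
  pat_meta <- do.call(rbind, rows)
  meta$ais <- paste(rep(0L, 3L), collapse = ";")
  meta <- rbind(meta[, c("sample_id", "patient_id", "age_group",
                         "outcome_class", "timepoint_days", "gender",
                         "ais", "survived_28d")],
                pat_meta[, c("sample_id", "patient_id", "age_group",
                             "outcome_class", "timepoint_days", "gender",
                             "ais", "survived_28d")])
  rownames(meta) <- NULL

  values <- do.call(cbind, cols)
  mat <- expression_matrix(values, probe_ids, names(cols))
  truth <- list(responsive_probes = probe_ids[responsive],
                signs = stats::setNames(sign_i, probe_ids),
                means = stats::setNames(M, probe_ids),
                variances = stats::setNames(V, probe_ids),
                expected_dfr = expected_dfr,
                control_ids = ctrl_ids,
                seed = params$seed)
  list(matrix = mat, meta = within_parse_ais(meta), truth = truth)
}

#' Simulate a longitudinal plasma cytokine panel
#'
#' Concentrations are log-normal: log concentration = analyte baseline +
#' time profile + delta_age * 1[aged] + Normal(0, dispersion) noise. The
#' default age effect is negative for every analyte, emulating the blunted
#' circulating cytokine response of the aged; the default time profile peaks
#' early and decays. Dropout is monotone as in [simulate_cohort()].
#'
#' @param analytes analyte names.
#' @param delta_age named (per analyte) or scalar age effect on the log
#'   scale; negative means aged below young.
#' @param time_profile numeric vector over `timepoints_hours` added to the
#'   log-mean (scalar 0 for a flat profile).
#' @param baseline_log named or scalar log baseline concentration (pg/mL).
#' @param dispersion residual SD on the log scale (> 0).
#' @param n_per_cohort patients per age group.
#' @param timepoints_hours sampling grid in hours post-injury.
#' @param dropout_hazard per-step monotone dropout probability.
#' @param seed integer seed.
#' @return list with `panel` (long data.frame: patient_id, age_group,
#'   analyte, timepoint_hours, concentration) and `truth` (delta_age and
#'   time profile used).
#' @export
simulate_cytokines <- function(analytes = c("IL-6", "IL-8", "IL-10",
                                            "IL-1b", "IP-10", "MCP-1",
                                            "TNF-a"),
                               delta_age = -0.5,
                               time_profile = NULL,
                               baseline_log = log(50),
                               dispersion = 0.5,
                               n_per_cohort = 17L,
                               timepoints_hours = c(12, 24, 96, 185,
                                                    336, 504, 672),
                               dropout_hazard = 0.1,
                               seed = 1L) {
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  if (is.null(time_profile)) {
    time_profile <- 1.5 * exp(-timepoints_hours / 150)
  } else if (length(time_profile) == 1L) {
    time_profile <- rep(time_profile, length(timepoints_hours))
  }
  if (length(time_profile) != length(timepoints_hours)) {
    stop("time_profile must match timepoints_hours", call. = FALSE)
  }
  expand <- function(x) {
    if (length(x) == 1L) stats::setNames(rep(x, length(analytes)), analytes)
    else x[analytes]
  }
  delta_age <- expand(delta_age)
  baseline_log <- expand(baseline_log)
  set.seed(seed)
  out <- list()
  for (age in c("young", "aged")) {
    for (k in seq_len(n_per_cohort)) {
      pid <- sprintf("%s_%02d", age, k)
      n_tp <- length(timepoints_hours)
      keep <- n_tp
      for (j in seq_len(n_tp - 1L)) {
        if (stats::runif(1) < dropout_hazard) { keep <- j; break }
      }
      for (j in seq_len(keep)) {
        mu <- baseline_log + time_profile[j] +
          if (age == "aged") delta_age else 0
        conc <- exp(stats::rnorm(length(analytes), mu, dispersion))
        out[[length(out) + 1L]] <- data.frame(
          patient_id = pid, age_group = age, analyte = analytes,
          timepoint_hours = timepoints_hours[j], concentration = conc,
          stringsAsFactors = FALSE)
      }
    }
  }
  list(panel = do.call(rbind, out),
       truth = list(delta_age = delta_age, time_profile = time_profile,
                    seed = seed))
}

#' Simulate a two-cohort clinical count table
#'
#' Multinomial draws per cohort at the given true category proportions;
#' any unallocated probability mass goes to an implicit "other" category
#' that is dropped, so column sums may be below the group totals.
#'
#' @param true_proportions list of two numeric vectors (one per group),
#'   same category names, each summing to at most 1.
#' @param group_totals two positive integer denominators.
#' @param group_labels cohort names.
#' @param seed integer seed.
#' @return a [clinical_count_table()].
#' @export
simulate_clinical_table <- function(true_proportions, group_totals,
                                    group_labels = c("young", "aged"),
                                    seed = 1L) {
  stopifnot(length(true_proportions) == 2L, length(group_totals) == 2L)
  cats <- names(true_proportions[[1L]])
  set.seed(seed)
  counts <- vapply(1:2, function(g) {
    p <- true_proportions[[g]]
    if (any(p < 0) || sum(p) > 1 + 1e-12) {
      stop("proportions must be in [0,1] and sum to <= 1", call. = FALSE)
    }
    rest <- max(0, 1 - sum(p))
    draw <- stats::rmultinom(1L, group_totals[g], c(p, rest))[, 1L]
    draw[seq_along(p)]
  }, numeric(length(cats)))
  counts <- matrix(counts, nrow = length(cats))
  rownames(counts) <- cats
  colnames(counts) <- group_labels
  clinical_count_table(counts, group_totals, cats, group_labels)
}
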