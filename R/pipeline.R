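#' Pipeline configuration
#'
#' One declarative object naming the input source (a simulation or TSV
#' paths), the selection thresholds, DFR options, classification options and
#' statistics options for an end-to-end run. Every stochastic stage carries
#' an explicit seed; the configuration round-trips through JSON unchanged.
#'
#' @param simulate a [simulation_params()] object, or NULL to load TSVs.
#' @param expression_path,meta_path TSV inputs used when `simulate` is NULL.
#' @param alpha,min_fold,use_adjusted selection thresholds.
#' @param dfr_subset "all" (every probe passing reference flooring) or
#'   "selected" (trauma-responsive probes only).
#' @param dfr_log report natural-log DFR.
#' @param classify_timepoint day whose samples feed the LOOCV comparison.
#' @param n_perm,perm_seed Monte Carlo permutation settings.
#' @param stats_alpha level for the trajectory group comparisons.
#' @param out_dir output directory for artifacts (NULL: nothing written).
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(simulate = simulation_params(),
                            expression_path = NULL, meta_path = NULL,
                            alpha = 0.001, min_fold = 2,
                            use_adjusted = TRUE,
                            dfr_subset = c("all", "selected"),
                            dfr_log = FALSE,
                            classify_timepoint = 0.5,
                            n_perm = 99L, perm_seed = 1L,
                            stats_alpha = 0.05,
                            out_dir = NULL) {
  dfr_subset <- match.arg(dfr_subset)
  if (is.null(simulate) &&
      (is.null(expression_path) || is.null(meta_path))) {
    stop("either a simulation or expression + metadata paths are required",
         call. = FALSE)
  }
  structure(list(simulate = simulate,
                 expression_path = expression_path, meta_path = meta_path,
                 alpha = alpha, min_fold = min_fold,
                 use_adjusted = use_adjusted,
                 dfr_subset = dfr_subset, dfr_log = dfr_log,
                 classify_timepoint = classify_timepoint,
                 n_perm = as.integer(n_perm),
                 perm_seed = as.integer(perm_seed),
                 stats_alpha = stats_alpha, out_dir = out_dir),
            class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Stages, in order: obtain the cohort (simulate or load), build the
#' healthy-control reference, select trauma-responsive probes, compute DFR
#' trajectories per (age group x timepoint), run LOOCV classification with
#' its Monte Carlo permutation null at the configured timepoint, and compare
#' cohort DFR distributions per timepoint (ANOVA + Newman-Keuls). With an
#' `out_dir` configured, per-stage TSV/JSON artifacts and a run manifest
#' (thresholds, seeds, stage counts) are written; identical configurations
#' produce identical bundles.
#'
#' @param config a [pipeline_config()].
#' @return list of class `PipelineResult` with `selection`, `trajectories`,
#'   `loocv`, `permutation`, `comparisons` (per timepoint), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (!is.null(config$simulate)) {
    sim <- simulate_cohort(config$simulate)
    mat <- sim$matrix; meta <- sim$meta
  } else {
    mat <- read_expression_matrix(config$expression_path)
    meta <- read_sample_meta(config$meta_path)
  }
  ctrl_ids <- meta$sample_id[meta$age_group == "control"]
  reference <- build_reference(mat, ctrl_ids)

  groups <- meta$age_group[match(colnames(mat), meta$sample_id)]
  selection <- select_trauma_responsive(mat, groups, alpha = config$alpha,
                                        min_fold = config$min_fold,
                                        use_adjusted = config$use_adjusted)
  subset <- if (config$dfr_subset == "selected") {
    selection$table$probe_id[selection$table$selected]
  } else NULL
  trajectories <- dfr_trajectories(mat, meta, reference,
                                   probe_subset = subset,
                                   natural_log = config$dfr_log)

  keep <- !is.na(meta$timepoint_days) &
    meta$timepoint_days == config$classify_timepoint
  cls_ids <- meta$sample_id[keep]
  cls_labels <- meta$age_group[keep]
  cls_mat <- expression_matrix(unclass(mat)[, cls_ids, drop = FALSE],
                               rownames(mat), cls_ids)
  permutation <- monte_carlo_label_permutation(
    cls_mat, cls_labels, n_perm = config$n_perm, seed = config$perm_seed,
    alpha = config$alpha, use_adjusted = FALSE,
    selection_inside_fold = TRUE)

  scores <- dfr_scores(mat, reference, probe_subset = subset,
                       natural_log = config$dfr_log)
  sc <- merge(scores, meta, by = "sample_id")
  sc <- sc[!is.na(sc$timepoint_days), , drop = FALSE]
  comparisons <- lapply(split(sc, sc$timepoint_days), function(cell) {
    if (length(unique(cell$age_group)) < 2L) return(NULL)
    anova_newman_keuls(cell$score, cell$age_group,
                       alpha = config$stats_alpha)
  })
  comparisons <- Filter(Negate(is.null), comparisons)

  manifest <- list(
    n_probes = nrow(mat), n_samples = ncol(mat),
    n_controls = length(ctrl_ids),
    thresholds = list(alpha = config$alpha, min_fold = config$min_fold,
                      use_adjusted = config$use_adjusted,
                      stats_alpha = config$stats_alpha),
    seeds = list(simulation = if (!is.null(config$simulate))
                   config$simulate$seed else NULL,
                 permutation = config$perm_seed),
    dfr = list(subset = config$dfr_subset, natural_log = config$dfr_log,
               n_probes_used = if (is.null(subset)) nrow(mat)
                               else length(subset)),
    counts = list(selected_probes = selection$n_selected,
                  classified_samples = length(cls_ids),
                  n_perm = config$n_perm))

  result <- structure(list(selection = selection,
                           trajectories = trajectories,
                           loocv = permutation$loocv,
                           permutation = permutation,
                           comparisons = comparisons,
                           manifest = manifest),
                      class = "PipelineResult")
  if (!is.null(config$out_dir)) write_pipeline_bundle(result, sc, config)
  result
}

write_pipeline_bundle <- function(result, scores, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  utils::write.table(result$selection$table, p("selection.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$trajectories, p("dfr_trajectories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(scores[, c("sample_id", "patient_id", "age_group",
                                "timepoint_days", "score")],
                     p("dfr_scores.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(observed_rate = result$permutation$observed_rate,
         p_value = result$permutation$p_value,
         n_perm = result$permutation$n_perm),
    p("classification.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult\n")
  print(x$selection)
  cat(sprintf("  LOOCV rate %.3f, permutation p = %.4g\n",
              x$permutation$observed_rate, x$permutation$p_value))
  cat(sprintf("  %d trajectory cells, %d timepoint comparisons\n",
              nrow(x$trajectories), length(x$comparisons)))
  invisible(x)
}
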