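#' Distance-from-reference (DFR) score for one sample
#'
#' The DFR summates a patient's total transcriptomic deviation from the
#' healthy-control baseline, counting up- and downregulation alike:
#'
#' \deqn{DFR = \sum_i (e_i - M_i)^2 / V_i}
#'
#' where `e_i` is the patient's expression on probe i and `M_i`, `V_i` are
#' the control-group mean and variance. The natural-log variant (log of the
#' sum, not a sum of logs) is available but off by default; reported scores
#' follow the no-log convention, with a display divisor of 10^3 applied only
#' at formatting time.
#'
#' @param expr_column named numeric vector of one sample's expression, names
#'   = probe ids (a column of an `ExpressionMatrix` extracted with
#'   `drop = FALSE` works via [dfr_scores()]).
#' @param reference a `ReferenceStats` from [build_reference()].
#' @param probe_subset probe ids to sum over; default all reference probes.
#' @param natural_log if TRUE return log(sum).
#' @return list of class `DFRScore`: `score`, `n_probes_used`,
#'   `natural_log_applied`, `display_scale` (1000).
#' @export
dfr_score <- function(expr_column, reference, probe_subset = NULL,
                      natural_log = FALSE) {
  stopifnot(inherits(reference, "ReferenceStats"))
  if (is.null(names(expr_column))) {
    stop("expr_column must be named by probe id", call. = FALSE)
  }
  if (is.null(probe_subset)) probe_subset <- reference$probe_ids
  if (length(probe_subset) == 0L) {
    stop("empty probe subset", call. = FALSE)
  }
  missing_ref <- setdiff(probe_subset, reference$probe_ids)
  missing_col <- setdiff(probe_subset, names(expr_column))
  if (length(missing_ref) || length(missing_col)) {
    stop("probes absent from ",
         if (length(missing_ref)) "reference: " else "sample: ",
         paste(utils::head(c(missing_ref, missing_col), 5L), collapse = ", "),
         call. = FALSE)
  }
  e <- expr_column[probe_subset]
  m <- reference$means[probe_subset]
  v <- reference$variances[probe_subset]
  s <- sum((e - m)^2 / v)
  structure(list(score = if (natural_log) log(s) else s,
                 n_probes_used = length(probe_subset),
                 natural_log_applied = natural_log,
                 display_scale = 1000),
            class = "DFRScore")
}

#' @export
print.DFRScore <- function(x, ...) {
  cat(sprintf("DFR%s = %.4g over %d probes (x10^3: %.3f)\n",
              if (x$natural_log_applied) " (natural log)" else "",
              x$score, x$n_probes_used, x$score / x$display_scale))
  invisible(x)
}

#' DFR scores for every sample of a matrix
#'
#' @param matrix an `ExpressionMatrix`.
#' @param reference a `ReferenceStats`.
#' @param probe_subset probe ids to sum over (default all reference probes).
#' @param natural_log if TRUE report log of each sum.
#' @return data.frame with `sample_id`, `score`, `n_probes_used`.
#' @export
dfr_scores <- function(matrix, reference, probe_subset = NULL,
                       natural_log = FALSE) {
  if (is.null(probe_subset)) probe_subset <- reference$probe_ids
  if (length(probe_subset) == 0L) stop("empty probe subset", call. = FALSE)
  missing_mat <- setdiff(probe_subset, rownames(matrix))
  if (length(missing_mat)) {
    stop("probes absent from matrix: ",
         paste(utils::head(missing_mat, 5L), collapse = ", "), call. = FALSE)
  }
  x <- unclass(matrix)[probe_subset, , drop = FALSE]
  m <- reference$means[probe_subset]
  v <- reference$variances[probe_subset]
  sums <- colSums((x - m)^2 / v)
  data.frame(sample_id = colnames(x),
             score = if (natural_log) log(sums) else unname(sums),
             n_probes_used = length(probe_subset),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cohort DFR trajectories
#'
#' Per (cohort x timepoint) mean, SD (n-1 denominator) and patient count of
#' DFR scores; patients missing a timepoint (dropout) are simply absent from
#' that cell, and empty cells are omitted with a warning. Display strings
#' use the conventional x10^3 divisor.
#'
#' @inheritParams dfr_scores
#' @param metadata sample metadata data.frame (see [read_sample_meta()]).
#' @param grouping metadata column(s) defining the cohort, default
#'   `"age_group"`.
#' @return data.frame of class `TrajectorySummary` with columns cohort,
#'   timepoint_days, mean_score, sd_score, n, display (mean +/- sd, x10^3).
#' @export
dfr_trajectories <- function(matrix, metadata, reference,
                             probe_subset = NULL, grouping = "age_group",
                             natural_log = FALSE) {
  miss <- setdiff(grouping, colnames(metadata))
  if (length(miss)) stop("grouping columns absent from metadata: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  scores <- dfr_scores(matrix, reference, probe_subset, natural_log)
  df <- merge(scores, metadata, by = "sample_id")
  df <- df[!is.na(df$timepoint_days), , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("no patient samples with timepoints to summarise")
    return(data.frame())
  }
  key <- do.call(interaction,
                 c(unname(as.list(df[grouping])), list(df$timepoint_days),
                   drop = TRUE))
  agg <- do.call(rbind, lapply(split(df, key), function(cell) {
    data.frame(cohort = paste(unlist(cell[1L, grouping]), collapse = "."),
               timepoint_days = cell$timepoint_days[1L],
               mean_score = mean(cell$score),
               sd_score = if (nrow(cell) > 1L) stats::sd(cell$score) else 0,
               n = nrow(cell), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$cohort, agg$timepoint_days), , drop = FALSE]
  agg$display <- sprintf("%.3f ± %.3f (x10^3)",
                         agg$mean_score / 1000, agg$sd_score / 1000)
  rownames(agg) <- NULL
  class(agg) <- c("TrajectorySummary", class(agg))
  agg
}
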