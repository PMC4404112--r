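#' Per-probe one-way ANOVA F-test
#'
#' Classical one-way F statistic and upper-tail p-value for every probe
#' (row) across the given sample groups, vectorised over probes. Probes
#' whose within-group mean square is exactly zero have it raised to the
#' `floor_quantile`-th quantile of the positive within-group mean squares
#' (the same quantile-floor safeguard used for reference variances);
#' a probe constant across all samples gets F = 0, p = 1.
#'
#' @param matrix an `ExpressionMatrix` (probes x samples).
#' @param group_labels character/factor of length `ncol(matrix)`.
#' @param floor_quantile quantile used to floor degenerate within-group
#'   variances.
#' @return data.frame with columns `probe_id`, `f_statistic`, `p_value`.
#' @export
ftest_per_probe <- function(matrix, group_labels, floor_quantile = 0.10) {
  x <- unclass(matrix)
  g <- factor(group_labels)
  if (length(g) != ncol(x)) {
    stop("group_labels must have one entry per sample", call. = FALSE)
  }
  sizes <- table(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("every group needs >= 2 samples; deficient: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  N <- ncol(x); k <- nlevels(g)
  # group means via indicator matrix: (probes x k)
  ind <- stats::model.matrix(~ g - 1L)
  gm <- x %*% ind %*% diag(1 / as.numeric(sizes), k)
  grand <- rowMeans(x)
  ssb <- as.numeric((gm - grand)^2 %*% as.numeric(sizes))
  sst <- rowSums((x - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  pos <- msw[msw > 0]
  if (length(pos) && any(msw == 0)) {
    msw[msw == 0] <- stats::quantile(pos, floor_quantile, names = FALSE)
  }
  f <- ifelse(msb == 0, 0, msb / msw)
  p <- ifelse(msb == 0, 1, stats::pf(f, k - 1, N - k, lower.tail = FALSE))
  data.frame(probe_id = rownames(x), f_statistic = f, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg false-discovery adjustment
#'
#' Step-up adjusted p-values: monotone after sorting and capped at 1.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
adjust_fdr_bh <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Signed fold change between log2-scale means
#'
#' Converts a difference of log2 means to a linear ratio r = 2^(group -
#' reference) and reports r when r >= 1 and -1/r otherwise, so that -3.1
#' reads as "3.1-fold down versus controls". The magnitude is always >= 1.
#'
#' @param group_mean_log2,reference_mean_log2 log2-scale means (vectors
#'   recycle as usual).
#' @return signed fold change(s).
#' @export
signed_fold_change <- function(group_mean_log2, reference_mean_log2) {
  r <- 2^(group_mean_log2 - reference_mean_log2)
  ifelse(r >= 1, r, -1 / r)
}

#' Select trauma-responsive probe sets
#'
#' Combines the per-probe F-test across groups with a fold-change filter
#' against the control group: a probe is selected when its (by default
#' false-discovery-adjusted) p-value is at most `alpha` and at least one
#' non-control group shows an absolute fold change of at least `min_fold`
#' versus the control mean. Counts of selected probes (and distinct genes,
#' when a probe-to-gene table is supplied) are recorded in the result.
#'
#' @inheritParams ftest_per_probe
#' @param alpha significance threshold on the chosen p-value.
#' @param min_fold minimum absolute linear fold change vs controls in at
#'   least one non-control group.
#' @param use_adjusted if TRUE (default) apply `alpha` to BH-adjusted
#'   p-values, else to raw p-values.
#' @param control_group label of the control group used as the fold-change
#'   reference; if absent from `group_labels` the fold filter is skipped.
#' @param probe_gene_table optional data.frame with columns `probe_id`,
#'   `gene` for gene-level counting.
#' @return object of class `SelectionResult`: data.frame `table` (probe_id,
#'   f_statistic, p_value, adjusted_p, per-group fold change columns,
#'   selected) plus the thresholds used and selected probe/gene counts.
#' @export
select_trauma_responsive <- function(matrix, group_labels, alpha = 0.001,
                                     min_fold = 2, use_adjusted = TRUE,
                                     control_group = "control",
                                     probe_gene_table = NULL,
                                     floor_quantile = 0.10) {
  ft <- ftest_per_probe(matrix, group_labels, floor_quantile)
  ft$adjusted_p <- adjust_fdr_bh(ft$p_value)
  x <- unclass(matrix)
  g <- factor(group_labels)
  fold_ok <- rep(TRUE, nrow(x))
  fold_cols <- list()
  if (control_group %in% levels(g)) {
    ref_mean <- rowMeans(x[, g == control_group, drop = FALSE])
    others <- setdiff(levels(g), control_group)
    folds <- sapply(others, function(lv) {
      signed_fold_change(rowMeans(x[, g == lv, drop = FALSE]), ref_mean)
    })
    folds <- base::matrix(folds, nrow = nrow(x),
                          dimnames = list(NULL, others))
    fold_cols <- as.data.frame(folds)
    names(fold_cols) <- paste0("fold_", others)
    fold_ok <- apply(abs(folds) >= min_fold, 1L, any)
  } else if (is.finite(min_fold) && min_fold > 1) {
    warning("no '", control_group,
            "' group present; fold-change filter skipped")
  }
  if (is.infinite(min_fold)) fold_ok <- rep(FALSE, nrow(x))
  p_used <- if (use_adjusted) ft$adjusted_p else ft$p_value
  selected <- p_used <= alpha & fold_ok
  tab <- cbind(ft, fold_cols)
  tab$selected <- selected
  n_genes <- NA_integer_
  if (!is.null(probe_gene_table)) {
    sel_genes <- probe_gene_table$gene[
      probe_gene_table$probe_id %in% tab$probe_id[selected]]
    n_genes <- length(unique(sel_genes))
  }
  structure(list(table = tab,
                 alpha = alpha, min_fold = min_fold,
                 use_adjusted = use_adjusted,
                 control_group = control_group,
                 n_selected = sum(selected),
                 n_genes_selected = n_genes),
            class = "SelectionResult")
}

#' @export
print.SelectionResult <- function(x, ...) {
  cat(sprintf(
    "SelectionResult: %d of %d probe sets selected (%s p <= %g, |fold| >= %g)\n",
    x$n_selected, nrow(x$table),
    if (x$use_adjusted) "adjusted" else "raw", x$alpha, x$min_fold))
  if (!is.na(x$n_genes_selected)) {
    cat(sprintf("  %d distinct genes\n", x$n_genes_selected))
  }
  invisible(x)
}

#' Restrict a selection to a user-supplied gene panel
#'
#' Returns the probes that both map to a panel gene (via the probe-to-gene
#' table) and pass the selection, mirroring the restriction of a previously
#' published outcome-predictive gene panel to the genes actually responsive
#' in the profiled cell population.
#'
#' @param selection a `SelectionResult`.
#' @param panel character vector of gene identifiers.
#' @param probe_gene_table data.frame with columns `probe_id`, `gene`.
#' @return list with `probe_ids` (selected panel probes), `genes`
#'   (surviving distinct panel genes), `n_panel` and `n_surviving`.
#'   An empty intersection yields an empty subset with a warning.
#' @export
restrict_gene_set <- function(selection, panel, probe_gene_table) {
  stopifnot(inherits(selection, "SelectionResult"))
  tab <- selection$table
  panel_probes <- probe_gene_table[probe_gene_table$gene %in% panel, ,
                                   drop = FALSE]
  keep <- tab$selected & tab$probe_id %in% panel_probes$probe_id
  probes <- tab$probe_id[keep]
  genes <- sort(unique(
    probe_gene_table$gene[probe_gene_table$probe_id %in% probes]))
  if (length(probes) == 0L) {
    warning("no panel gene survives the selection; empty probe subset")
  }
  list(probe_ids = probes, genes = genes,
       n_panel = length(unique(panel)), n_surviving = length(genes))
}
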