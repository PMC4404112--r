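#' Nearest-centroid classifier on expression profiles
#'
#' Fits one centroid (per-probe mean) per class and predicts the class whose
#' centroid minimises Euclidean distance over the working probe set; ties go
#' to the lexicographically smaller class label, so prediction is fully
#' deterministic.
#'
#' @param matrix an `ExpressionMatrix` (probes x training samples).
#' @param labels class label per training sample.
#' @return object of class `nearest_centroid`: list with `centroids`
#'   (probes x classes) and `classes`.
#' @export
nearest_centroid_fit <- function(matrix, labels) {
  g <- factor(labels)
  if (nlevels(g) < 2L) stop("need >= 2 classes", call. = FALSE)
  if (any(table(g) < 1L)) stop("empty class", call. = FALSE)
  x <- unclass(matrix)
  cents <- vapply(levels(g), function(lv) {
    rowMeans(x[, g == lv, drop = FALSE])
  }, numeric(nrow(x)))
  cents <- base::matrix(cents, nrow = nrow(x),
                        dimnames = list(rownames(x), levels(g)))
  structure(list(centroids = cents, classes = levels(g)),
            class = "nearest_centroid")
}

#' @rdname nearest_centroid_fit
#' @param model a fitted `nearest_centroid`.
#' @param column named numeric vector (one sample, names = probe ids).
#' @return predicted class label.
#' @export
nearest_centroid_predict <- function(model, column) {
  cents <- model$centroids
  if (!is.null(names(column))) column <- column[rownames(cents)]
  d2 <- colSums((cents - as.numeric(column))^2)
  # lexicographic tie-break: classes are sorted factor levels, min picks first
  model$classes[which.min(d2)]
}

#' Leave-one-out cross-validated misclassification rate
#'
#' For each held-out sample, probe selection (optional) and classifier
#' fitting use only the remaining samples; the held-out sample is then
#' predicted and compared with its true label. Re-running selection inside
#' every fold avoids the optimistic bias of selecting probes on the full
#' data; the biased variant (selection once, outside the folds) is retained
#' for comparison. In-fold selection keeps probes with F-test p <= `alpha`
#' across the training labels (BH-adjusted if `use_adjusted`); if it selects
#' nothing the fold falls back to all probes.
#'
#' @param matrix an `ExpressionMatrix`.
#' @param labels class label per sample.
#' @param alpha selection threshold used inside (or outside) folds; NULL
#'   disables selection.
#' @param use_adjusted apply `alpha` to BH-adjusted p-values.
#' @param selection_inside_fold re-select probes within each fold (default).
#' @param fit,predict classifier contract; defaults to nearest-centroid.
#' @return object of class `LoocvResult`: `n_samples`, `n_misclassified`,
#'   `misclassification_rate`, `predictions` data.frame,
#'   `selection_inside_fold`, `classifier`.
#' @export
loocv_misclassification <- function(matrix, labels, alpha = NULL,
                                    use_adjusted = FALSE,
                                    selection_inside_fold = TRUE,
                                    fit = nearest_centroid_fit,
                                    predict = nearest_centroid_predict) {
  x <- unclass(matrix)
  labels <- as.character(labels)
  n <- ncol(x)
  if (length(labels) != n) stop("one label per sample", call. = FALSE)
  select_probes <- function(cols, labs) {
    ft <- ftest_per_probe(expression_matrix(x[, cols, drop = FALSE],
                                            rownames(x),
                                            colnames(x)[cols]), labs)
    p <- if (use_adjusted) adjust_fdr_bh(ft$p_value) else ft$p_value
    keep <- ft$probe_id[p <= alpha]
    if (length(keep) == 0L) rownames(x) else keep
  }
  probes_global <- rownames(x)
  if (!is.null(alpha) && !selection_inside_fold) {
    tab <- table(labels)
    if (any(tab < 2L)) stop("selection needs >= 2 samples per class",
                            call. = FALSE)
    probes_global <- select_probes(seq_len(n), labels)
  }
  preds <- character(n)
  for (i in seq_len(n)) {
    train <- setdiff(seq_len(n), i)
    labs <- labels[train]
    if (length(unique(labs)) < 2L) {
      stop("fold for sample '", colnames(x)[i],
           "' collapses to a single class", call. = FALSE)
    }
    probes <- probes_global
    if (!is.null(alpha) && selection_inside_fold) {
      if (any(table(labs) < 2L)) {
        stop("fold for sample '", colnames(x)[i],
             "' leaves a class with < 2 samples for selection",
             call. = FALSE)
      }
      probes <- select_probes(train, labs)
    }
    model <- fit(expression_matrix(x[probes, train, drop = FALSE],
                                   probes, colnames(x)[train]), labs)
    preds[i] <- predict(model, x[probes, i])
  }
  miss <- sum(preds != labels)
  structure(list(n_samples = n, n_misclassified = miss,
                 misclassification_rate = miss / n,
                 predictions = data.frame(sample_id = colnames(x),
                                          true = labels, predicted = preds,
                                          stringsAsFactors = FALSE),
                 selection_inside_fold = selection_inside_fold,
                 classifier = "nearest_centroid"),
            class = "LoocvResult")
}

#' @export
print.LoocvResult <- function(x, ...) {
  cat(sprintf("LOOCV: %d/%d misclassified (rate %.3f)\n",
              x$n_misclassified, x$n_samples, x$misclassification_rate))
  invisible(x)
}

#' Monte Carlo permutation null for the LOOCV misclassification rate
#'
#' Permutes the sample labels uniformly (preserving class sizes) `n_perm`
#' times, re-runs the full LOOCV pipeline each time, and reports the
#' add-one-smoothed p-value `(1 + #\{permuted rate <= observed\}) /
#' (1 + n_perm)`, testing whether the observed rate beats chance.
#'
#' @inheritParams loocv_misclassification
#' @param n_perm number of label permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @return object of class `PermutationNull`: `observed_rate`,
#'   `permuted_rates`, `p_value`, `n_perm`, `seed`.
#' @export
monte_carlo_label_permutation <- function(matrix, labels, n_perm = 1000L,
                                          seed = 1L, alpha = NULL,
                                          use_adjusted = FALSE,
                                          selection_inside_fold = TRUE,
                                          fit = nearest_centroid_fit,
                                          predict = nearest_centroid_predict) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  obs <- loocv_misclassification(matrix, labels, alpha, use_adjusted,
                                 selection_inside_fold, fit, predict)
  set.seed(seed)
  perm_rates <- vapply(seq_len(n_perm), function(b) {
    loocv_misclassification(matrix, sample(labels), alpha, use_adjusted,
                            selection_inside_fold, fit,
                            predict)$misclassification_rate
  }, numeric(1))
  p <- (1 + sum(perm_rates <= obs$misclassification_rate)) / (1 + n_perm)
  structure(list(observed_rate = obs$misclassification_rate,
                 permuted_rates = perm_rates, p_value = p,
                 n_perm = n_perm, seed = seed, loocv = obs),
            class = "PermutationNull")
}

#' @export
print.PermutationNull <- function(x, ...) {
  cat(sprintf(
    "Permutation null: observed rate %.3f, p = %.4g (%d permutations)\n",
    x$observed_rate, x$p_value, x$n_perm))
  invisible(x)
}
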