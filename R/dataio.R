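#' Construct a validated expression matrix
#'
#' An expression matrix is a plain numeric matrix of normalized log2-scale
#' intensities with probe identifiers as row names and sample identifiers as
#' column names. This constructor enforces the container invariants used by
#' every downstream operation: unique identifiers, finite values, and
#' consistent dimensions. Normalization is assumed to have happened upstream;
#' the package never rescales intensities except where fold changes require
#' explicit conversion to the linear scale.
#'
#' @param values numeric matrix, one row per probe, one column per sample.
#' @param probe_ids character vector of unique probe identifiers; defaults to
#'   `rownames(values)`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `colnames(values)`.
#' @return a numeric matrix of class `ExpressionMatrix` with dimnames set.
#' @export
expression_matrix <- function(values, probe_ids = rownames(values),
                              sample_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(probe_ids) || is.null(sample_ids)) {
    stop("probe and sample identifiers are required", call. = FALSE)
  }
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values)) {
    stop("length(probe_ids) must equal nrow(values)", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("length(sample_ids) must equal ncol(values)", call. = FALSE)
  }
  if (anyDuplicated(probe_ids)) {
    stop("duplicated probe identifiers: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("expression values must all be finite (no NA/NaN/Inf)",
         call. = FALSE)
  }
  dimnames(values) <- list(probe_ids, sample_ids)
  class(values) <- c("ExpressionMatrix", class(values))
  values
}

#' Read an expression matrix from a tab-delimited file
#'
#' The canonical dialect is UTF-8 TSV: a header row of sample identifiers, a
#' first column of probe identifiers, and a numeric body. Missing or
#' non-numeric cells are rejected at load time (there is no imputation rule);
#' pre-filter probes or samples before writing the file.
#'
#' @param path path to a TSV file.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           fileEncoding = "UTF-8")
  if (ncol(tab) < 2L) stop("expected probe id column plus >=1 sample column",
                           call. = FALSE)
  probe_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  body <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric value at probe '%s', sample '%s'",
                 probe_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]),
         call. = FALSE)
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("missing value at probe '%s', sample '%s'",
                 probe_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]),
         call. = FALSE)
  }
  expression_matrix(num, probe_ids, sample_ids)
}

#' Write an expression matrix to a tab-delimited file
#'
#' Inverse of [read_expression_matrix()]: full double precision is preserved
#' so that write-then-read is an identity on identifiers and values.
#'
#' @param x an `ExpressionMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(probe_id = rownames(x),
                   format(unclass(x), digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' Sample metadata is a TSV with one row per sample and the columns
#' `sample_id`, `patient_id`, `age_group` (aged/young/control),
#' `outcome_class` (complicated/intermediate/uncomplicated/control),
#' `timepoint_days` (empty for controls), `gender`, `ais` (semicolon-joined
#' per-body-region integers) and `survived_28d` (TRUE/FALSE).
#'
#' @param path TSV path.
#' @return a data.frame with `ais` parsed into a list column of integer
#'   vectors.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  validate_sample_meta(within_parse_ais(tab))
}

within_parse_ais <- function(tab) {
  if (!is.null(tab$ais) && is.character(tab$ais)) {
    tab$ais <- lapply(strsplit(tab$ais, ";", fixed = TRUE),
                      function(v) as.integer(v[nzchar(v)]))
  }
  tab
}

#' @rdname read_sample_meta
#' @param meta a sample metadata data.frame as returned by
#'   [read_sample_meta()] or [simulate_cohort()].
#' @export
write_sample_meta <- function(meta, path) {
  out <- meta
  if (is.list(out$ais)) {
    out$ais <- vapply(out$ais, paste, character(1), collapse = ";")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a sample metadata table
#'
#' Checks the metadata invariants: unique sample ids, control samples carry
#' the control outcome class and no timepoint, and timepoints lie on the
#' study sampling grid (days post-injury) unless a custom grid is given.
#'
#' @param meta a data.frame with the SampleMeta columns.
#' @param timepoint_grid allowed `timepoint_days` values.
#' @return `meta`, invisibly usable, after validation.
#' @export
validate_sample_meta <- function(meta,
                                 timepoint_grid = c(0.5, 1, 4, 7, 14, 21, 28)) {
  stopifnot(is.data.frame(meta))
  needed <- c("sample_id", "patient_id", "age_group", "outcome_class")
  miss <- setdiff(needed, colnames(meta))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id in metadata", call. = FALSE)
  }
  ctrl <- meta$age_group == "control"
  if (any(ctrl & meta$outcome_class != "control")) {
    stop("control samples must have outcome_class 'control'", call. = FALSE)
  }
  if (!is.null(meta$timepoint_days)) {
    if (any(ctrl & !is.na(meta$timepoint_days))) {
      stop("control samples must not carry a timepoint", call. = FALSE)
    }
    tp <- meta$timepoint_days[!ctrl & !is.na(meta$timepoint_days)]
    off <- setdiff(unique(tp), timepoint_grid)
    if (length(off)) {
      stop("timepoints off the study grid: ", paste(off, collapse = ", "),
           call. = FALSE)
    }
  }
  meta
}

#' Read / write a long-format cytokine panel
#'
#' Long-format TSV with columns `patient_id`, `age_group`, `analyte`,
#' `timepoint_hours`, `concentration` (pg/mL, non-negative). Missing
#' timepoints (dropout) are simply absent rows.
#'
#' @param path TSV path.
#' @return a data.frame.
#' @export
read_cytokine_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  needed <- c("patient_id", "age_group", "analyte", "timepoint_hours",
              "concentration")
  miss <- setdiff(needed, colnames(tab))
  if (length(miss)) stop("cytokine panel missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(tab$concentration < 0, na.rm = TRUE)) {
    stop("cytokine concentrations must be non-negative", call. = FALSE)
  }
  tab
}

#' @rdname read_cytokine_panel
#' @param panel a cytokine panel data.frame.
#' @export
write_cytokine_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a GEO series-matrix text file (convenience)
#'
#' Minimal parser for the series-matrix flavour of GEO exports: metadata
#' lines beginning with `!`, and the expression table between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`. Sample
#' titles, when present (`!Sample_title`), are recovered with surrounding
#' quotes stripped.
#'
#' @param path path to a series-matrix text file (uncompressed).
#' @return a list with elements `matrix` (an [expression_matrix()]) and
#'   `sample_titles` (character or NULL).
#' @export
read_geo_series_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(beg) != 1L || length(end) != 1L || end <= beg) {
    stop("missing series-matrix table begin/end sentinels", call. = FALSE)
  }
  unquote <- function(x) gsub('^"|"$', "", x)
  titles <- NULL
  tl <- grep("^!Sample_title\\b", lines)
  if (length(tl) == 1L) {
    titles <- unquote(strsplit(lines[tl], "\t", fixed = TRUE)[[1L]][-1L])
  }
  body <- lines[(beg + 1L):(end - 1L)]
  cells <- lapply(strsplit(body, "\t", fixed = TRUE), unquote)
  header <- cells[[1L]]
  rows <- cells[-1L]
  probe_ids <- vapply(rows, `[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1L]),
                   numeric(length(header) - 1L)))
  if (length(header) == 2L) vals <- matrix(vals, ncol = 1L)
  list(matrix = expression_matrix(vals, probe_ids, header[-1L]),
       sample_titles = titles)
}

#' Build per-probe healthy-control reference statistics
#'
#' Computes the control-group mean `M_i` and unbiased (n-1 denominator)
#' variance `V_i` for every probe, the baseline against which the
#' distance-from-reference score standardizes each patient's expression.
#' Probes with near-zero control variance would make the score explode, so
#' variances below a floor -- the `floor_quantile`-th quantile of all
#' positive per-probe variances -- are raised to that floor.
#'
#' @param matrix an `ExpressionMatrix`.
#' @param control_sample_ids sample ids of the healthy controls (>= 2).
#' @param floor_quantile quantile of positive variances used as the variance
#'   floor; 0 floors only exactly-zero variances at the smallest positive
#'   variance.
#' @return an object of class `ReferenceStats`: list with `probe_ids`,
#'   `means`, `variances` (floored, strictly positive), `variance_floor`,
#'   `n_controls`.
#' @export
build_reference <- function(matrix, control_sample_ids, floor_quantile = 0.10) {
  missing_ids <- setdiff(control_sample_ids, colnames(matrix))
  if (length(missing_ids)) {
    stop("control samples absent from matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  if (length(control_sample_ids) < 2L) {
    stop("need at least 2 control samples to estimate a reference",
         call. = FALSE)
  }
  ctrl <- unclass(matrix)[, control_sample_ids, drop = FALSE]
  n <- ncol(ctrl)
  means <- rowMeans(ctrl)
  variances <- rowSums((ctrl - means)^2) / (n - 1)
  pos <- variances[variances > 0]
  if (length(pos) == 0L) {
    stop("degenerate reference: all control variances are zero",
         call. = FALSE)
  }
  floor_val <- stats::quantile(pos, floor_quantile, names = FALSE)
  variances <- pmax(variances, floor_val)
  structure(list(probe_ids = rownames(matrix),
                 means = stats::setNames(means, rownames(matrix)),
                 variances = stats::setNames(variances, rownames(matrix)),
                 variance_floor = floor_val,
                 n_controls = n),
            class = "ReferenceStats")
}

#' @export
print.ReferenceStats <- function(x, ...) {
  cat(sprintf(
    "ReferenceStats: %d probes, %d controls, variance floor %.4g\n",
    length(x$probe_ids), x$n_controls, x$variance_floor))
  invisible(x)
}

#' Assemble a two-cohort clinical count table
#'
#' Holds category counts for exactly two cohorts (e.g. discharge
#' dispositions for young vs aged), together with cohort denominators, for
#' univariate contingency statistics. Counts in one column may sum to less
#' than the group total when categories are not exhaustive.
#'
#' @param counts integer matrix, rows = categories, 2 columns = cohorts.
#' @param group_totals positive integer denominators per cohort.
#' @param row_labels,group_labels dimension labels; default from dimnames.
#' @param exclusive if TRUE (default) categories are mutually exclusive and
#'   each column must sum to at most its group total; set FALSE for
#'   non-exclusive indicator rows (e.g. comorbidities), where only the
#'   per-cell bound applies.
#' @return object of class `ClinicalCountTable`.
#' @export
clinical_count_table <- function(counts, group_totals,
                                 row_labels = rownames(counts),
                                 group_labels = colnames(counts),
                                 exclusive = TRUE) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2L) stop("exactly two cohorts required", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (length(group_totals) != 2L || any(group_totals <= 0)) {
    stop("group_totals must be two positive integers", call. = FALSE)
  }
  if (exclusive && any(colSums(counts) > group_totals)) {
    stop("column counts exceed the group total", call. = FALSE)
  }
  if (any(counts > rep(group_totals, each = nrow(counts)))) {
    stop("a count exceeds its group total", call. = FALSE)
  }
  dimnames(counts) <- list(row_labels, group_labels)
  structure(list(counts = counts, group_totals = group_totals,
                 row_labels = row_labels, group_labels = group_labels),
            class = "ClinicalCountTable")
}

#' Read a clinical count table from TSV
#'
#' Format: header `category<TAB><group1><TAB><group2>`, one category per
#' row, and a final row labelled `TOTAL` carrying the cohort denominators.
#'
#' @param path TSV path.
#' @param exclusive passed to [clinical_count_table()].
#' @return a [clinical_count_table()].
#' @export
read_clinical_count_table <- function(path, exclusive = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  tot_row <- tab[[1L]] == "TOTAL"
  if (sum(tot_row) != 1L) stop("expected exactly one TOTAL row", call. = FALSE)
  counts <- as.matrix(tab[!tot_row, -1L, drop = FALSE])
  rownames(counts) <- tab[[1L]][!tot_row]
  clinical_count_table(counts,
                       group_totals = as.numeric(tab[tot_row, -1L]),
                       group_labels = colnames(tab)[-1L],
                       exclusive = exclusive)
}
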