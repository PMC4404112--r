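#' Construct aged-young matched pairs
#'
#' Candidate pairs must match exactly on gender, 28-day survival, and the
#' set of sampled timepoints; among candidates the summed absolute
#' difference in per-region abbreviated injury scores (AIS) is minimised
#' greedily: the globally cheapest remaining candidate pair is accepted
#' first, ties broken by ascending aged then young patient id. Greedy
#' matching is verified against an exhaustive assignment oracle on small
#' instances in the test suite.
#'
#' @param metadata sample metadata data.frame (one row per sample) with
#'   `patient_id`, `age_group`, `gender`, `ais` (list column of integer
#'   vectors or semicolon string), `survived_28d`, `timepoint_days`.
#' @return object of class `MatchedPairSet`: data.frame `pairs` (aged,
#'   young, ais_distance), `unmatched` ids, and the criteria record.
#' @export
match_pairs <- function(metadata) {
  metadata <- within_parse_ais(metadata)
  pat <- lapply(split(metadata, metadata$patient_id), function(d) {
    list(patient_id = d$patient_id[1L],
         age_group = d$age_group[1L],
         gender = d$gender[1L],
         ais = if (is.list(d$ais)) d$ais[[1L]] else d$ais[1L],
         survived = d$survived_28d[1L],
         timepoints = sort(unique(d$timepoint_days[!is.na(d$timepoint_days)])))
  })
  aged <- Filter(function(p) p$age_group == "aged", pat)
  young <- Filter(function(p) p$age_group == "young", pat)
  ais_dist <- function(a, b) {
    n <- max(length(a), length(b))
    sum(abs(c(a, rep(0L, n - length(a))) - c(b, rep(0L, n - length(b)))))
  }
  cand <- list()
  for (a in aged) for (y in young) {
    if (!identical(a$gender, y$gender)) next
    if (!identical(a$survived, y$survived)) next
    if (!identical(a$timepoints, y$timepoints)) next
    cand[[length(cand) + 1L]] <- data.frame(
      aged = a$patient_id, young = y$patient_id,
      ais_distance = ais_dist(a$ais, y$ais), stringsAsFactors = FALSE)
  }
  pairs <- data.frame(aged = character(), young = character(),
                      ais_distance = numeric(), stringsAsFactors = FALSE)
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$ais_distance, cand$aged, cand$young), ,
                 drop = FALSE]
    used_a <- character(); used_y <- character()
    for (r in seq_len(nrow(cand))) {
      row <- cand[r, ]
      if (row$aged %in% used_a || row$young %in% used_y) next
      pairs <- rbind(pairs, row)
      used_a <- c(used_a, row$aged); used_y <- c(used_y, row$young)
    }
  }
  all_ids <- vapply(c(aged, young), `[[`, character(1), "patient_id")
  structure(list(pairs = pairs,
                 unmatched = sort(setdiff(all_ids,
                                          c(pairs$aged, pairs$young))),
                 criteria = c("gender (exact)", "28-day survival (exact)",
                              "sampled timepoints (identical set)",
                              "minimal summed |AIS difference|")),
            class = "MatchedPairSet")
}

#' @export
print.MatchedPairSet <- function(x, ...) {
  cat(sprintf("MatchedPairSet: %d pairs, %d unmatched\n",
              nrow(x$pairs), length(x$unmatched)))
  invisible(x)
}

#' One-way ANOVA with Student-Newman-Keuls pairwise comparisons
#'
#' Omnibus one-way ANOVA followed by the SNK step-down procedure on the
#' studentized-range distribution: group means are ordered and each pair is
#' tested at the critical value for the number of means it spans; a
#' non-rejected stretch blocks all comparisons nested inside it. With two
#' groups the SNK decision coincides with the pooled two-sample t-test.
#' Unequal group sizes use the pairwise 2/(1/ni+1/nj) harmonic form.
#'
#' @param values numeric response vector.
#' @param groups group label per observation (>= 2 groups, >= 2 each).
#' @param alpha familywise level for the stepwise comparisons.
#' @return object of class `GroupComparison`: omnibus `f_statistic`,
#'   `p_value`, `df`, and `pairwise` data.frame (group_a, group_b, span,
#'   q_statistic, p_value, reject).
#' @export
anova_newman_keuls <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(table(g) < 2L)) stop("each group needs >= 2 observations",
                               call. = FALSE)
  if (all(tapply(values, g, stats::var) == 0)) {
    stop("degenerate (zero) within-group variance", call. = FALSE)
  }
  fit <- stats::aov(values ~ g)
  an <- stats::anova(fit)
  mse <- an[["Mean Sq"]][2L]
  df_err <- an[["Df"]][2L]
  means <- tapply(values, g, mean)
  ns <- tapply(values, g, length)
  ord <- order(means)
  means <- means[ord]; ns <- ns[ord]
  k <- length(means)
  lv <- names(means)
  blocked <- matrix(FALSE, k, k)
  pw <- list()
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      se <- sqrt(mse / 2 * (1 / ns[i] + 1 / ns[j]))
      q <- abs(means[j] - means[i]) / se
      p <- stats::ptukey(q, span, df_err, lower.tail = FALSE)
      reject <- !blocked[i, j] && p <= alpha
      if (!reject) {
        # block every comparison nested inside a non-rejected stretch
        for (a in i:j) for (b in i:j) blocked[a, b] <- TRUE
      }
      pw[[length(pw) + 1L]] <- data.frame(
        group_a = lv[i], group_b = lv[j], span = span,
        q_statistic = unname(q), p_value = unname(p), reject = reject,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(method = "newman-keuls", alpha = alpha,
                 f_statistic = an[["F value"]][1L],
                 p_value = an[["Pr(>F)"]][1L],
                 df = an[["Df"]],
                 group_means = means, group_ns = ns,
                 pairwise = do.call(rbind, pw)),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("GroupComparison (%s): omnibus %s = %.4g, p = %.4g\n",
              x$method,
              if (x$method == "kruskal-wallis") "H" else "F",
              if (x$method == "kruskal-wallis") x$h_statistic
              else x$f_statistic,
              x$p_value))
  if (!is.null(x$pairwise)) {
    rej <- x$pairwise[x$pairwise$reject, , drop = FALSE]
    cat(sprintf("  %d pairwise rejection(s) at alpha = %g\n",
                nrow(rej), x$alpha))
  }
  invisible(x)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected rank-based H with the chi-square reference distribution.
#'
#' @param values numeric response vector.
#' @param groups group label per observation (>= 2 groups).
#' @return object of class `GroupComparison` with `h_statistic`, `df`,
#'   `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  kt <- stats::kruskal.test(values, g)
  h <- unname(kt$statistic); p <- kt$p.value
  if (!is.finite(h)) { h <- 0; p <- 1 }   # every observation tied
  structure(list(method = "kruskal-wallis",
                 h_statistic = h,
                 df = unname(kt$parameter),
                 p_value = p, alpha = NA, pairwise = NULL),
            class = "GroupComparison")
}

#' Holm-Sidak step-down multiple comparisons
#'
#' Sorted p-values p_(j) are compared step-down with 1 - (1-alpha)^(1/(m-j+1));
#' the first failure stops all later rejections. Adjusted values are the
#' running maximum of 1 - (1-p_(j))^(m-j+1), capped at 1, reported in the
#' input order.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param alpha familywise level.
#' @return data.frame with `p_value`, `adjusted_p`, `reject`.
#' @export
holm_sidak <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  adj <- pmin(1, cummax(1 - (1 - ps)^(m - seq_len(m) + 1)))
  crit <- 1 - (1 - alpha)^(1 / (m - seq_len(m) + 1))
  rej_sorted <- logical(m)
  for (j in seq_len(m)) {
    if (ps[j] <= crit[j]) rej_sorted[j] <- TRUE else break
  }
  out <- data.frame(p_value = p_values,
                    adjusted_p = numeric(m), reject = logical(m))
  out$adjusted_p[ord] <- adj
  out$reject[ord] <- rej_sorted
  out
}

#' Age-by-time linear model for a cytokine analyte
#'
#' Fits a fixed-effects linear model on log-transformed concentrations with
#' categorical age group and categorical timepoint factors (optionally their
#' interaction) and reports type-II F tests per factor, which handle the
#' unbalanced designs produced by longitudinal dropout. Zero concentrations
#' are offset by half the smallest positive value before the log.
#'
#' @param panel long-format cytokine data.frame (see
#'   [read_cytokine_panel()]).
#' @param analyte analyte name to model.
#' @param include_interaction add the age:time interaction term.
#' @return object of class `GlmResult`: `effects` data.frame (term, df,
#'   f_statistic, p_value), `age_estimate` (aged-vs-young coefficient on the
#'   log scale), `n_obs`, `model`.
#' @export
cytokine_glm <- function(panel, analyte, include_interaction = FALSE) {
  d <- panel[panel$analyte == analyte & !is.na(panel$concentration), ,
             drop = FALSE]
  if (nrow(d) == 0L) stop("no observations for analyte '", analyte, "'",
                          call. = FALSE)
  if (length(unique(d$age_group)) < 2L ||
      length(unique(d$timepoint_hours)) < 2L) {
    stop("need >= 2 age groups and >= 2 timepoints with data", call. = FALSE)
  }
  conc <- d$concentration
  if (any(conc == 0)) conc <- conc + min(conc[conc > 0]) / 2
  d$log_conc <- log(conc)
  # young is the reference level when present, so the age estimate reads as
  # the aged-minus-young log-concentration shift
  lev <- unique(d$age_group)
  if ("young" %in% lev) lev <- c("young", setdiff(lev, "young"))
  d$age_group <- factor(d$age_group, levels = lev)
  d$time_f <- factor(d$timepoint_hours)
  fml <- if (include_interaction) log_conc ~ age_group * time_f
         else log_conc ~ age_group + time_f
  fit <- stats::lm(fml, data = d)
  a2 <- car::Anova(fit, type = 2)
  terms <- rownames(a2)[rownames(a2) != "Residuals"]
  effects <- data.frame(term = sub("time_f", "time", terms),
                        df = a2[terms, "Df"],
                        f_statistic = a2[terms, "F value"],
                        p_value = a2[terms, "Pr(>F)"],
                        stringsAsFactors = FALSE)
  coefs <- stats::coef(fit)
  age_coef <- coefs[grep("^age_group", names(coefs))][1L]
  structure(list(analyte = analyte, effects = effects,
                 age_estimate = unname(age_coef),
                 n_obs = nrow(d), model = fit,
                 include_interaction = include_interaction),
            class = "GlmResult")
}

#' @export
print.GlmResult <- function(x, ...) {
  cat(sprintf("GlmResult for %s (n = %d):\n", x$analyte, x$n_obs))
  print(x$effects, row.names = FALSE)
  invisible(x)
}

#' Univariate contingency statistics for one category of a count table
#'
#' Reports each cohort's proportion for the chosen category (formatted at a
#' configurable percent precision), the two-sided Fisher exact p-value on
#' the 2x2 table (category vs rest, cohort vs cohort), and the sample odds
#' ratio with the Haldane half-count correction when any cell is zero.
#'
#' @param table a [clinical_count_table()].
#' @param row category (row label or index) to compare.
#' @param percent_digits decimals used in the percent strings (default 1,
#'   matching typical clinical-table precision).
#' @return list: `proportions`, `percents` (formatted), `fisher_p`,
#'   `odds_ratio`, `table2x2`.
#' @export
contingency_stats <- function(table, row, percent_digits = 1) {
  stopifnot(inherits(table, "ClinicalCountTable"))
  if (is.character(row)) row <- match(row, table$row_labels)
  if (is.na(row) || row < 1L || row > nrow(table$counts)) {
    stop("unknown category row", call. = FALSE)
  }
  a <- table$counts[row, ]
  b <- table$group_totals - a
  m <- rbind(category = a, rest = b)
  prop <- a / table$group_totals
  pct <- sprintf(paste0("%.", percent_digits, "f%%"), 100 * prop)
  ft <- stats::fisher.test(m)
  cells <- unname(c(m[1, 1], m[1, 2], m[2, 1], m[2, 2]))
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  list(proportions = prop,
       percents = stats::setNames(pct, table$group_labels),
       fisher_p = ft$p.value, odds_ratio = or, table2x2 = m)
}

#' Wilcoxon two-sample (rank-sum) test
#'
#' Exact p by enumeration when the combined sample size is at most 12 and
#' no ties are present; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param x,y numeric samples (>= 1 observation each).
#' @param alternative as in [stats::wilcox.test()].
#' @return list: `statistic` (rank-sum W of `x`), `p_value`, `exact`.
#' @export
wilcoxon_two_sample <- function(x, y, alternative = "two.sided") {
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples need >= 1 observation", call. = FALSE)
  }
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y)) <= 12L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1   # every observation tied across both samples
  list(statistic = unname(wt$statistic), p_value = p, exact = exact)
}
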