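make_patient_meta <- function(patient_id, age_group, gender, ais,
                              survived, timepoints) {
  do.call(rbind, lapply(seq_along(timepoints), function(i) {
    data.frame(sample_id = paste0(patient_id, "_", i),
               patient_id = patient_id, age_group = age_group,
               outcome_class = "complicated", gender = gender,
               survived_28d = survived, timepoint_days = timepoints[i],
               stringsAsFactors = FALSE)
  })) -> d
  d$ais <- rep(list(ais), nrow(d))
  d
}

test_that("matching requires exact gender/survival/timepoints and breaks ties by id", {
  meta <- rbind(
    make_patient_meta("aged_b", "aged", "male", c(3, 3, 3), TRUE, c(0.5, 1)),
    make_patient_meta("aged_a", "aged", "male", c(3, 3, 3), TRUE, c(0.5, 1)),
    make_patient_meta("young_b", "young", "male", c(3, 3, 3), TRUE, c(0.5, 1)),
    make_patient_meta("young_a", "young", "male", c(3, 3, 3), TRUE, c(0.5, 1)))
  mp <- match_pairs(meta)
  expect_identical(nrow(mp$pairs), 2L)
  expect_identical(mp$pairs$aged, c("aged_a", "aged_b"))
  expect_identical(mp$pairs$young, c("young_a", "young_b"))
  expect_length(mp$unmatched, 0)

  # hard criteria: male survivor finds no female candidate
  meta2 <- rbind(
    make_patient_meta("aged_m", "aged", "male", c(3, 3, 3), TRUE, 0.5),
    make_patient_meta("young_f", "young", "female", c(3, 3, 3), TRUE, 0.5))
  mp2 <- match_pairs(meta2)
  expect_identical(nrow(mp2$pairs), 0L)
  expect_identical(mp2$unmatched, c("aged_m", "young_f"))

  # survival mismatch also blocks
  meta3 <- rbind(
    make_patient_meta("aged_s", "aged", "male", c(3, 3, 3), TRUE, 0.5),
    make_patient_meta("young_d", "young", "male", c(3, 3, 3), FALSE, 0.5))
  expect_identical(nrow(match_pairs(meta3)$pairs), 0L)
})

test_that("greedy matching recovers a known unique optimal assignment", {
  # diagonal-dominant AIS costs: aged_i <-> young_i is uniquely optimal
  set.seed(401)
  for (rep in 1:5) {
    n <- 5
    perm <- sample(n)
    meta <- list()
    for (i in seq_len(n)) {
      # regions 1-2 separate patients by >= 2 between indices; diagonal
      # cost <= 1 < any off-diagonal cost, so the optimum is unique
      base <- c(i, i, sample(1:4, 1))
      meta[[length(meta) + 1L]] <-
        make_patient_meta(sprintf("aged_%d", i), "aged", "male",
                          base, TRUE, 0.5)
      # partner young_perm[i] shares (nearly) the same AIS; others far off
      meta[[length(meta) + 1L]] <-
        make_patient_meta(sprintf("young_%d", perm[i]), "young", "male",
                          base + c(0, 0, sample(0:1, 1)), TRUE, 0.5)
    }
    meta <- do.call(rbind, meta)
    mp <- match_pairs(meta)
    got <- mp$pairs[order(mp$pairs$aged), ]

    # exhaustive assignment oracle over all n! young permutations
    pat <- split(meta, meta$patient_id)
    ais_of <- function(id) pat[[id]]$ais[[1]]
    cost <- function(a, y) sum(abs(ais_of(a) - ais_of(y)))
    aged_ids <- sprintf("aged_%d", 1:n)
    young_ids <- sprintf("young_%d", 1:n)
    perms <- rbind(1:n)
    perms <- as.matrix(expand.grid(rep(list(1:n), n)))
    perms <- perms[apply(perms, 1, function(p) !any(duplicated(p))), ]
    costs <- apply(perms, 1, function(p) {
      sum(vapply(1:n, function(i) cost(aged_ids[i], young_ids[p[i]]),
                 numeric(1)))
    })
    expect_equal(sum(got$ais_distance), min(costs))
  }
})

test_that("SNK with two groups coincides with the pooled t decision", {
  set.seed(402)
  for (rep in 1:10) {
    x <- rnorm(8); y <- rnorm(8, mean = runif(1, 0, 2))
    res <- anova_newman_keuls(c(x, y), rep(c("a", "b"), each = 8))
    tt <- stats::t.test(x, y, var.equal = TRUE)
    # ptukey is evaluated by numerical integration; agreement to ~1e-7
    expect_equal(res$pairwise$p_value, tt$p.value, tolerance = 1e-6)
    expect_identical(res$pairwise$reject, tt$p.value <= 0.05)
  }
})

test_that("SNK rejects the extreme pair but not the null pair", {
  set.seed(403)
  vals <- c(rnorm(10, 0), rnorm(10, 0), rnorm(10, 10))
  g <- rep(c("g1", "g2", "g3"), each = 10)
  res <- anova_newman_keuls(vals, g)
  pw <- res$pairwise
  null_pair <- pw[pw$span == 2 & pw$group_a %in% c("g1", "g2") &
                    pw$group_b %in% c("g1", "g2"), ]
  far_pairs <- pw[pw$group_b == "g3" | pw$group_a == "g3", ]
  expect_false(null_pair$reject)
  expect_true(all(far_pairs$reject))
  # oracle: q statistics against hand-computed studentized range quantities
  an <- stats::anova(stats::aov(vals ~ factor(g)))
  mse <- an[["Mean Sq"]][2]
  means <- sort(tapply(vals, g, mean))
  q_hand <- (means[3] - means[1]) / sqrt(mse / 2 * (1 / 10 + 1 / 10))
  expect_equal(max(pw$q_statistic), unname(q_hand), tolerance = 1e-10)
  expect_equal(pw$p_value[pw$span == 3],
               stats::ptukey(unname(q_hand), 3, 27, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("equal group means yield no SNK rejections", {
  vals <- rep(c(1, 2, 3), times = 3)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- anova_newman_keuls(vals, g)
  expect_false(any(res$pairwise$reject))
  expect_error(anova_newman_keuls(rep(5, 6), rep(c("a", "b"), each = 3)),
               "degenerate")
})

test_that("Kruskal-Wallis H matches the tie-corrected rank formula", {
  set.seed(404)
  x <- c(1.1, 3.2, 2.5); y <- c(4.7, 0.3, 6.1)
  res <- kruskal_wallis(c(x, y), rep(c("a", "b"), each = 3))
  r <- rank(c(x, y)); n <- 6
  h_hand <- 12 / (n * (n + 1)) *
    (sum(r[1:3])^2 / 3 + sum(r[4:6])^2 / 3) - 3 * (n + 1)
  expect_equal(res$h_statistic, h_hand, tolerance = 1e-12)
  # identical groups: H = 0 after tie correction handles the all-tied ranks
  res0 <- kruskal_wallis(rep(c(2, 2, 2), 2), rep(c("a", "b"), each = 3))
  expect_equal(res0$h_statistic, 0, tolerance = 1e-12)
  # exhaustive small-sample permutation: observed H sits in the null tail
  # for a large shift
  big <- kruskal_wallis(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  combs <- utils::combn(6, 3)
  vals <- c(1, 2, 3, 11, 12, 13)
  h_of <- function(idx) {
    g <- rep("b", 6); g[idx] <- "a"
    kruskal_wallis(vals, g)$h_statistic
  }
  null_h <- apply(combs, 2, h_of)
  expect_equal(mean(null_h >= big$h_statistic - 1e-12), 2 / 20)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
  # power: large shift, larger n
  set.seed(405)
  shifted <- kruskal_wallis(c(rnorm(10), rnorm(10, 5)),
                            rep(c("a", "b"), each = 10))
  expect_lt(shifted$p_value, 0.05)
})

test_that("Holm-Sidak reproduces the hand step-down computation", {
  one <- holm_sidak(0.04, alpha = 0.05)
  expect_true(one$reject)
  expect_equal(one$adjusted_p, 0.04)
  hs <- holm_sidak(c(0.001, 0.2, 0.9), alpha = 0.05)
  expect_identical(hs$reject, c(TRUE, FALSE, FALSE))
  expect_equal(hs$adjusted_p[1], 1 - (1 - 0.001)^3, tolerance = 1e-12)
  expect_equal(hs$adjusted_p[2], 1 - (1 - 0.2)^2, tolerance = 1e-12)
  none <- holm_sidak(rep(1, 4))
  expect_false(any(none$reject))
  # rejects a superset of Bonferroni and a subset of unadjusted
  set.seed(406)
  for (i in 1:5) {
    p <- runif(12)^2
    hs <- holm_sidak(p, alpha = 0.05)
    bonf <- p <= 0.05 / 12
    expect_true(all(hs$reject[bonf]))
    expect_true(all(p[hs$reject] <= 0.05))
  }
  expect_error(holm_sidak(c(0.2, -0.1)), "0, 1")
})

test_that("the age-by-time model matches a hand/aov oracle on balanced data", {
  # balanced 2x2 with 3 replicates per cell: type II = sequential ANOVA
  set.seed(407)
  d <- expand.grid(patient = 1:3, age_group = c("young", "aged"),
                   timepoint_hours = c(12, 96))
  mu <- with(d, 4 + ifelse(age_group == "aged", -1, 0) +
               ifelse(timepoint_hours == 96, -0.5, 0))
  d$concentration <- exp(mu + rnorm(nrow(d), 0, 0.2))
  d$analyte <- "IL-6"
  d$patient_id <- paste0(d$age_group, d$patient)
  fit <- cytokine_glm(d, "IL-6")
  an <- stats::anova(stats::aov(
    log(concentration) ~ factor(age_group) + factor(timepoint_hours),
    data = d))
  expect_equal(fit$effects$f_statistic[fit$effects$term == "age_group"],
               an[["F value"]][1], tolerance = 1e-10)
  expect_equal(fit$effects$f_statistic[fit$effects$term == "time"],
               an[["F value"]][2], tolerance = 1e-10)
  expect_lt(fit$age_estimate, 0)
  expect_error(cytokine_glm(d, "IL-99"), "no observations")
})

test_that("the age factor's null type-I error is calibrated", {
  set.seed(408)
  rejections <- vapply(1:300, function(r) {
    sim <- simulate_cytokines(analytes = "IL-6", delta_age = 0,
                              time_profile = 0, dispersion = 0.5,
                              n_per_cohort = 8,
                              timepoints_hours = c(12, 96, 336),
                              dropout_hazard = 0.1, seed = 7000 + r)
    fit <- cytokine_glm(sim$panel, "IL-6")
    fit$effects$p_value[fit$effects$term == "age_group"] < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("an interaction term can be requested", {
  sim <- simulate_cytokines(analytes = "IL-8", delta_age = -1,
                            n_per_cohort = 10, seed = 409)
  fit <- cytokine_glm(sim$panel, "IL-8", include_interaction = TRUE)
  expect_true("age_group:time" %in% fit$effects$term)
})

test_that("contingency statistics reproduce printed-style percentages", {
  counts <- rbind(home = c(480, 66), other = c(100, 40))
  tab <- clinical_count_table(counts, group_totals = c(1395, 533),
                              group_labels = c("young", "aged"))
  cs <- contingency_stats(tab, "home")
  expect_identical(unname(cs$percents), c("34.4%", "12.4%"))
  expect_equal(unname(cs$proportions), c(480 / 1395, 66 / 533))
  expect_lt(cs$fisher_p, 0.001)
})

test_that("Fisher exact p matches hypergeometric enumeration", {
  # symmetric table: OR 1, p 1
  sym <- clinical_count_table(rbind(x = c(4, 4)), c(8, 8))
  cs <- contingency_stats(sym, "x")
  expect_equal(cs$odds_ratio, 1)
  expect_equal(cs$fisher_p, 1)
  # 3,0 / 0,3 -> p = 1/10
  t2 <- clinical_count_table(rbind(x = c(3, 0)), c(3, 3))
  cs2 <- contingency_stats(t2, "x")
  expect_equal(cs2$fisher_p, 1 / 10, tolerance = 1e-12)
  expect_gt(cs2$odds_ratio, 1)   # Haldane-corrected, finite

  # enumeration oracle over random tables with total <= 40
  fisher_enum <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    support <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(support, m, n, k)
    sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
  }
  set.seed(410)
  for (i in 1:20) {
    tot <- sample(10:40, 2)
    a <- sample(0:tot[1], 1); c <- sample(0:tot[2], 1)
    tab <- clinical_count_table(rbind(x = c(a, c)), tot)
    got <- contingency_stats(tab, "x")$fisher_p
    expect_equal(got, fisher_enum(a, tot[1] - a, c, tot[2] - c),
                 tolerance = 1e-7)
  }
  expect_error(clinical_count_table(rbind(x = c(1, 1)), c(0, 5)),
               "positive")
})

test_that("Wilcoxon two-sample matches small-sample enumeration", {
  idp <- wilcoxon_two_sample(c(3, 3, 3), c(3, 3, 3))
  expect_gt(idp$p_value, 0.9)
  expect_false(idp$exact)
  # x entirely below y: one-sided p = 1/C(4,2) = 1/6
  low <- wilcoxon_two_sample(c(1, 2), c(3, 4), alternative = "less")
  expect_true(low$exact)
  expect_equal(low$p_value, 1 / 6, tolerance = 1e-12)
  set.seed(411)
  pw <- wilcoxon_two_sample(rnorm(30), rnorm(30, 2))
  expect_lt(pw$p_value, 0.05)
  expect_error(wilcoxon_two_sample(numeric(0), 1:3), ">= 1")
})
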