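test_that("within-subject curves enumerate subsets exactly", {
  pr <- small_processed()
  wc <- within_subject_curve(pr, "ellipse", k_values = c(1, 3, 8))
  expect_identical(wc$n_subsets, as.integer(choose(8, c(1, 3, 8))))
  # k = 1: aggregating one trajectory is the identity, so the curve value
  # is the mean individual error
  E <- tracewoc:::individual_error_matrix(pr, "ellipse")
  expect_equal(wc$mean_error[1L], mean(E), tolerance = 1e-12)
  # k = 8: exactly one subset, the full self-aggregate
  full <- vapply(seq_len(nrow(E)), function(i) {
    trajs <- lapply(1:8, function(k) list(
      subject_id = "s", template_name = "ellipse", segment_index = k,
      aligned_points = pr$data$ellipse$P[, , i, k],
      bin_counts = pr$data$ellipse$counts[, i, k]))
    error_profile(aggregate_trajectories(trajs),
                  pr$templates$ellipse)$mean_error
  }, numeric(1))
  expect_equal(wc$mean_error[3L], mean(full), tolerance = 1e-12)
  expect_error(within_subject_curve(pr, "ellipse", k_values = 9), "exceeds")
})

test_that("between-subject curves are seeded, bounded and consistent at n = 1", {
  pr <- small_processed()
  E <- tracewoc:::individual_error_matrix(pr, "ellipse")
  bc <- between_subject_curve(pr, "ellipse", n_values = c(1, 4),
                              n_reps = 800, seed = 5)
  # n = 1 is the identity: Monte-Carlo mean within 3 SE of the exact mean
  se <- sd(E) / sqrt(800)
  expect_lt(abs(bc$mean_error[1L] - mean(E)), 3 * se + 1e-9)
  bc2 <- between_subject_curve(pr, "ellipse", n_values = c(1, 4),
                               n_reps = 800, seed = 5)
  expect_identical(bc$mean_error, bc2$mean_error)
  expect_error(between_subject_curve(pr, "ellipse", n_values = 1000,
                                     n_reps = 10), "exceeds")
})

test_that("between-subject mean aggregation matches the closed-form noise law", {
  # iid isotropic Gaussian per-bin noise: the error of the mean of n
  # trajectories is E||N2(0, (s^2/n) I)|| = s * sqrt(pi / (2 n))
  tpl <- segment_template("ellipse", n_ref = 40)
  s <- 2
  set.seed(31)
  pr <- manual_processed(tpl, n_sub = 150, n_seg = 4, function(i, k)
    matrix(rnorm(80, 0, s), ncol = 2))
  bc <- between_subject_curve(pr, "ellipse", n_values = c(2, 8, 32),
                              n_reps = 1200, seed = 9, method = "mean")
  expected <- s * sqrt(pi / (2 * c(2, 8, 32)))
  expect_equal(bc$mean_error, expected, tolerance = 0.05)
})

test_that("outperformance percentiles count individual trajectories", {
  tpl <- segment_template("ellipse", n_ref = 10)
  # crowd of identical on-template trajectories, individuals never exact:
  # the crowd dominates everyone
  set.seed(13)
  pr <- manual_processed(tpl, n_sub = 12, n_seg = 4, function(i, k)
    matrix(rnorm(20, 0, 1), ncol = 2))
  op <- outperformance_percentile(pr, "ellipse")
  oracle <- 100 * mean(tracewoc:::individual_error_matrix(pr, "ellipse") >
                         op$woc_error)
  expect_equal(op$percentile, oracle)
  expect_length(op$individual_errors, 12L * 4L)

  # degenerate extremes: crowd below the minimum / above the maximum
  pr_same <- manual_processed(tpl, n_sub = 6, n_seg = 2, function(i, k)
    matrix(c(rep(i, 10), rep(0, 10)), ncol = 2))  # subject-constant offsets
  opd <- outperformance_percentile(pr_same, "ellipse")
  expect_equal(opd$percentile,
               100 * mean(tracewoc:::individual_error_matrix(
                 pr_same, "ellipse") > opd$woc_error))
  pr_zero <- manual_processed(tpl, n_sub = 5, n_seg = 2, function(i, k)
    matrix(rnorm(20, 0, 0.5), ncol = 2))
  wt <- woc_trajectory(pr_zero, "ellipse")
  expect_true(wt$error$mean_error <
                min(tracewoc:::individual_error_matrix(pr_zero, "ellipse")))
  expect_equal(outperformance_percentile(pr_zero, "ellipse")$percentile, 100)
})

test_that("outperformance is invariant to rescaling all errors", {
  tpl <- segment_template("ellipse", n_ref = 10)
  set.seed(17)
  offs <- lapply(1:8, function(i) matrix(rnorm(20), ncol = 2))
  pr1 <- manual_processed(tpl, 8, 3, function(i, k) offs[[i]] * (k / 3))
  pr2 <- manual_processed(tpl, 8, 3, function(i, k) 7 * offs[[i]] * (k / 3))
  expect_equal(outperformance_percentile(pr1, "ellipse")$percentile,
               outperformance_percentile(pr2, "ellipse")$percentile)
})

test_that("age profiles average segments, subjects, then templates", {
  tpl <- segment_template("ellipse", n_ref = 10)
  # constant 2 mm displacement everywhere: every age maps to 2 mm
  ages <- c(6.2, 6.8, 9.1, 14.5, 14.9)
  pr <- manual_processed(tpl, 5, 3, function(i, k)
    cbind(rep(2, 10), 0), ages = ages)
  ap <- age_error_profile(pr, n_boot = 0)
  expect_equal(ap$age, c(6, 9, 14))
  expect_equal(ap$mean_error, rep(2, 3))
  expect_identical(ap$n_subjects, c(2L, 1L, 2L))
  # single-age cohort: one entry, the overall mean individual error
  pr1 <- manual_processed(tpl, 4, 2, function(i, k)
    matrix(rnorm(20), ncol = 2), ages = rep(8.3, 4))
  ap1 <- age_error_profile(pr1, n_boot = 0)
  expect_identical(nrow(ap1), 1L)
  expect_equal(ap1$mean_error,
               mean(tracewoc:::individual_error_matrix(pr1, "ellipse")))
})

test_that("generated cohorts show decreasing error with age", {
  pvals <- vapply(1:3, function(sd) {
    cfg <- synthetic_config(n_subjects = 60, templates = "ellipse",
                            outlier_fraction = 0, seed = 100 + sd)
    pr <- process_cohort(generate_cohort(cfg, templates = one_template()))
    ap <- age_error_profile(pr, n_boot = 0)
    ct <- suppressWarnings(cor.test(ap$age, ap$mean_error,
                                    method = "spearman",
                                    alternative = "less"))
    ct$p.value
  }, numeric(1))
  expect_true(all(pvals < 0.01))
})

test_that("group comparisons treat exchangeable groups symmetrically", {
  tpl <- segment_template("ellipse", n_ref = 10)
  set.seed(23)
  ages <- c(rep(8, 10), rep(14, 10))
  pr <- manual_processed(tpl, 20, 4, function(i, k)
    matrix(rnorm(20, 0, 1.5), ncol = 2), ages = ages)
  gc <- group_comparison(pr, "ellipse", n_boot = 200, seed = 3)
  # identical error structure: individual means agree within the CIs
  expect_gt(gc$individual_young["ci_high"], gc$individual_old["estimate"])
  expect_lt(gc$individual_young["ci_low"], gc$individual_old["estimate"])
  expect_identical(gc$n_young, 10L)
  expect_error(group_comparison(pr, "ellipse", age_threshold = 99),
               "empty age group")
})

test_that("diversity measures mean distance to the collective trajectory", {
  tpl <- segment_template("ellipse", n_ref = 10)
  # identical individuals: zero diversity
  pr0 <- manual_processed(tpl, 5, 2, function(i, k) cbind(rep(1, 10), 0))
  expect_equal(diversity_score(pr0, "ellipse"), 0)
  # symmetric pair at +/- d with mean aggregation: diversity d
  d <- 3
  pr2 <- manual_processed(tpl, 2, 1, function(i, k)
    cbind(rep(if (i == 1) d else -d, 10), 0), method = "mean")
  expect_equal(diversity_score(pr2, "ellipse", method = "mean"), d)
  # brute-force double loop on a random cohort
  set.seed(29)
  pr <- manual_processed(tpl, 7, 3, function(i, k)
    matrix(rnorm(20), ncol = 2))
  collective <- woc_trajectory(pr, "ellipse")$aggregate$aligned_points
  trajs <- list()
  for (i in 1:7) for (k in 1:3)
    trajs[[length(trajs) + 1L]] <- pr$data$ellipse$P[, , i, k]
  expect_equal(diversity_score(pr, "ellipse"),
               bf_diversity(trajs, collective), tolerance = 1e-12)
})

test_that("subject-level bootstrap intervals behave at the extremes", {
  cfg <- synthetic_config(n_subjects = 6, templates = "ellipse",
                          duration = 2, seed = 19)
  coh <- generate_cohort(cfg, templates = one_template())
  ci <- bootstrap_ci(function(ch) 42, coh, n_boot = 50, seed = 1)
  expect_equal(unname(ci), c(42, 42))
  stat <- function(ch) mean(ch$subjects$age)
  ci1 <- bootstrap_ci(stat, coh, n_boot = 100, seed = 7)
  ci2 <- bootstrap_ci(stat, coh, n_boot = 100, seed = 7)
  expect_identical(ci1, ci2)
  expect_lte(ci1["low"], ci1["high"])
  # resampling keeps all of a subject's trajectories together
  set.seed(3)
  res <- resample_subjects(coh)
  expect_identical(nrow(res$subjects), 6L)
  expect_true(all(vapply(res$traces, function(tr)
    tr$subject_id %in% res$subjects$subject_id, logical(1))))
})

test_that("bootstrap errors carry resample context", {
  cfg <- synthetic_config(n_subjects = 3, templates = "ellipse",
                          duration = 1, seed = 4)
  coh <- generate_cohort(cfg, templates = one_template())
  expect_error(bootstrap_ci(function(ch) stop("boom"), coh, n_boot = 5),
               "bootstrap resample 1")
})

test_that("the skill sweep spans perfect to random selection", {
  pr <- small_processed()
  E <- tracewoc:::individual_error_matrix(pr, "ellipse")
  skill <- rowMeans(E)
  sw <- skill_selection_sweep(pr, "ellipse",
                              noise_levels = c(0, 1, Inf), n_draws = 300,
                              seed = 2)
  expect_equal(sw$curve$expected_error[1L], min(skill))
  expect_equal(sw$curve$expected_error[3L], mean(skill))
  expect_true(all(diff(sw$curve$expected_error) > -1e-9))
  # crossover percentile equals a quantile scan of the sorted errors
  errs <- sort(as.vector(E))
  oracle <- 100 * sum(errs < sw$crowd_error) / length(errs)
  expect_equal(sw$crossover_percentile, oracle)
})
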