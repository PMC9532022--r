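# The wisdom-of-the-crowd analyses: within- vs between-subject aggregation
# curves, outperformance percentiles, age stratification, diversity,
# subject-level bootstrap confidence intervals and the skill-selection
# sweep. All functions operate on a `woc_processed` cohort.

template_data <- function(processed, template) {
  stopifnot(inherits(processed, "woc_processed"))
  td <- processed$data[[template]]
  if (is.null(td)) stop("no processed data for template '", template, "'")
  td
}

# Mean error of every individual trajectory: n_subjects x n_segments.
individual_error_matrix <- function(processed, template) {
  td <- template_data(processed, template)
  R <- processed$templates[[template]]$ref_points
  D <- sqrt((td$P[, 1L, , , drop = FALSE] - R[, 1L])^2 +
              (td$P[, 2L, , , drop = FALSE] - R[, 2L])^2)
  dim(D) <- dim(td$P)[c(1L, 3L, 4L)]
  apply(D, c(2L, 3L), mean, na.rm = TRUE)
}

# One individual trajectory per subject, flattened to (2 n_ref) x n_sub.
# segment: an index, or "random" (uses the current RNG state).
one_per_subject <- function(td, n_segments, segment = 1L) {
  n_sub <- dim(td$P)[3L]
  segs <- if (identical(segment, "random"))
    sample.int(n_segments, n_sub, replace = TRUE)
  else rep.int(as.integer(segment), n_sub)
  Pf <- flatten_trajectories(td)
  Pf[, (seq_len(n_sub) - 1L) * n_segments + segs, drop = FALSE]
}

#' Crowd trajectory and error for one template
#'
#' Builds the wisdom-of-the-crowd trajectory by taking one individual
#' trajectory from each subject (the first time slice by default) and
#' aggregating them, and scores it against the template.
#'
#' @param processed a `woc_processed` cohort.
#' @param template template name.
#' @param segment which time slice to take per subject: an index (default
#'   1) or `"random"`.
#' @param subjects optional character vector restricting the crowd to a
#'   subject subset.
#' @param method aggregation method; defaults to the cohort's.
#' @return list with `aggregate` (as [aggregate_trajectories()]) and
#'   `error` (as [error_profile()]).
#' @export
woc_trajectory <- function(processed, template, segment = 1L,
                           subjects = NULL, method = processed$method) {
  td <- template_data(processed, template)
  X <- one_per_subject(td, processed$n_segments, segment)
  if (!is.null(subjects)) {
    keep <- td$subject_ids %in% subjects
    if (!any(keep)) stop("no subjects left in the crowd")
    X <- X[, keep, drop = FALSE]
  }
  agg <- aggregate_trajectories(X, method = method)
  agg$template_name <- template
  list(aggregate = agg,
       error = error_profile(agg, processed$templates[[template]]))
}

#' Within-subject aggregation curve
#'
#' For each subset size `k`, enumerates all `choose(n_segments, k)` subsets
#' of each subject's individual trajectories, aggregates each subset and
#' scores it; the curve value is the average error over subsets within
#' subject, then over subjects. This is the "crowd within": because a
#' subject repeats their own systematic bias, the curve plateaus near the
#' bias-induced error floor instead of falling towards zero.
#'
#' @param processed a `woc_processed` cohort.
#' @param template template name.
#' @param k_values subset sizes (each <= `n_segments`).
#' @param n_boot bootstrap resamples (over subjects) for 95% confidence
#'   intervals; 0 to skip.
#' @param seed seed for the bootstrap.
#' @param method aggregation method; defaults to the cohort's.
#' @return data frame of class `woc_curve` with columns `n`, `mean_error`,
#'   `ci_low`, `ci_high`, `n_subsets`; attribute `source = "within"`.
#' @export
within_subject_curve <- function(processed, template,
                                 k_values = seq_len(processed$n_segments),
                                 n_boot = 0L, seed = 1L,
                                 method = processed$method) {
  td <- template_data(processed, template)
  R <- processed$templates[[template]]$ref_points
  n_seg <- processed$n_segments
  if (any(k_values > n_seg))
    stop("k exceeds the number of individual trajectories per subject")
  n_sub <- dim(td$P)[3L]
  per_subject <- matrix(NA_real_, n_sub, length(k_values))
  n_subsets <- integer(length(k_values))
  for (j in seq_along(k_values)) {
    k <- k_values[j]
    combs <- utils::combn(n_seg, k)
    n_subsets[j] <- ncol(combs)
    for (i in seq_len(n_sub)) {
      Ms <- td$P[, , i, , drop = FALSE]
      dim(Ms) <- c(nrow(R) * 2L, n_seg)
      errs <- vapply(seq_len(ncol(combs)), function(cc) {
        a <- stack_centre(Ms[, combs[, cc], drop = FALSE], method)
        mean(flat_bin_errors(a, R), na.rm = TRUE)
      }, numeric(1))
      per_subject[i, j] <- mean(errs)
    }
  }
  curve_with_ci(k_values, per_subject, n_subsets, "within", n_boot, seed)
}

#' Between-subject aggregation curve
#'
#' For each crowd size `n`, Monte-Carlo estimate of the expected error of
#' the aggregate of `n` trajectories from `n` distinct subjects: subjects
#' are drawn without replacement within a draw, one randomly chosen
#' individual trajectory per drawn subject, repeated `n_reps` times.
#'
#' @inheritParams within_subject_curve
#' @param n_values crowd sizes (each <= number of subjects).
#' @param n_reps Monte-Carlo draws per crowd size; default 10000.
#' @param n_boot subject-level bootstrap resamples for 95% confidence
#'   intervals (each re-running a reduced Monte Carlo); 0 to skip.
#' @return data frame of class `woc_curve` with `source = "between"`.
#' @export
between_subject_curve <- function(processed, template, n_values,
                                  n_reps = 10000L, seed = 1L, n_boot = 0L,
                                  method = processed$method) {
  td <- template_data(processed, template)
  R <- processed$templates[[template]]$ref_points
  n_seg <- processed$n_segments
  n_sub <- dim(td$P)[3L]
  if (any(n_values > n_sub)) stop("crowd size exceeds the number of subjects")
  Pf <- flatten_trajectories(td)
  set.seed(seed)
  mc_mean <- function(sub_pool, reps) {
    vapply(n_values, function(n) {
      errs <- vapply(seq_len(reps), function(r) {
        subs <- sub_pool[sample.int(length(sub_pool), n)]
        segs <- sample.int(n_seg, n, replace = TRUE)
        a <- stack_centre(Pf[, (subs - 1L) * n_seg + segs, drop = FALSE],
                          method)
        mean(flat_bin_errors(a, R), na.rm = TRUE)
      }, numeric(1))
      mean(errs)
    }, numeric(1))
  }
  est <- mc_mean(seq_len(n_sub), n_reps)
  ci_low <- ci_high <- rep(NA_real_, length(n_values))
  if (n_boot > 0L) {
    reps_b <- max(100L, ceiling(n_reps / 20))
    B <- vapply(seq_len(n_boot),
                function(b) mc_mean(sample.int(n_sub, n_sub, replace = TRUE),
                                    reps_b),
                numeric(length(n_values)))
    B <- matrix(B, nrow = length(n_values))
    ci_low <- apply(B, 1L, stats::quantile, probs = 0.025)
    ci_high <- apply(B, 1L, stats::quantile, probs = 0.975)
  }
  out <- data.frame(n = n_values, mean_error = est,
                    ci_low = pmin(ci_low, est, na.rm = FALSE),
                    ci_high = pmax(ci_high, est, na.rm = FALSE),
                    n_subsets = NA_integer_)
  attr(out, "source") <- "between"
  attr(out, "template") <- template
  class(out) <- c("woc_curve", "data.frame")
  out
}

curve_with_ci <- function(n_values, per_subject, n_subsets, source,
                          n_boot, seed) {
  est <- colMeans(per_subject)
  ci_low <- ci_high <- rep(NA_real_, length(n_values))
  if (n_boot > 0L) {
    set.seed(seed)
    n_sub <- nrow(per_subject)
    B <- vapply(seq_len(n_boot), function(b) {
      colMeans(per_subject[sample.int(n_sub, n_sub, replace = TRUE), ,
                           drop = FALSE])
    }, numeric(length(n_values)))
    B <- matrix(B, nrow = length(n_values))
    ci_low <- pmin(apply(B, 1L, stats::quantile, probs = 0.025), est)
    ci_high <- pmax(apply(B, 1L, stats::quantile, probs = 0.975), est)
  }
  out <- data.frame(n = n_values, mean_error = est, ci_low = ci_low,
                    ci_high = ci_high, n_subsets = n_subsets)
  attr(out, "source") <- source
  class(out) <- c("woc_curve", "data.frame")
  out
}

#' Fraction of individual trajectories outperformed by the crowd
#'
#' Compares the error of every individual trajectory with the error of the
#' crowd trajectory (one individual trajectory per subject, aggregated).
#'
#' @inheritParams woc_trajectory
#' @return list with `percentile` (percentage of individual trajectories
#'   whose error exceeds the crowd's, in \[0, 100\]), `woc_error`, and
#'   `individual_errors` (all per-trajectory mean errors, for histograms).
#' @export
outperformance_percentile <- function(processed, template, segment = 1L,
                                      method = processed$method) {
  errs <- as.vector(individual_error_matrix(processed, template))
  wt <- woc_trajectory(processed, template, segment = segment,
                       method = method)
  list(percentile = 100 * mean(errs > wt$error$mean_error),
       woc_error = wt$error$mean_error,
       individual_errors = errs)
}

#' Mean individual error by age
#'
#' For each integer age present in the cohort: the individual error
#' averaged over time slices within subject, over subjects of that age
#' within each template, and then (arithmetically) over templates.
#' Confidence intervals by subject-level bootstrap.
#'
#' @param processed a `woc_processed` cohort.
#' @param n_boot bootstrap resamples; 0 to skip.
#' @param seed bootstrap seed.
#' @return data frame with `age`, `mean_error`, `ci_low`, `ci_high`,
#'   `n_subjects`.
#' @export
age_error_profile <- function(processed, n_boot = 200L, seed = 1L) {
  if (all(is.na(processed$subjects$age))) stop("cohort has no ages")
  tnames <- names(processed$data)
  # per-subject, per-template mean error (over segments)
  per <- lapply(tnames, function(tn) {
    e <- rowMeans(individual_error_matrix(processed, tn))
    stats::setNames(e, template_data(processed, tn)$subject_ids)
  })
  ages <- stats::setNames(floor(processed$subjects$age),
                          processed$subjects$subject_id)
  age_mean <- function(ids_by_age) {
    vapply(ids_by_age, function(ids) {
      v <- vapply(per, function(e) mean(e[names(e) %in% ids], na.rm = TRUE),
                  numeric(1))
      mean(v, na.rm = TRUE)
    }, numeric(1))
  }
  ids_by_age <- split(names(ages), ages)
  est <- age_mean(ids_by_age)
  ci_low <- ci_high <- rep(NA_real_, length(est))
  if (n_boot > 0L) {
    set.seed(seed)
    B <- vapply(seq_len(n_boot), function(b) {
      res <- lapply(ids_by_age,
                    function(ids) ids[sample.int(length(ids),
                                                 length(ids),
                                                 replace = TRUE)])
      age_mean(res)
    }, numeric(length(est)))
    B <- matrix(B, nrow = length(est))
    ci_low <- pmin(apply(B, 1L, stats::quantile, 0.025, na.rm = TRUE), est)
    ci_high <- pmax(apply(B, 1L, stats::quantile, 0.975, na.rm = TRUE), est)
  }
  data.frame(age = as.numeric(names(ids_by_age)), mean_error = est,
             ci_low = ci_low, ci_high = ci_high,
             n_subjects = lengths(ids_by_age), row.names = NULL)
}

#' Age-stratified crowd comparison
#'
#' Splits subjects at `age_threshold` into low-skill (young) and
#' high-skill (old) groups and computes, per template: the mean individual
#' error of each group and the error of each group's own crowd trajectory
#' (one individual trajectory per subject, aggregated within the group).
#' The strong-crowd signature is `woc_young < individual_old`: a crowd of
#' young children beating the average older child.
#'
#' @inheritParams woc_trajectory
#' @param age_threshold years; default 10.5.
#' @param n_boot subject-level bootstrap resamples for 95% confidence
#'   intervals; default 500.
#' @param seed bootstrap seed.
#' @return list of class `woc_groups`: `individual_young`,
#'   `individual_old`, `woc_young`, `woc_old` (each a named vector
#'   `c(estimate, ci_low, ci_high)`), plus group sizes.
#' @export
group_comparison <- function(processed, template, age_threshold = 10.5,
                             n_boot = 500L, seed = 1L, segment = 1L,
                             method = processed$method) {
  td <- template_data(processed, template)
  R <- processed$templates[[template]]$ref_points
  ages <- processed$subjects$age[match(td$subject_ids,
                                       processed$subjects$subject_id)]
  young <- which(!is.na(ages) & ages < age_threshold)
  old <- which(!is.na(ages) & ages > age_threshold)
  if (!length(young) || !length(old))
    stop("empty age group at threshold ", age_threshold)
  E <- individual_error_matrix(processed, template)
  X <- one_per_subject(td, processed$n_segments, segment)
  stat_group <- function(idx) {
    c(indiv = mean(E[idx, ]),
      woc = mean(flat_bin_errors(stack_centre(X[, idx, drop = FALSE],
                                              method), R), na.rm = TRUE))
  }
  est_y <- stat_group(young)
  est_o <- stat_group(old)
  boot <- function(idx) {
    set.seed(seed)
    B <- vapply(seq_len(n_boot), function(b)
      stat_group(idx[sample.int(length(idx), length(idx), replace = TRUE)]),
      numeric(2))
    apply(B, 1L, stats::quantile, probs = c(0.025, 0.975))
  }
  ci_y <- ci_o <- matrix(NA_real_, 2L, 2L,
                         dimnames = list(NULL, c("indiv", "woc")))
  if (n_boot > 0L) { ci_y <- boot(young); ci_o <- boot(old) }
  pack <- function(est, ci, which)
    c(estimate = unname(est[which]),
      ci_low = min(ci[1L, which], est[which]),
      ci_high = max(ci[2L, which], est[which]))
  structure(list(template_name = template, age_threshold = age_threshold,
                 individual_young = pack(est_y, ci_y, "indiv"),
                 individual_old = pack(est_o, ci_o, "indiv"),
                 woc_young = pack(est_y, ci_y, "woc"),
                 woc_old = pack(est_o, ci_o, "woc"),
                 n_young = length(young), n_old = length(old)),
            class = "woc_groups")
}

#' @export
print.woc_groups <- function(x, ...) {
  cat("Age-stratified crowd comparison, template '", x$template_name,
      "' (threshold ", x$age_threshold, " y)\n", sep = "")
  f <- function(v) sprintf("%.3f mm [%.3f, %.3f]", v[1], v[2], v[3])
  cat("  individual young:", f(x$individual_young), " (n =", x$n_young, ")\n")
  cat("  individual old:  ", f(x$individual_old), " (n =", x$n_old, ")\n")
  cat("  crowd young:     ", f(x$woc_young), "\n")
  cat("  crowd old:       ", f(x$woc_old), "\n")
  invisible(x)
}

#' Trajectory diversity of a group
#'
#' Mean Euclidean distance of the group's individual trajectories to the
#' group's collective (crowd) trajectory: per individual trajectory the
#' per-bin distances are averaged, then averaged over trajectories. More
#' diverse groups converge to their average faster (diversity prediction
#' theorem), which is how a noisy young crowd catches up with an older one.
#'
#' @inheritParams woc_trajectory
#' @param subjects optional subject subset defining the group (default all).
#' @return mean distance in mm.
#' @export
diversity_score <- function(processed, template, subjects = NULL,
                            segment = 1L, method = processed$method) {
  td <- template_data(processed, template)
  keep <- if (is.null(subjects)) seq_along(td$subject_ids) else
    which(td$subject_ids %in% subjects)
  if (!length(keep)) stop("empty group")
  X <- one_per_subject(td, processed$n_segments, segment)[, keep,
                                                          drop = FALSE]
  collective <- stack_centre(X, method)
  n_seg <- processed$n_segments
  cols <- as.vector(outer(seq_len(n_seg), (keep - 1L) * n_seg, "+"))
  Pf <- flatten_trajectories(td)[, cols, drop = FALSE]
  n_ref <- nrow(td$P)
  D <- sqrt((Pf[seq_len(n_ref), , drop = FALSE] -
               collective[seq_len(n_ref)])^2 +
              (Pf[n_ref + seq_len(n_ref), , drop = FALSE] -
                 collective[n_ref + seq_len(n_ref)])^2)
  mean(colMeans(D, na.rm = TRUE), na.rm = TRUE)
}

#' Subject-level bootstrap confidence interval
#'
#' Creates "virtual experiments" by drawing subjects with replacement up
#' to the original cohort size (all of a subject's trajectories travel
#' together), recomputes the statistic on each, and returns the central
#' `level` empirical quantiles.
#'
#' @param statistic function mapping a cohort (of the same class as
#'   `cohort`) to a single number.
#' @param cohort a `woc_cohort` or `woc_processed` object.
#' @param n_boot number of virtual experiments; default 500.
#' @param level confidence level; default 0.95.
#' @param seed RNG seed.
#' @return named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(statistic, cohort, n_boot = 500L, level = 0.95,
                         seed = 1L) {
  set.seed(seed)
  vals <- vapply(seq_len(n_boot), function(b) {
    res <- tryCatch(statistic(resample_subjects(cohort)), error = function(e)
      stop("statistic failed on bootstrap resample ", b, ": ",
           conditionMessage(e), call. = FALSE))
    as.numeric(res)
  }, numeric(1))
  alpha <- (1 - level) / 2
  q <- stats::quantile(vals, probs = c(alpha, 1 - alpha), names = FALSE)
  c(low = q[1L], high = q[2L])
}

#' Resample a cohort's subjects with replacement
#'
#' One bootstrap "virtual experiment": subjects drawn with replacement up
#' to the original number of subjects; duplicated subjects get suffixed
#' identifiers so the result is again a valid cohort. Uses the current RNG
#' state.
#'
#' @param cohort a `woc_cohort` or `woc_processed` object.
#' @return an object of the same class.
#' @export
resample_subjects <- function(cohort) UseMethod("resample_subjects")

#' @export
resample_subjects.woc_cohort <- function(cohort) {
  n <- nrow(cohort$subjects)
  pick <- sample.int(n, n, replace = TRUE)
  subjects <- cohort$subjects[pick, , drop = FALSE]
  old_ids <- subjects$subject_id
  subjects$subject_id <- sprintf("%s.b%03d", old_ids, seq_len(n))
  traces <- list()
  for (i in seq_len(n)) {
    for (tr in cohort$traces) {
      if (tr$subject_id == old_ids[i]) {
        tr$subject_id <- subjects$subject_id[i]
        traces[[length(traces) + 1L]] <- tr
      }
    }
  }
  out <- trace_cohort(subjects, traces, cohort$templates)
  for (a in c("outlier", "config")) attr(out, a) <- attr(cohort, a)
  out
}

#' @export
resample_subjects.woc_processed <- function(cohort) {
  n <- nrow(cohort$subjects)
  pick <- sample.int(n, n, replace = TRUE)
  old_ids <- cohort$subjects$subject_id[pick]
  new_ids <- sprintf("%s.b%03d", old_ids, seq_len(n))
  subjects <- cohort$subjects[pick, , drop = FALSE]
  subjects$subject_id <- new_ids
  data <- lapply(cohort$data, function(td) {
    idx <- match(old_ids, td$subject_ids)
    ok <- !is.na(idx)
    list(P = td$P[, , idx[ok], , drop = FALSE],
         counts = td$counts[, idx[ok], , drop = FALSE],
         subject_ids = new_ids[ok])
  })
  out <- cohort
  out$subjects <- subjects
  out$data <- data
  out
}

#' Skill-selection sweep
#'
#' How good must a skill-selection criterion be for one selected individual
#' to beat the crowd? A selector observes each subject's true skill (their
#' mean individual error) corrupted by Gaussian noise of sd
#' `noise_level * sd(skill)` and picks the apparent best subject; with
#' zero noise it picks the truly best individual, with infinite noise a
#' random one. For each noise level the expected error of the selected
#' subject is estimated by Monte Carlo. The crossover percentile is the
#' point of the empirical individual-error distribution at which an
#' individual first beats the crowd: the percentage of individual
#' trajectories with error below the crowd error.
#'
#' @inheritParams woc_trajectory
#' @param noise_levels selector noise levels (multiples of the skill sd);
#'   `Inf` allowed.
#' @param n_draws Monte-Carlo draws per level; default 1000.
#' @param seed RNG seed.
#' @return list with `curve` (data frame `noise_level`,
#'   `expected_error`), `crowd_error` and `crossover_percentile`.
#' @export
skill_selection_sweep <- function(processed, template,
                                  noise_levels = c(0, 0.25, 0.5, 1, 2, 4,
                                                   Inf),
                                  n_draws = 1000L, seed = 1L, segment = 1L,
                                  method = processed$method) {
  E <- individual_error_matrix(processed, template)
  skill <- rowMeans(E)                 # per-subject true skill
  s <- stats::sd(skill)
  wt <- woc_trajectory(processed, template, segment = segment,
                       method = method)
  set.seed(seed)
  expected <- vapply(noise_levels, function(lam) {
    if (!is.finite(lam)) return(mean(skill))
    if (lam == 0) return(skill[which.min(skill)])
    sel <- vapply(seq_len(n_draws), function(d)
      skill[which.min(skill + stats::rnorm(length(skill), 0, lam * s))],
      numeric(1))
    mean(sel)
  }, numeric(1))
  errs <- as.vector(E)
  list(curve = data.frame(noise_level = noise_levels,
                          expected_error = expected),
       crowd_error = wt$error$mean_error,
       crossover_percentile = 100 * mean(errs < wt$error$mean_error))
}
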