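# The umbrella analysis: fit the full wisdom-of-the-crowd analysis to a
# tracing cohort and present it through the usual modelling methods.

#' Fit the wisdom-of-the-crowd analysis to a tracing cohort
#'
#' Runs the complete analysis on a cohort of traces: cleaning, splicing
#' into raw individual trajectories, nearest-reference-point subsampling,
#' and — per template — the mean individual error, the crowd trajectory and
#' its error, within- and between-subject aggregation curves, the
#' outperformance percentile, the age-stratified group comparison and the
#' group diversities, plus the pooled age profile.
#'
#' @param cohort a `woc_cohort` (raw traces) or a `woc_processed` cohort.
#' @param n_segments raw individual trajectories per trace; default 8.
#' @param method centre-of-mass method, `"median"` (default) or `"mean"`.
#' @param clean apply [clean_cohort()] first (raw cohorts only);
#'   default `TRUE`.
#' @param k_values within-subject subset sizes; default `1..n_segments`.
#' @param n_values between-subject crowd sizes; default powers of two up to
#'   the cohort size.
#' @param n_reps Monte-Carlo draws per between-subject crowd size.
#' @param n_boot bootstrap resamples for confidence intervals.
#' @param age_threshold years splitting low-/high-skill groups; default
#'   10.5.
#' @param seed master seed for all Monte-Carlo components.
#' @return an object of class `woc`; see [print.woc()], [summary.woc()],
#'   [plot.woc()].
#' @examples
#' cfg <- synthetic_config(n_subjects = 20, templates = "ellipse", seed = 7)
#' fit <- woc(generate_cohort(cfg), n_reps = 200, n_boot = 50)
#' fit
#' @export
woc <- function(cohort, n_segments = 8L, method = c("median", "mean"),
                clean = TRUE, k_values = seq_len(n_segments),
                n_values = NULL, n_reps = 1000L, n_boot = 200L,
                age_threshold = 10.5, seed = 1L) {
  method <- match.arg(method)
  cl <- match.call()
  report <- NULL
  if (inherits(cohort, "woc_processed")) {
    processed <- cohort
  } else {
    if (clean) {
      cleaned <- clean_cohort(cohort)
      cohort <- cleaned$cohort
      report <- cleaned$report
    }
    processed <- process_cohort(cohort, n_segments = n_segments,
                                method = method)
  }
  n_sub_min <- min(vapply(processed$data, function(td) dim(td$P)[3L],
                          integer(1)))
  n_values <- n_values %||% unique(pmin(2^(0:10), n_sub_min))
  have_age <- any(!is.na(processed$subjects$age))
  young_ids <- old_ids <- NULL
  if (have_age) {
    young_ids <- processed$subjects$subject_id[
      !is.na(processed$subjects$age) & processed$subjects$age < age_threshold]
    old_ids <- processed$subjects$subject_id[
      !is.na(processed$subjects$age) & processed$subjects$age > age_threshold]
  }
  per_template <- list()
  for (tn in names(processed$data)) {
    E <- individual_error_matrix(processed, tn)
    wt <- woc_trajectory(processed, tn)
    res <- list(
      mean_individual_error = mean(E),
      woc_error = wt$error$mean_error,
      woc_profile = wt$error,
      within = within_subject_curve(processed, tn, k_values = k_values,
                                    n_boot = n_boot,
                                    seed = derive_seed(seed, 1L)),
      between = between_subject_curve(processed, tn, n_values = n_values,
                                      n_reps = n_reps,
                                      seed = derive_seed(seed, 2L)),
      outperformance = outperformance_percentile(processed, tn))
    if (have_age && length(young_ids) && length(old_ids)) {
      res$groups <- group_comparison(processed, tn,
                                     age_threshold = age_threshold,
                                     n_boot = n_boot,
                                     seed = derive_seed(seed, 3L))
      res$diversity_young <- diversity_score(processed, tn,
                                             subjects = young_ids)
      res$diversity_old <- diversity_score(processed, tn,
                                           subjects = old_ids)
    }
    per_template[[tn]] <- res
  }
  age_profile <- if (have_age)
    age_error_profile(processed, n_boot = n_boot,
                      seed = derive_seed(seed, 4L)) else NULL
  structure(list(call = cl, per_template = per_template,
                 age_profile = age_profile, cleaning = report,
                 processed = processed, method = method,
                 n_segments = processed$n_segments,
                 age_threshold = age_threshold, seed = seed),
            class = "woc")
}

# Cross-template arithmetic means of the headline statistics.
woc_overall <- function(x) {
  g <- function(f) mean(vapply(x$per_template, f, numeric(1)))
  out <- list(mean_individual_error = g(function(p) p$mean_individual_error),
              woc_error = g(function(p) p$woc_error),
              outperformance = g(function(p) p$outperformance$percentile))
  if (!is.null(x$per_template[[1L]]$groups)) {
    out$individual_young <- g(function(p) p$groups$individual_young[1L])
    out$individual_old <- g(function(p) p$groups$individual_old[1L])
    out$woc_young <- g(function(p) p$groups$woc_young[1L])
    out$woc_old <- g(function(p) p$groups$woc_old[1L])
    out$diversity_young <- g(function(p) p$diversity_young)
    out$diversity_old <- g(function(p) p$diversity_old)
  }
  out
}

#' @export
print.woc <- function(x, ...) {
  cat("Wisdom-of-the-crowd trajectory analysis (", x$method,
      " aggregation, ", x$n_segments, " trajectories per subject)\n\n",
      sep = "")
  ov <- woc_overall(x)
  cat(sprintf("Templates: %s\n",
              paste(names(x$per_template), collapse = ", ")))
  cat(sprintf("Mean individual error: %.2f mm\n", ov$mean_individual_error))
  cat(sprintf("Crowd (WOC) error:     %.2f mm\n", ov$woc_error))
  cat(sprintf("Crowd outperforms %.1f%% of individual trajectories\n",
              ov$outperformance))
  invisible(x)
}

#' Summarise a wisdom-of-the-crowd analysis
#'
#' @param object a `woc` fit.
#' @param ... unused.
#' @return a list of class `summary.woc` with per-template and overall
#'   headline statistics.
#' @export
summary.woc <- function(object, ...) {
  tab <- do.call(rbind, lapply(names(object$per_template), function(tn) {
    p <- object$per_template[[tn]]
    data.frame(template = tn,
               individual_error = p$mean_individual_error,
               woc_error = p$woc_error,
               outperformance = p$outperformance$percentile,
               within_k_max = p$within$mean_error[nrow(p$within)],
               between_n_max = p$between$mean_error[nrow(p$between)])
  }))
  structure(list(table = tab, overall = woc_overall(object),
                 cleaning = object$cleaning,
                 age_threshold = object$age_threshold),
            class = "summary.woc")
}

#' @export
print.summary.woc <- function(x, ...) {
  cat("Per-template wisdom-of-the-crowd summary (errors in mm):\n")
  tab <- x$table
  tab[-1L] <- lapply(tab[-1L], round, 3L)
  print(tab, row.names = FALSE)
  ov <- x$overall
  cat(sprintf("\nAcross templates: individual %.2f mm -> crowd %.2f mm (%.1fx)\n",
              ov$mean_individual_error, ov$woc_error,
              ov$mean_individual_error / ov$woc_error))
  if (!is.null(ov$individual_young))
    cat(sprintf(paste0("Age groups (threshold %.1f y): individual young ",
                       "%.2f / old %.2f mm; crowd young %.2f / old %.2f mm\n"),
                x$age_threshold, ov$individual_young, ov$individual_old,
                ov$woc_young, ov$woc_old))
  if (!is.null(x$cleaning))
    cat(sprintf("Cleaning: %d of %d traces retained\n",
                x$cleaning$n_retained, x$cleaning$n_input))
  invisible(x)
}

#' Plot a wisdom-of-the-crowd analysis
#'
#' Base-graphics panels, one template at a time: (1) the template with the
#' crowd trajectory; (2) within- and between-subject aggregation curves on
#' log-log axes; (3) histogram of individual errors with the crowd error
#' marked; (4) the age profile of individual error.
#'
#' @param x a `woc` fit.
#' @param template template to plot; default the first.
#' @param which subset of `1:4`.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.woc <- function(x, template = names(x$per_template)[1L],
                     which = 1:4, ...) {
  p <- x$per_template[[template]]
  tpl <- x$processed$templates[[template]]
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    graphics::plot(tpl$points, type = "l", lty = 2, asp = 1,
                   xlab = "x (mm)", ylab = "y (mm)",
                   main = paste0("'", template, "' crowd trajectory"), ...)
    pts <- p$woc_profile
    agg <- woc_trajectory(x$processed, template)$aggregate$aligned_points
    graphics::lines(rbind(agg, agg[1L, ]), col = "red")
    graphics::points(tpl$ref_points, pch = 16, cex = 0.4)
  }
  if (2 %in% which) {
    rng <- range(p$within$mean_error, p$between$mean_error)
    graphics::plot(p$within$n, p$within$mean_error, type = "b", log = "xy",
                   ylim = rng, xlab = "trajectories aggregated",
                   ylab = "mean error (mm)", main = "aggregation curves",
                   col = "black", pch = 16, ...)
    graphics::lines(p$between$n, p$between$mean_error, type = "b",
                    col = "red", pch = 16)
    graphics::legend("bottomleft", c("within subject", "between subjects"),
                     col = c("black", "red"), lty = 1, bty = "n")
  }
  if (3 %in% which) {
    graphics::hist(p$outperformance$individual_errors, breaks = 30,
                   xlab = "individual error (mm)", main = "crowd vs individuals",
                   ...)
    graphics::abline(v = p$outperformance$woc_error, col = "red", lwd = 2)
  }
  if (4 %in% which && !is.null(x$age_profile)) {
    ap <- x$age_profile
    graphics::plot(ap$age, ap$mean_error, type = "b", pch = 16,
                   xlab = "age (years)", ylab = "mean individual error (mm)",
                   main = "error by age", ...)
    ok <- !is.na(ap$ci_low) & ap$ci_high > ap$ci_low
    if (any(ok))
      graphics::arrows(ap$age[ok], ap$ci_low[ok], ap$age[ok],
                       ap$ci_high[ok], angle = 90, code = 3, length = 0.02)
  }
  invisible(x)
}

#' Count violations of the convexity (Jensen) bound
#'
#' With mean aggregation the crowd's per-bin error can never exceed the
#' per-bin average of the individual errors (triangle inequality /
#' convexity of the norm); this holds exactly at every bin with full
#' coverage and is a useful pipeline self-check.
#'
#' @param processed a `woc_processed` cohort.
#' @param tol numerical slack; default `1e-9`.
#' @return integer count of violating bins across templates.
#' @export
jensen_bound_violations <- function(processed, tol = 1e-9) {
  total <- 0L
  for (tn in names(processed$data)) {
    td <- processed$data[[tn]]
    tpl <- processed$templates[[tn]]
    X <- one_per_subject(td, processed$n_segments, 1L)
    agg_err <- flat_bin_errors(row_means_na(X), tpl$ref_points)
    n_ref <- nrow(tpl$ref_points)
    D <- sqrt((X[seq_len(n_ref), , drop = FALSE] - tpl$ref_points[, 1L])^2 +
                (X[n_ref + seq_len(n_ref), , drop = FALSE] -
                   tpl$ref_points[, 2L])^2)
    indiv_err <- row_means_na(D)
    full <- rowSums(is.na(X)) == 0L
    total <- total + sum(agg_err[full] > indiv_err[full] + tol, na.rm = TRUE)
  }
  total
}

#' Run the full pipeline as one reproducible job
#'
#' Simulate (or load) a cohort, clean it, process it, fit the
#' wisdom-of-the-crowd analysis and write a machine-readable summary plus
#' tables. A stored configuration and seed reproduce every number.
#'
#' @param config a named list (or a YAML file path, read with the `yaml`
#'   package) with optional entries: `synthetic` (arguments to
#'   [synthetic_config()]) or `input_dir` (a cohort directory for
#'   [load_cohort()]); `cleaning` (arguments to [clean_cohort()]);
#'   `n_segments`; `method`; `analysis` (`k_values`, `n_values`, `n_reps`,
#'   `n_boot`, `age_threshold`); `seed`.
#' @param out_dir optional output directory; if given, writes
#'   `summary.json`, `curves.csv`, `errors.csv` and `age_profile.csv`.
#' @return the summary list, invisibly; component `fit` carries the `woc`
#'   object.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package")
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    stages[[name]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }
  cohort <- if (!is.null(config$input_dir)) load_cohort(config$input_dir)
  else generate_cohort(do.call(synthetic_config,
                               c(config$synthetic,
                                 if (is.null(config$synthetic$seed))
                                   list(seed = seed))))
  tick("cohort")
  cleaned <- do.call(clean_cohort, c(list(cohort), config$cleaning))
  tick("clean")
  processed <- process_cohort(cleaned$cohort,
                              n_segments = config$n_segments %||% 8L,
                              method = config$method %||% "median")
  tick("process")
  an <- config$analysis %||% list()
  fit <- woc(processed,
             k_values = an$k_values %||% seq_len(processed$n_segments),
             n_values = an$n_values,
             n_reps = an$n_reps %||% 1000L,
             n_boot = an$n_boot %||% 200L,
             age_threshold = an$age_threshold %||% 10.5,
             seed = seed)
  fit$cleaning <- cleaned$report
  tick("analyse")
  smry <- summary(fit)
  summary_list <- list(
    seed = seed,
    n_subjects = nrow(processed$subjects),
    cleaning = cleaned$report[c("n_input", "removed_short",
                                "removed_low_std", "removed_jump",
                                "n_retained")],
    per_template = lapply(fit$per_template, function(p) list(
      mean_individual_error = p$mean_individual_error,
      woc_error = p$woc_error,
      outperformance_percentile = p$outperformance$percentile)),
    overall = woc_overall(fit),
    jensen_bound_violations = jensen_bound_violations(processed),
    stage_seconds = stages)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    curves <- do.call(rbind, lapply(names(fit$per_template), function(tn) {
      p <- fit$per_template[[tn]]
      rbind(cbind(template = tn, source = "within",
                  as.data.frame(p$within)),
            cbind(template = tn, source = "between",
                  as.data.frame(p$between)))
    }))
    utils::write.csv(curves, file.path(out_dir, "curves.csv"),
                     row.names = FALSE)
    utils::write.csv(smry$table, file.path(out_dir, "errors.csv"),
                     row.names = FALSE)
    if (!is.null(fit$age_profile))
      utils::write.csv(fit$age_profile,
                       file.path(out_dir, "age_profile.csv"),
                       row.names = FALSE)
  }
  summary_list$fit <- fit
  invisible(summary_list)
}
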