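# Brute-force oracles and shared fixtures. The oracles are deliberately
# naive (explicit loops, direct formulas) and independent of the package
# internals they check.

# Nearest reference point per point, exhaustive all-pairs scan.
bf_nearest <- function(points, refs) {
  out <- integer(nrow(points))
  for (i in seq_len(nrow(points))) {
    d <- rep(NA_real_, nrow(refs))
    for (j in seq_len(nrow(refs)))
      d[j] <- sqrt(sum((points[i, ] - refs[j, ])^2))
    out[i] <- which.min(d)  # which.min takes the first minimum: low index
  }
  out
}

# Per-bin coordinate-wise medians by explicit group-by.
bf_bin_centres <- function(points, bins, n_ref, fun = stats::median) {
  out <- matrix(NA_real_, n_ref, 2L)
  for (b in seq_len(n_ref)) {
    sel <- bins == b
    if (any(sel))
      out[b, ] <- c(fun(points[sel, 1L]), fun(points[sel, 2L]))
  }
  out
}

# Cumulative arc length of a polyline by a plain loop.
bf_arclength <- function(pts) {
  s <- numeric(nrow(pts))
  for (i in 2:nrow(pts))
    s[i] <- s[i - 1L] + sqrt(sum((pts[i, ] - pts[i - 1L, ])^2))
  s
}

# Per-bin Euclidean distances and mean error.
bf_errors <- function(pts, refs) {
  d <- rep(NA_real_, nrow(refs))
  for (i in seq_len(nrow(refs)))
    d[i] <- sqrt(sum((pts[i, ] - refs[i, ])^2))
  list(per_bin = d, mean = mean(d, na.rm = TRUE))
}

# Diversity by a double loop over trajectories and bins.
bf_diversity <- function(traj_list, collective) {
  means <- numeric(length(traj_list))
  for (i in seq_along(traj_list)) {
    pts <- traj_list[[i]]
    d <- numeric(0)
    for (b in seq_len(nrow(pts)))
      if (!is.na(pts[b, 1L]) && !is.na(collective[b, 1L]))
        d <- c(d, sqrt(sum((pts[b, ] - collective[b, ])^2)))
    means[i] <- mean(d)
  }
  mean(means)
}

# Point-in-convex-polygon (hull vertices in order), with tolerance.
in_convex_hull <- function(p, hull, tol = 1e-9) {
  n <- nrow(hull)
  s <- numeric(n)
  for (i in seq_len(n)) {
    a <- hull[i, ]; b <- hull[i %% n + 1L, ]
    s[i] <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  }
  all(s >= -tol) || all(s <= tol)
}

# ---- shared fixtures ---------------------------------------------------

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- maker()
  .fixtures[[key]]
}

five_templates <- function() cached("tpl5", function() default_templates())
one_template <- function() cached("tpl1", function() default_templates("ellipse"))

# Fully processed default synthetic cohort (the study conditions) per seed.
default_processed <- function(seed) {
  cached(paste0("def", seed), function() {
    cfg <- synthetic_config(seed = seed)
    cleaned <- clean_cohort(generate_cohort(cfg, templates = five_templates()))
    process_cohort(cleaned$cohort)
  })
}

# A small single-template processed cohort for cheap unit tests.
small_processed <- function() {
  cached("small", function() {
    cfg <- synthetic_config(n_subjects = 20, templates = "ellipse", seed = 42)
    process_cohort(clean_cohort(generate_cohort(
      cfg, templates = one_template()))$cohort)
  })
}

# Hand-built processed object: aligned points = reference points + given
# per-trajectory offsets. offsets: array (n_sub, n_seg, 2) of constant
# displacement, or a function(i, k) returning an n_ref x 2 matrix.
manual_processed <- function(template, n_sub, n_seg, offset_fun,
                             ages = NULL, method = "median") {
  n_ref <- nrow(template$ref_points)
  P <- array(NA_real_, c(n_ref, 2L, n_sub, n_seg))
  counts <- array(1L, c(n_ref, n_sub, n_seg))
  for (i in seq_len(n_sub)) for (k in seq_len(n_seg))
    P[, , i, k] <- template$ref_points + offset_fun(i, k)
  ids <- sprintf("M%03d", seq_len(n_sub))
  subjects <- data.frame(subject_id = ids,
                         age = ages %||% rep(NA_real_, n_sub),
                         handedness = "right", gender = "unknown")
  tl <- list(template); names(tl) <- template$name
  structure(list(data = stats::setNames(
    list(list(P = P, counts = counts, subject_ids = ids)), template$name),
    subjects = subjects, templates = tl,
    n_segments = as.integer(n_seg), method = method),
    class = "woc_processed")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal raw-trajectory wrapper for subsample_individual().
raw_traj <- function(xy, subject = "s1", template = "ellipse", segment = 1L) {
  list(subject_id = subject, template_name = template,
       segment_index = segment, xy = xy)
}
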