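# Splicing of full 30 s traces into raw individual trajectories and
# nearest-reference-point subsampling into individual trajectories with one
# point per template reference point.

#' Splice a trace into raw individual trajectories of equal duration
#'
#' A subject traces the closed template several times within one 30 s
#' trial; single passes cannot be delimited reliably for inaccurate traces,
#' so each trace is divided into `n_segments` slices of equal wall-clock
#' duration and each slice is treated as one raw individual trajectory.
#' Sample `i` goes to slice `floor(n_segments * (t_i - t_0) / duration)`,
#' with the final sample assigned to the last slice.
#'
#' @param trace a [trace_record()].
#' @param n_segments number of equal-duration slices; default 8 (5 and 12
#'   are the usual robustness alternatives).
#' @return list of `n_segments` lists, each with `t`, `xy` and
#'   `segment_index`, in temporal order.
#' @export
splice_trace <- function(trace, n_segments = 8L) {
  stopifnot(inherits(trace, "woc_trace"), n_segments >= 1L)
  if (trace$duration <= 0) stop("trace duration must be positive")
  idx <- pmin(floor(n_segments * (trace$t - trace$t[1L]) / trace$duration) + 1L,
              n_segments)
  counts <- tabulate(idx, nbins = n_segments)
  if (any(counts == 0L))
    stop("n_segments = ", n_segments, " leaves empty time slice(s); ",
         "the trace has only ", length(trace$t), " samples")
  lapply(seq_len(n_segments), function(k) {
    sel <- idx == k
    list(subject_id = trace$subject_id, template_name = trace$template_name,
         segment_index = k, t = trace$t[sel],
         xy = trace$xy[sel, , drop = FALSE])
  })
}

#' Assign points to the nearest template reference point
#'
#' Each point is labelled with the index of the Euclidean-nearest reference
#' point; exact ties break toward the lowest index.
#'
#' @param points two-column matrix of mm coordinates.
#' @param template a complete `woc_template`.
#' @return integer vector of bin labels in `1..n_ref`.
#' @export
assign_bins <- function(points, template) {
  if (is.null(template$ref_points))
    stop("template has no reference points")
  points <- as.matrix(points)
  R <- template$ref_points
  d2 <- outer(rowSums(points^2), rep.int(1, nrow(R))) -
    2 * points %*% t(R) +
    outer(rep.int(1, nrow(points)), rowSums(R^2))
  max.col(-d2, ties.method = "first")
}

#' Subsample a raw individual trajectory onto the reference points
#'
#' Per reference bin, the aligned point is the median (or mean) centre of
#' mass of the raw points assigned to that bin; bins receiving no points
#' are missing (`NA`), never interpolated.
#'
#' @param raw one element of [splice_trace()]'s output (any list with an
#'   `xy` matrix).
#' @param template a complete `woc_template`.
#' @param method `"median"` (default) or `"mean"`.
#' @param bins optional precomputed [assign_bins()] labels for `raw$xy`.
#' @return list with `aligned_points` (`n_ref` x 2, `NA` rows for empty
#'   bins), `bin_counts`, and the identifying fields of `raw`.
#' @export
subsample_individual <- function(raw, template,
                                 method = c("median", "mean"), bins = NULL) {
  method <- match.arg(method)
  pts <- raw$xy
  if (NROW(pts) == 0L) stop("raw trajectory is empty")
  if (is.null(bins)) bins <- assign_bins(pts, template)
  n_ref <- nrow(template$ref_points)
  counts <- tabulate(bins, nbins = n_ref)
  aligned <- matrix(NA_real_, n_ref, 2L)
  occupied <- which(counts > 0L)
  agg <- if (method == "median") grouped_medians else grouped_means
  aligned[occupied, ] <- agg(pts, bins, counts, occupied)
  if (all(counts == 0L)) warning("all bins empty after subsampling")
  list(subject_id = raw$subject_id, template_name = raw$template_name,
       segment_index = raw$segment_index, aligned_points = aligned,
       bin_counts = counts)
}

# Coordinate-wise medians of pts grouped by bin label, for the occupied
# bins, via one order() per coordinate (no per-group loop).
grouped_medians <- function(pts, bins, counts, occupied) {
  cnt <- counts[occupied]
  ends <- cumsum(cnt)
  starts <- ends - cnt + 1L
  lo <- starts + (cnt - 1L) %/% 2L
  hi <- starts + cnt %/% 2L
  out <- matrix(NA_real_, length(occupied), 2L)
  for (j in 1:2) {
    sorted <- pts[order(bins, pts[, j]), j]
    out[, j] <- (sorted[lo] + sorted[hi]) / 2
  }
  out
}

grouped_means <- function(pts, bins, counts, occupied) {
  sums <- rowsum(pts, bins)
  sums / counts[occupied]
}

#' Process a cleaned cohort into aligned individual trajectories
#'
#' Runs [splice_trace()] and [subsample_individual()] over every trace and
#' packs the results into per-template arrays ready for aggregation and
#' analysis.
#'
#' @param cohort a cleaned `woc_cohort`.
#' @param n_segments raw individual trajectories per trace; default 8.
#' @param method per-bin centre of mass, `"median"` (default) or `"mean"`.
#' @return an object of class `woc_processed`: per template, an array `P`
#'   of dimension `(n_ref, 2, n_subjects, n_segments)` of aligned points
#'   (`NA` where a bin is empty), a matching `counts` array, and the
#'   ordered `subject_ids`; plus the subject table, the template registry,
#'   `n_segments` and `method`.
#' @export
process_cohort <- function(cohort, n_segments = 8L,
                           method = c("median", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "woc_cohort"))
  data <- list()
  for (tpl_name in names(cohort$templates)) {
    tpl <- cohort$templates[[tpl_name]]
    sel <- vapply(cohort$traces, function(tr) tr$template_name == tpl_name,
                  logical(1))
    traces <- cohort$traces[sel]
    if (!length(traces)) next
    subject_ids <- vapply(traces, `[[`, character(1), "subject_id")
    n_sub <- length(traces)
    n_ref <- nrow(tpl$ref_points)
    P <- array(NA_real_, c(n_ref, 2L, n_sub, n_segments))
    counts <- array(0L, c(n_ref, n_sub, n_segments))
    for (i in seq_len(n_sub)) {
      tr <- traces[[i]]
      bins <- assign_bins(tr$xy, tpl)  # bin labels are segment-independent
      segs <- splice_trace(tr, n_segments)
      for (k in seq_len(n_segments)) {
        seg <- segs[[k]]
        sel_k <- bins[match(seg$t, tr$t)]
        ind <- subsample_individual(seg, tpl, method = method, bins = sel_k)
        P[, , i, k] <- ind$aligned_points
        counts[, i, k] <- ind$bin_counts
      }
    }
    data[[tpl_name]] <- list(P = P, counts = counts,
                             subject_ids = unname(subject_ids))
  }
  structure(list(data = data, subjects = cohort$subjects,
                 templates = cohort$templates,
                 n_segments = as.integer(n_segments), method = method),
            class = "woc_processed")
}

#' @export
print.woc_processed <- function(x, ...) {
  cat("Processed tracing cohort (", x$method, " centres of mass, ",
      x$n_segments, " segments per trace)\n", sep = "")
  for (nm in names(x$data))
    cat(sprintf("  %-12s %4d subjects x %d trajectories, %d reference points\n",
                nm, dim(x$data[[nm]]$P)[3L], x$n_segments,
                dim(x$data[[nm]]$P)[1L]))
  invisible(x)
}

# Flatten a template's array to (2 n_ref) x (n_sub * n_seg), column index
# (subject - 1) * n_segments + segment.
flatten_trajectories <- function(td) {
  d <- dim(td$P)
  Pf <- aperm(td$P, c(1L, 2L, 4L, 3L))
  dim(Pf) <- c(d[1L] * 2L, d[4L] * d[3L])
  Pf
}
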