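# Aggregation of individual trajectories into a crowd (wisdom-of-the-crowd)
# trajectory, and Euclidean error profiles against the template.

#' Aggregate individual trajectories
#'
#' Per reference bin, the aggregate point is the coordinate-wise median (or
#' mean) over the non-missing aligned points of the inputs; a bin is
#' missing only if it is missing in every input.
#'
#' @param trajs list of individual trajectories (as produced by
#'   [subsample_individual()]), all for the same template; alternatively a
#'   `(n_ref, 2, k)` array or a `(2 n_ref) x k` matrix of flattened
#'   trajectories.
#' @param method `"median"` (default) or `"mean"`.
#' @return list with `aligned_points` (`n_ref` x 2), `n_contributing`
#'   (non-missing inputs per bin), `method` and, when available,
#'   `template_name`.
#' @export
aggregate_trajectories <- function(trajs, method = c("median", "mean")) {
  method <- match.arg(method)
  template_name <- NULL
  if (is.list(trajs) && length(trajs) == 0L)
    stop("no trajectories to aggregate")
  if (is.list(trajs) && !is.null(trajs[[1L]]$aligned_points)) {
    tn <- unique(vapply(trajs, `[[`, character(1), "template_name"))
    if (length(tn) > 1L)
      stop("cannot aggregate trajectories from different templates: ",
           paste(tn, collapse = ", "))
    template_name <- tn
    X <- vapply(trajs, function(tr) as.vector(tr$aligned_points),
                numeric(2L * nrow(trajs[[1L]]$aligned_points)))
    if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  } else if (is.array(trajs) && length(dim(trajs)) == 3L) {
    X <- trajs
    dim(X) <- c(dim(trajs)[1L] * 2L, dim(trajs)[3L])
  } else {
    X <- as.matrix(trajs)
  }
  if (ncol(X) == 0L) stop("no trajectories to aggregate")
  agg <- stack_centre(X, method)
  n_ref <- length(agg) / 2L
  contributing <- matrix(rowSums(!is.na(X)), n_ref, 2L)[, 1L]
  pts <- matrix(agg, n_ref, 2L)
  pts[contributing == 0L, ] <- NA_real_
  list(template_name = template_name, aligned_points = pts,
       n_contributing = as.integer(contributing), method = method)
}

#' Euclidean error profile of a trajectory against its template
#'
#' Per-bin Euclidean distance between the trajectory's aligned points and
#' the template reference points, plus the total error (arithmetic mean of
#' the non-missing per-bin distances) and the coverage (fraction of bins
#' with a defined point).
#'
#' @param traj an individual or aggregate trajectory (anything with an
#'   `aligned_points` matrix), or a bare `n_ref` x 2 matrix.
#' @param template the matching complete `woc_template`.
#' @return list with `per_bin_error`, `mean_error`, `coverage` and
#'   `template_name`.
#' @export
error_profile <- function(traj, template) {
  pts <- if (is.matrix(traj)) traj else traj$aligned_points
  R <- template$ref_points
  if (nrow(pts) != nrow(R))
    stop("trajectory length ", nrow(pts), " does not match the template's ",
         nrow(R), " reference points")
  d <- sqrt(rowSums((pts - R)^2))
  ok <- !is.na(d)
  if (!any(ok)) stop("no non-missing bins: error undefined")
  list(template_name = template$name, per_bin_error = d,
       mean_error = mean(d[ok]), coverage = mean(ok))
}

#' Per-region error maps
#'
#' Regional views of where on the template the crowd improves on
#' individuals: the per-bin mean of the individual error profiles, the
#' per-bin error of the aggregate trajectory, or their difference
#' (improvement).
#'
#' @param trajs non-empty list of individual trajectories for one template.
#' @param template the complete `woc_template`.
#' @param mode `"individual-average"`, `"aggregate"` or `"improvement"`.
#' @param method aggregation method for the crowd trajectory.
#' @return numeric vector of length `n_ref`.
#' @export
regional_error_map <- function(trajs, template,
                               mode = c("individual-average", "aggregate",
                                        "improvement"),
                               method = c("median", "mean")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (!length(trajs)) stop("empty trajectory list")
  indiv <- function() {
    E <- vapply(trajs,
                function(tr) error_profile(tr, template)$per_bin_error,
                numeric(nrow(template$ref_points)))
    if (is.null(dim(E))) E <- matrix(E, ncol = 1L)
    row_means_na(E)
  }
  aggr <- function() {
    agg <- aggregate_trajectories(trajs, method = method)
    error_profile(agg, template)$per_bin_error
  }
  switch(mode,
         `individual-average` = indiv(),
         aggregate = aggr(),
         improvement = indiv() - aggr())
}
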