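# Closed template curves: analytic families, arc-length segmentation and
# per-segment reference points (median centres of mass).
#
# Coordinates are millimetres in the native touch convention: origin at the
# screen's top-left corner, y increasing downward. Every statistic computed
# downstream is invariant to translation and reflection, so the convention
# only matters for plotting. The drawing area of the tablets the package
# models is 216 x 135 mm.

SCREEN_MM <- c(216, 135)
SCREEN_PX <- c(1920, 1200)

#' Construct a closed template curve
#'
#' Builds the dense polyline of one of the five analytic template families
#' used in the tracing task (an ellipse, a thinner ellipse of larger
#' eccentricity, three- and four-petal rose curves, and a lemniscate), or
#' wraps a user-supplied polyline (`name = "custom"`). The returned template
#' has no segmentation yet; see [segment_template()] for the full
#' constructor including reference points.
#'
#' The analytic families are parameterised as
#' ellipse `(a cos t, b sin t)` with semi-axes `size/2`;
#' rose curves `r(t) = r0 + r1 cos(k t)` with `k = 3` or `4`; and the
#' lemniscate of Bernoulli `(a cos t, a sin t cos t) / (1 + sin^2 t)`.
#' All curves are centred in the drawing area and traversed once, with the
#' first dense point repeated at the end so the polyline closes exactly.
#'
#' @param name one of `"ellipse"`, `"thin_ellipse"`, `"three_petal"`,
#'   `"four_petal"`, `"lemniscate"` or `"custom"`.
#' @param size numeric length-2 bounding box (width, height) in mm. Defaults
#'   per family: ellipse 110 x 70, thin ellipse 120 x 40, petals 110 x 110,
#'   lemniscate 110 mm wide. Must fit the 216 x 135 mm drawing area.
#' @param n_dense number of distinct dense points (>= 500 for analytic
#'   families).
#' @param points for `name = "custom"`, a two-column matrix or data frame of
#'   dense points in mm tracing the closed curve once (closure implied; the
#'   closing point is appended if absent).
#' @param centre centre of the curve in mm; default is the screen centre.
#' @return an object of class `woc_template` (unsegmented): a list with
#'   `name`, `points` (closed dense polyline, last row equals the first),
#'   `n_dense` (distinct points) and `centre`.
#' @seealso [segment_template()], [segment_by_arclength()],
#'   [compute_reference_points()], [read_template_csv()]
#' @examples
#' tpl <- make_template("ellipse", size = c(100, 100), n_dense = 1000)
#' tpl <- compute_reference_points(segment_by_arclength(tpl, 50))
#' @export
make_template <- function(name, size = NULL, n_dense = 1000, points = NULL,
                          centre = SCREEN_MM / 2) {
  name <- match.arg(name, c("ellipse", "thin_ellipse", "three_petal",
                            "four_petal", "lemniscate", "custom"))
  if (name == "custom") {
    if (is.null(points)) stop("'points' must be supplied for a custom template")
    pts <- as.matrix(points)
    storage.mode(pts) <- "double"
    if (ncol(pts) != 2L || nrow(pts) < 3L)
      stop("custom template points must be an n x 2 matrix with n >= 3")
    if (sqrt(sum((pts[1L, ] - pts[nrow(pts), ])^2)) > 1e-6)
      pts <- rbind(pts, pts[1L, ])  # closure implied by the file format
    return(new_template(name, pts, centre = colMeans(pts[-nrow(pts), , drop = FALSE])))
  }
  size <- size %||% switch(name,
    ellipse      = c(110, 70),
    thin_ellipse = c(120, 40),
    three_petal  = c(110, 110),
    four_petal   = c(110, 110),
    lemniscate   = c(110, 110 * lemniscate_aspect()))
  if (length(size) == 1L) size <- c(size, size)
  if (any(size <= 0)) stop("degenerate size: width and height must be positive")
  if (any(size > SCREEN_MM))
    stop("template size exceeds the 216 x 135 mm drawing area")
  if (n_dense < 500) stop("n_dense must be at least 500 for analytic templates")
  th <- seq(0, 2 * pi, length.out = n_dense + 1L)  # closing point included
  xy <- switch(name,
    ellipse      = ,
    thin_ellipse = cbind(size[1] / 2 * cos(th), size[2] / 2 * sin(th)),
    three_petal  = rose_curve(th, 3L, size),
    four_petal   = rose_curve(th, 4L, size),
    lemniscate   = lemniscate_curve(th, size[1] / 2))
  xy <- sweep(xy, 2L, centre, "+")
  xy[nrow(xy), ] <- xy[1L, ]  # exact closure against rounding
  new_template(name, xy, centre = centre)
}

# Polar rose r = r0 + r1 cos(k t), scaled so the bounding width matches
# size[1]; r0/r1 ratio fixed at 35/20, the default petal geometry.
rose_curve <- function(th, k, size) {
  r0 <- 35; r1 <- 20
  s <- size[1] / (2 * (r0 + r1))
  r <- s * (r0 + r1 * cos(k * th))
  cbind(r * cos(th), r * sin(th) * size[2] / size[1])
}

# Lemniscate of Bernoulli with half-width a; height/width aspect of the
# analytic form (max |y| = a / (2 sqrt(2))).
lemniscate_curve <- function(th, a) {
  d <- 1 + sin(th)^2
  cbind(a * cos(th) / d, a * sin(th) * cos(th) / d)
}

lemniscate_aspect <- function() 1 / (2 * sqrt(2)) * 2  # height / width

new_template <- function(name, points, centre) {
  structure(list(name = name, points = points,
                 n_dense = nrow(points) - 1L, centre = centre),
            class = "woc_template")
}

#' Divide a closed polyline into equal-arc-length segments
#'
#' Computes cumulative arc length along the dense polyline, places segment
#' boundaries at `k * L / n_segments` for total length `L`, and labels each
#' dense point with the half-open arc interval `[start, end)` containing it.
#' Repeated identical consecutive points (zero-length edges) are dropped
#' with a warning before segmentation.
#'
#' @param template a `woc_template` (or a bare two-column matrix, in which
#'   case the segmentation pieces are returned as a list).
#' @param n_segments number of equal-length segments (>= 1).
#' @return the template with fields `n_ref`, `total_length`, `boundaries`
#'   (length `n_segments + 1`), `arc` (cumulative arc length per dense
#'   point, closing point included) and `seg_labels` (segment index per
#'   distinct dense point).
#' @export
segment_by_arclength <- function(template, n_segments) {
  bare <- !inherits(template, "woc_template")
  pts <- if (bare) {
    p <- as.matrix(template)
    if (sqrt(sum((p[1L, ] - p[nrow(p), ])^2)) > 1e-6) p <- rbind(p, p[1L, ])
    p
  } else template$points
  if (n_segments < 1L) stop("n_segments must be at least 1")
  edge <- sqrt(rowSums((pts[-1L, , drop = FALSE] -
                          pts[-nrow(pts), , drop = FALSE])^2))
  if (any(edge == 0)) {
    warning("dropping ", sum(edge == 0), " repeated consecutive point(s)")
    keep <- c(TRUE, edge > 0)
    pts <- pts[keep, , drop = FALSE]
    edge <- edge[edge > 0]
  }
  arc <- c(0, cumsum(edge))            # per dense point, closing row last
  total <- arc[length(arc)]
  if (total <= 0) stop("polyline has zero length")
  boundaries <- total * seq(0, n_segments) / n_segments
  # Distinct points only: the closing duplicate repeats point 1.
  s <- arc[-length(arc)]
  labels <- pmin(floor(n_segments * s / total) + 1L, n_segments)
  if (bare)
    return(list(boundaries = boundaries, labels = labels, arc = arc,
                total_length = total))
  template$points <- pts
  template$n_dense <- nrow(pts) - 1L
  template$n_ref <- as.integer(n_segments)
  template$total_length <- total
  template$boundaries <- boundaries
  template$arc <- arc
  template$seg_labels <- as.integer(labels)
  template
}

#' Compute per-segment reference points
#'
#' The reference point of each segment is the median centre of mass
#' (coordinate-wise median) of the dense polyline points belonging to that
#' segment. Reference points are the unit at which trajectories are binned,
#' aggregated and scored.
#'
#' @param template a segmented `woc_template` (see [segment_by_arclength()]).
#' @return the template with an `n_ref` x 2 `ref_points` matrix.
#' @export
compute_reference_points <- function(template) {
  stopifnot(inherits(template, "woc_template"))
  if (is.null(template$seg_labels))
    stop("template has no segmentation; call segment_by_arclength() first")
  pts <- template$points[-nrow(template$points), , drop = FALSE]
  lab <- template$seg_labels
  counts <- tabulate(lab, nbins = template$n_ref)
  if (any(counts == 0L))
    stop("template rejected: segment(s) ",
         paste(which(counts == 0L), collapse = ", "),
         " contain no dense points (increase n_dense)")
  ref <- matrix(NA_real_, template$n_ref, 2L)
  for (j in 1:2) {
    o <- order(lab, pts[, j])
    sorted <- pts[o, j]
    ends <- cumsum(counts)
    starts <- ends - counts + 1L
    lo <- starts + (counts - 1L) %/% 2L
    hi <- starts + counts %/% 2L
    ref[, j] <- (sorted[lo] + sorted[hi]) / 2
  }
  template$ref_points <- ref
  template
}

#' Fully construct a template: curve, segmentation and reference points
#'
#' Convenience wrapper chaining [make_template()], [segment_by_arclength()]
#' and [compute_reference_points()]. By default the two ellipses get 50
#' reference points and the other templates 100, counts high enough to
#' represent each curve faithfully while leaving several trace samples per
#' bin.
#'
#' @inheritParams make_template
#' @param n_ref number of reference points; default depends on the family.
#' @param n_dense dense polyline resolution; default `max(2000, 20 * n_ref)`.
#' @return a complete `woc_template`.
#' @export
segment_template <- function(name, n_ref = NULL, size = NULL, n_dense = NULL,
                             points = NULL, centre = SCREEN_MM / 2) {
  n_ref <- n_ref %||%
    (if (name %in% c("ellipse", "thin_ellipse")) 50L else 100L)
  n_dense <- n_dense %||% max(2000L, 20L * n_ref)
  tpl <- make_template(name, size = size, n_dense = n_dense, points = points,
                       centre = centre)
  compute_reference_points(segment_by_arclength(tpl, n_ref))
}

#' The default five-template registry
#'
#' @param names subset of the five default template names.
#' @return a named list of complete `woc_template` objects.
#' @export
default_templates <- function(names = c("ellipse", "thin_ellipse",
                                        "three_petal", "four_petal",
                                        "lemniscate")) {
  out <- lapply(names, segment_template)
  names(out) <- names
  out
}

#' Read a custom template from CSV
#'
#' Expects a header `x_mm,y_mm` and one dense point per row; the closed
#' curve is implied (the first point is appended at the end if needed).
#'
#' @param path CSV file path.
#' @param n_ref number of reference points for segmentation.
#' @return a complete `woc_template` named `"custom"`.
#' @export
read_template_csv <- function(path, n_ref = 100L) {
  d <- utils::read.csv(path)
  if (!all(c("x_mm", "y_mm") %in% names(d)))
    stop("template CSV must have columns x_mm and y_mm")
  segment_template("custom", n_ref = n_ref, points = cbind(d$x_mm, d$y_mm))
}

#' @export
print.woc_template <- function(x, ...) {
  cat("Closed template curve '", x$name, "'\n", sep = "")
  cat("  dense points: ", x$n_dense, "\n", sep = "")
  if (!is.null(x$total_length))
    cat(sprintf("  arc length: %.2f mm in %d equal segments\n",
                x$total_length, x$n_ref))
  if (!is.null(x$ref_points))
    cat("  reference points: ", nrow(x$ref_points), "\n", sep = "")
  invisible(x)
}

# ---- arc-length interpolation helpers (used by the simulator) ----------

# Positions on the curve at arc-length positions s (taken modulo the total
# length), by linear interpolation of the dense polyline.
template_point_at <- function(template, s) {
  s <- s %% template$total_length
  cbind(stats::approx(template$arc, template$points[, 1L], xout = s)$y,
        stats::approx(template$arc, template$points[, 2L], xout = s)$y)
}

# Unit normals at arc positions s. Tangents are central differences of the
# dense polyline (periodic); the normal is the tangent rotated a quarter
# turn, (-ty, tx): left of the direction of travel, a fixed sign convention.
template_normal_at <- function(template, s) {
  pts <- template$points[-nrow(template$points), , drop = FALSE]
  n <- nrow(pts)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  tg <- pts[nxt, , drop = FALSE] - pts[prv, , drop = FALSE]
  tg <- tg / sqrt(rowSums(tg^2))
  s <- s %% template$total_length
  arc <- template$arc[-length(template$arc)]
  tx <- stats::approx(arc, tg[, 1L], xout = s, rule = 2)$y
  ty <- stats::approx(arc, tg[, 2L], xout = s, rule = 2)$y
  nr <- sqrt(tx^2 + ty^2)
  cbind(-ty / nr, tx / nr)
}
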