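# Internal numerical helpers shared across modules.

#' Row-wise medians of a numeric matrix
#'
#' Vectorised coordinate-wise median over the columns of `X`, one value per
#' row, with `NA` entries ignored per row (a row of all `NA` gives `NA`).
#' For even counts the midpoint of the two middle values is used. This is
#' the workhorse behind every "median centre of mass" in the package, so it
#' avoids an `apply()` loop: values are sorted within rows by a single
#' `order()` call and the middle order statistics are picked by indexing.
#'
#' @param X numeric matrix.
#' @return numeric vector of length `nrow(X)`.
#' @keywords internal
#' @noRd
row_medians <- function(X) {
  n <- nrow(X)
  k <- ncol(X)
  if (n == 0L) return(numeric(0))
  if (k == 1L) return(X[, 1L])
  m <- rowSums(!is.na(X))
  if (anyNA(X)) X[is.na(X)] <- Inf  # sorts past every real value, never indexed
  S <- matrix(X[order(row(X), X)], nrow = n, byrow = TRUE)
  lo <- pmax((m + 1L) %/% 2L, 1L)
  hi <- pmax((m + 2L) %/% 2L, 1L)
  out <- (S[cbind(seq_len(n), lo)] + S[cbind(seq_len(n), hi)]) / 2
  out[m == 0L] <- NA_real_
  out
}

# Row means ignoring NA, returning NA for all-NA rows (rowMeans semantics
# differ: they return NaN).
row_means_na <- function(X) {
  m <- rowSums(!is.na(X))
  out <- rowMeans(X, na.rm = TRUE)
  out[m == 0L] <- NA_real_
  out
}

# Aggregate the columns of a (2 * n_ref) x k point stack by the requested
# centre of mass.
stack_centre <- function(X, method) {
  if (method == "median") row_medians(X) else row_means_na(X)
}

# Euclidean per-bin distances between a flattened trajectory (x then y,
# length 2 * n_ref) and the template reference points.
flat_bin_errors <- function(a, ref_points) {
  n <- nrow(ref_points)
  sqrt((a[seq_len(n)] - ref_points[, 1L])^2 +
         (a[n + seq_len(n)] - ref_points[, 2L])^2)
}

# Derive a reproducible 31-bit sub-seed from a base seed and an index.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + 97 * as.numeric(index)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a
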