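#' Axis labels of the linac coordinate frame
#'
#' All 3D quantities in this package are expressed in the fixed room frame of
#' the linear accelerator: x = latero-lateral (LL, + towards patient left),
#' y = antero-posterior (AP, + anterior), z = cranio-caudal (CC, + cranial),
#' with the isocenter at the origin. Units are millimetres throughout.
#'
#' @return Character vector `c("ll", "ap", "cc")`.
#' @export
linac_axes <- function() c("ll", "ap", "cc")

#' Percentile range of a sample
#'
#' Difference between an upper and a lower sample percentile, the spread
#' statistic behind the intra-DIBH stability (S), intrafraction (V) and
#' interfraction (W) reproducibility indices. The default 5th-95th range
#' captures the bulk of the positional excursion while being robust to
#' isolated outlier samples.
#'
#' Percentiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), fixed package-wide so results are exactly
#' reproducible; the same estimator is used for every quartile summary.
#'
#' @param x Numeric vector (marker coordinates or positions, mm).
#' @param probs Length-2 numeric, lower and upper percentile in `[0, 1]`.
#' @param na.rm Drop non-finite values first (default `TRUE`).
#' @return Non-negative scalar, or `NA` if no finite values remain.
#' @examples
#' percentile_range(seq(0, 10, length.out = 1000))  # 9.0
#' @export
percentile_range <- function(x, probs = c(0.05, 0.95), na.rm = TRUE) {
  stopifnot(is.numeric(probs), length(probs) == 2L, probs[1] < probs[2])
  if (na.rm) x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  q <- stats::quantile(x, probs = probs, type = 7, names = FALSE)
  q[2] - q[1]
}

#' Median with quartile summary
#'
#' @param x Numeric vector.
#' @return Named numeric: `median`, `q25`, `q75` (type-7 quantiles).
#' @export
median_quartiles <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) {
    return(c(median = NA_real_, q25 = NA_real_, q75 = NA_real_))
  }
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q25 = q[1], q75 = q[3])
}

# Internal: median that tolerates empty input.
med_or_na <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) NA_real_ else stats::median(x)
}

# Internal: indices of samples with a <= t <= b (or t < b when
# incl_end = FALSE) on a strictly increasing time grid; binary search so
# window extraction stays cheap on long recordings.
time_slice <- function(times, a, b, incl_end = TRUE) {
  i1 <- findInterval(a - 1e-9, times) + 1L
  i2 <- findInterval(b + if (incl_end) 1e-9 else -1e-9, times)
  if (i2 < i1) integer(0) else i1:i2
}

# Internal: row-wise Euclidean norms of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

# Internal: coerce to an n x 3 matrix with axis column names.
as_points <- function(p) {
  p <- as.matrix(p)
  if (is.null(dim(p)) || ncol(p) != 3L) {
    stop("point sets must be n x 3 matrices (LL, AP, CC)", call. = FALSE)
  }
  storage.mode(p) <- "double"
  colnames(p) <- linac_axes()
  p
}
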