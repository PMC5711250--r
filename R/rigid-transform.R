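#' Rigid transform between marker constellations
#'
#' A rigid (rotation + translation, no scaling) map of 3D points in the linac
#' frame, parameterised the way setup errors are reported clinically: three
#' rotation angles in degrees about the LL, AP and CC axes and three
#' translations in millimetres. Rotations are applied about `center_mm`
#' (for fitted transforms, the centroid of the planning constellation — the
#' natural least-squares pivot), as intrinsic rotations in the fixed order
#' LL, then AP, then CC.
#'
#' A point `x` is mapped as `y = R (x - center) + center + t`.
#'
#' @param rotations_deg Numeric length 3, degrees about (LL, AP, CC).
#' @param translations_mm Numeric length 3, mm along (LL, AP, CC).
#' @param center_mm Rotation pivot, mm (default origin/isocenter).
#' @return Object of class `rigid_transform`.
#' @seealso [fit_rigid()], [apply_transform()], [invert_transform()]
#' @export
rigid_transform <- function(rotations_deg = c(0, 0, 0),
                            translations_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  stopifnot(length(rotations_deg) == 3L, all(is.finite(rotations_deg)),
            length(translations_mm) == 3L, all(is.finite(translations_mm)),
            length(center_mm) == 3L, all(is.finite(center_mm)))
  out <- list(
    rotations_deg = stats::setNames(as.numeric(rotations_deg), linac_axes()),
    translations_mm = stats::setNames(as.numeric(translations_mm), linac_axes()),
    center_mm = stats::setNames(as.numeric(center_mm), linac_axes())
  )
  class(out) <- "rigid_transform"
  out
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (intrinsic LL-AP-CC rotations about pivot)\n")
  cat(sprintf("  rotations   : %7.3f %7.3f %7.3f deg (LL, AP, CC)\n",
              x$rotations_deg[1], x$rotations_deg[2], x$rotations_deg[3]))
  cat(sprintf("  translations: %7.3f %7.3f %7.3f mm\n",
              x$translations_mm[1], x$translations_mm[2], x$translations_mm[3]))
  cat(sprintf("  pivot       : %7.2f %7.2f %7.2f mm\n",
              x$center_mm[1], x$center_mm[2], x$center_mm[3]))
  invisible(x)
}

#' Rotation matrix from LL/AP/CC angles
#'
#' Builds the 3 x 3 rotation matrix for intrinsic rotations applied in the
#' order LL (x), then AP (y), then CC (z): `R = Rx(a) Ry(b) Rz(c)`.
#' At the small angles typical of setup errors (a few degrees) the order
#' effect is second order, but one convention must be fixed for round-trips.
#'
#' @param angles_deg Numeric length 3, degrees about (LL, AP, CC).
#' @return 3 x 3 orthonormal matrix with determinant +1.
#' @export
euler_to_matrix <- function(angles_deg) {
  stopifnot(length(angles_deg) == 3L, all(is.finite(angles_deg)))
  th <- angles_deg * pi / 180
  ca <- cos(th[1]); sa <- sin(th[1])
  cb <- cos(th[2]); sb <- sin(th[2])
  cc <- cos(th[3]); sc <- sin(th[3])
  rx <- rbind(c(1, 0, 0), c(0, ca, -sa), c(0, sa, ca))
  ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
  rz <- rbind(c(cc, -sc, 0), c(sc, cc, 0), c(0, 0, 1))
  rx %*% ry %*% rz
}

#' Recover LL/AP/CC angles from a rotation matrix
#'
#' Inverse of [euler_to_matrix()] for `|AP angle| < 90` degrees (always the
#' case for setup rotations). The input is checked for orthonormality and
#' positive determinant.
#'
#' @param R 3 x 3 rotation matrix.
#' @param tol Orthonormality tolerance.
#' @return Numeric length 3, degrees about (LL, AP, CC).
#' @export
matrix_to_euler <- function(R, tol = 1e-8) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  if (max(abs(crossprod(R) - diag(3))) > tol) {
    stop("matrix is not orthonormal within tolerance", call. = FALSE)
  }
  if (det(R) < 0) stop("matrix is a reflection (det < 0)", call. = FALSE)
  b <- asin(max(-1, min(1, R[1, 3])))
  a <- atan2(-R[2, 3], R[3, 3])
  cc <- atan2(-R[1, 2], R[1, 1])
  c(a, b, cc) * 180 / pi
}

#' Apply a rigid transform to a point set
#'
#' @param transform A [rigid_transform()].
#' @param points n x 3 matrix of points (mm, LL/AP/CC columns).
#' @return n x 3 matrix of mapped points.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  p <- as_points(points)
  R <- euler_to_matrix(transform$rotations_deg)
  ctr <- transform$center_mm
  out <- sweep(p, 2, ctr) %*% t(R)
  out <- sweep(out, 2, ctr + transform$translations_mm, "+")
  colnames(out) <- linac_axes()
  rownames(out) <- rownames(p)
  out
}

#' Invert a rigid transform
#'
#' The inverse maps treatment coordinates back to planning coordinates; its
#' pivot is the image of the original pivot, so that
#' `apply_transform(invert_transform(T), apply_transform(T, x))` recovers `x`
#' to machine precision.
#'
#' @param transform A [rigid_transform()].
#' @return A [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  R <- euler_to_matrix(transform$rotations_deg)
  rigid_transform(
    rotations_deg = matrix_to_euler(t(R)),
    translations_mm = -transform$translations_mm,
    center_mm = transform$center_mm + transform$translations_mm
  )
}

#' Least-squares rigid registration of corresponding point sets
#'
#' Estimates the rigid transform mapping planning marker positions onto
#' treatment positions by minimising the summed squared Euclidean distance
#' over corresponding points: centroids are aligned, the rotation is the
#' SVD (Kabsch) solution of the cross-covariance with reflection correction,
#' and the translation is the centroid displacement. The rotation pivot is
#' the planning centroid.
#'
#' @param planning n x 3 matrix of planning positions (mm).
#' @param treatment n x 3 matrix of corresponding treatment positions (mm).
#' @return A [rigid_transform()] with attribute `"rms_mm"`, the post-fit
#'   root-mean-square residual distance.
#' @export
fit_rigid <- function(planning, treatment) {
  p <- as_points(planning)
  q <- as_points(treatment)
  if (nrow(p) != nrow(q)) stop("point sets differ in size", call. = FALSE)
  if (nrow(p) < 3L) {
    stop("rigid registration needs at least 3 corresponding points",
         call. = FALSE)
  }
  cp <- colMeans(p)
  cq <- colMeans(q)
  pc <- sweep(p, 2, cp)
  qc <- sweep(q, 2, cq)
  # collinearity check: a rotation about the marker line is unobservable
  sv_p <- svd(pc, nu = 0, nv = 0)$d
  if (sv_p[2] <= 1e-8 * max(sv_p[1], 1e-300)) {
    stop("degenerate geometry: markers are collinear (or coincident)",
         call. = FALSE)
  }
  h <- crossprod(pc, qc)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- rigid_transform(
    rotations_deg = matrix_to_euler(R),
    translations_mm = cq - cp,
    center_mm = cp
  )
  res <- apply_transform(tr, p) - q
  attr(tr, "rms_mm") <- sqrt(mean(rowSums(res^2)))
  tr
}

#' Residual marker displacements after rigid correction
#'
#' 3D distances between planning positions mapped through a fitted rigid
#' transform and the observed treatment positions, summarised as
#' median +/- interquartile range (75th minus 25th percentile), the summary
#' used for per-patient residual reporting.
#'
#' @param planning,treatment Corresponding n x 3 point sets (mm).
#' @param transform Fitted [rigid_transform()] (defaults to refitting).
#' @return List with `distances_mm` (per marker), `median_mm`, `iqr_mm`.
#' @export
residual_displacements <- function(planning, treatment,
                                   transform = fit_rigid(planning, treatment)) {
  p <- as_points(planning)
  q <- as_points(treatment)
  d <- row_norms(apply_transform(transform, p) - q)
  qs <- stats::quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(distances_mm = d, median_mm = qs[2], iqr_mm = qs[3] - qs[1])
}

#' Worst monitored session by planning-to-treatment distance
#'
#' Selects the session with the maximum mean 3D distance between planning
#' marker positions and that session's treatment positions (before any rigid
#' correction). Ties are broken towards the earliest session.
#'
#' @param planning n x 3 planning positions (mm).
#' @param treatment_by_session List of n x 3 per-session treatment positions.
#' @return List with `session` (index), `mean_distance_mm` (per session).
#' @export
worst_session <- function(planning, treatment_by_session) {
  stopifnot(length(treatment_by_session) >= 1L)
  p <- as_points(planning)
  md <- vapply(treatment_by_session, function(q) {
    q <- as_points(q)
    mean(row_norms(q - p), na.rm = TRUE)
  }, numeric(1))
  list(session = as.integer(which.max(md)),
       mean_distance_mm = unname(md))
}

#' Population decomposition of setup transform parameters
#'
#' Splits per-patient, per-breath-hold rigid transform parameters into the
#' standard population components of setup-error analysis: the group mean
#' `M` (mean over patients of the patient means), the systematic component
#' `Sigma` (standard deviation over patients of the patient means) and the
#' random component `sigma` (root mean square over patients of the
#' within-patient standard deviations).
#'
#' @param params Data frame with a `patient` column and one numeric column
#'   per transform parameter (e.g. `t_ll`, `t_ap`, `t_cc`, `r_ll`, `r_ap`,
#'   `r_cc`).
#' @return Data frame with one row per parameter and columns
#'   `parameter`, `M`, `Sigma`, `sigma`.
#' @export
population_errors <- function(params) {
  stopifnot(is.data.frame(params), "patient" %in% names(params))
  value_cols <- setdiff(names(params), "patient")
  if (length(value_cols) == 0L) stop("no parameter columns", call. = FALSE)
  patients <- unique(params$patient)
  if (length(patients) < 2L) {
    stop("population decomposition needs >= 2 patients", call. = FALSE)
  }
  per_pat <- lapply(patients, function(pt) params[params$patient == pt, , drop = FALSE])
  n_per <- vapply(per_pat, nrow, integer(1))
  if (any(n_per < 2L)) {
    stop("population decomposition needs >= 2 breath holds per patient",
         call. = FALSE)
  }
  out <- lapply(value_cols, function(cl) {
    means <- vapply(per_pat, function(df) mean(df[[cl]]), numeric(1))
    sds <- vapply(per_pat, function(df) stats::sd(df[[cl]]), numeric(1))
    data.frame(parameter = cl,
               M = mean(means),
               Sigma = stats::sd(means),
               sigma = sqrt(mean(sds^2)))
  })
  do.call(rbind, out)
}
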