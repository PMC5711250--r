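#' DLT camera model
#'
#' The 11-parameter Direct Linear Transformation maps a world point
#' `(X, Y, Z)` (mm, linac frame) to image coordinates `(u, v)` (pixels)
#' through the projective ratios
#' `u = (L1 X + L2 Y + L3 Z + L4) / (L9 X + L10 Y + L11 Z + 1)` and
#' `v = (L5 X + L6 Y + L7 Z + L8) / (L9 X + L10 Y + L11 Z + 1)`.
#' No lens-distortion terms are modelled.
#'
#' @param coefficients Numeric length 11 (`L1` ... `L11`).
#' @return Object of class `dlt_camera`.
#' @export
dlt_camera <- function(coefficients) {
  coefficients <- as.numeric(coefficients)
  stopifnot(length(coefficients) == 11L, all(is.finite(coefficients)))
  structure(list(L = coefficients), class = "dlt_camera")
}

#' @export
print.dlt_camera <- function(x, ...) {
  cat("DLT camera (11 coefficients):\n")
  print(signif(x$L, 6))
  invisible(x)
}

#' Synthetic camera from pose and intrinsics
#'
#' Builds a DLT camera looking from `position` towards `target`, with focal
#' length and principal point in pixels — the fixture used to emulate the
#' stereo pair of an optical localizer.
#'
#' @param position Camera centre, mm (world/linac frame).
#' @param target Look-at point, mm (default isocenter).
#' @param up Approximate up direction.
#' @param focal_px Focal length, px.
#' @param principal_px Principal point `(u0, v0)`, px.
#' @return A [dlt_camera()].
#' @export
make_camera <- function(position, target = c(0, 0, 0), up = c(0, 1, 0),
                        focal_px = 1800, principal_px = c(512, 512)) {
  position <- as.numeric(position); target <- as.numeric(target)
  zc <- target - position
  zc <- zc / sqrt(sum(zc^2))
  xc <- pracma_cross(zc, as.numeric(up))
  if (sqrt(sum(xc^2)) < 1e-9) stop("up direction parallel to view axis",
                                   call. = FALSE)
  xc <- xc / sqrt(sum(xc^2))
  yc <- pracma_cross(zc, xc)
  R <- rbind(xc, yc, zc)
  K <- rbind(c(focal_px, 0, principal_px[1]),
             c(0, focal_px, principal_px[2]),
             c(0, 0, 1))
  P <- K %*% cbind(R, -R %*% position)
  if (abs(P[3, 4]) < 1e-12) {
    stop("degenerate pose: camera plane passes through the origin",
         call. = FALSE)
  }
  P <- P / P[3, 4]
  dlt_camera(c(P[1, ], P[2, ], P[3, 1:3]))
}

# Internal: cross product (avoids an extra dependency for one line).
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Project world points through a DLT camera
#'
#' @param camera A [dlt_camera()].
#' @param points n x 3 world points, mm.
#' @return n x 2 matrix of pixel coordinates; rows with non-positive
#'   projective denominator (points at or behind the camera plane) are
#'   `NA` and flagged in the `"behind"` attribute.
#' @export
project_points <- function(camera, points) {
  stopifnot(inherits(camera, "dlt_camera"))
  p <- as_points(points)
  L <- camera$L
  den <- p %*% L[9:11] + 1
  u <- (p %*% L[1:3] + L[4]) / den
  v <- (p %*% L[5:7] + L[8]) / den
  out <- cbind(u = as.numeric(u), v = as.numeric(v))
  behind <- as.numeric(den) <= 0
  out[behind, ] <- NA_real_
  attr(out, "behind") <- behind
  out
}

#' Calibration grid phantom
#'
#' The daily calibration object: a square grid of equispaced passive
#' markers acquired at several couch heights, the central marker aligned
#' with the isocenter at the reference height. Defaults: a 36 x 36 cm grid
#' of 7 x 7 markers (6 cm spacing) replicated at five couch heights in
#' 5 cm steps, i.e. 245 world points. The grid plane is horizontal
#' (LL-CC); couch height moves along AP.
#'
#' @param n_side Markers per grid side.
#' @param size_mm Grid side length, mm.
#' @param heights_mm Couch heights (AP offsets), mm.
#' @return n x 3 matrix of world points, mm.
#' @export
grid_phantom <- function(n_side = 7, size_mm = 360,
                         heights_mm = c(0, -50, -100, -150, -200)) {
  u <- seq(-size_mm / 2, size_mm / 2, length.out = n_side)
  g <- expand.grid(ll = u, cc = u)
  out <- do.call(rbind, lapply(heights_mm, function(h) {
    cbind(ll = g$ll, ap = rep(h, nrow(g)), cc = g$cc)
  }))
  as_points(out)
}

#' Synthetic stereo views of the calibration phantom
#'
#' Projects the phantom through both cameras and adds isotropic Gaussian
#' pixel noise — the synthetic stand-in for acquiring the grid phantom with
#' the stereo localizer.
#'
#' @param camera_a,camera_b [dlt_camera()] objects.
#' @param phantom World points (default [grid_phantom()]).
#' @param noise_px Pixel noise SD (default 0.4 px, Monte-Carlo calibrated so the
#'   median 3D reconstruction error of the phantom fixture is about 1 mm).
#' @param seed Optional seed for the noise draw.
#' @return List: `world`, `image_a`, `image_b` (n x 2), `visible` (logical,
#'   in front of both cameras).
#' @export
generate_phantom_views <- function(camera_a, camera_b,
                                   phantom = grid_phantom(),
                                   noise_px = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  world <- as_points(phantom)
  ia <- project_points(camera_a, world)
  ib <- project_points(camera_b, world)
  visible <- !(attr(ia, "behind") | attr(ib, "behind"))
  n <- nrow(world)
  if (noise_px > 0) {
    ia <- ia + matrix(stats::rnorm(2 * n, 0, noise_px), n, 2)
    ib <- ib + matrix(stats::rnorm(2 * n, 0, noise_px), n, 2)
  }
  list(world = world, image_a = ia, image_b = ib, visible = visible)
}

#' DLT calibration from world-image correspondences
#'
#' Least-squares solution of the linearised DLT system, with Hartley-style
#' normalisation of world and image coordinates for conditioning. At least
#' six non-coplanar points are required: a single phantom height (coplanar
#' grid) is rejected, the full multi-height stack calibrates.
#'
#' @param world n x 3 world points, mm.
#' @param image n x 2 observed pixel coordinates.
#' @return A [dlt_camera()] with attribute `"rms_px"` (reprojection RMS).
#' @export
dlt_calibrate <- function(world, image) {
  world <- as_points(world)
  image <- as.matrix(image)
  stopifnot(ncol(image) == 2L, nrow(image) == nrow(world))
  ok <- stats::complete.cases(world) & stats::complete.cases(image)
  world <- world[ok, , drop = FALSE]
  image <- image[ok, , drop = FALSE]
  n <- nrow(world)
  if (n < 6L) stop("DLT calibration needs at least 6 points", call. = FALSE)
  # coplanarity check: the smallest principal extent must be non-negligible
  wc <- sweep(world, 2, colMeans(world))
  sv <- svd(wc, nu = 0, nv = 0)$d
  if (sv[3] <= 1e-6 * max(sv[1], 1e-300)) {
    stop(paste("degenerate calibration geometry: world points are coplanar",
               "(acquire the phantom at multiple couch heights)"),
         call. = FALSE)
  }
  # normalisation transforms
  cw <- colMeans(world)
  sw <- sqrt(3) / mean(row_norms(wc))
  wn <- wc * sw
  ci <- colMeans(image)
  ic <- sweep(image, 2, ci)
  si <- sqrt(2) / mean(sqrt(rowSums(ic^2)))
  im <- ic * si
  A <- matrix(0, 2 * n, 11)
  X <- cbind(wn, 1)
  A[seq(1, 2 * n, 2), 1:4] <- X
  A[seq(2, 2 * n, 2), 5:8] <- X
  A[seq(1, 2 * n, 2), 9:11] <- -im[, 1] * wn
  A[seq(2, 2 * n, 2), 9:11] <- -im[, 2] * wn
  bvec <- as.numeric(t(im))
  sv_a <- svd(A, nu = 0, nv = 0)$d
  if (sv_a[11] <= 1e-10 * sv_a[1]) {
    stop("degenerate calibration geometry: DLT system is rank deficient",
         call. = FALSE)
  }
  Ln <- qr.solve(A, bvec)
  # denormalise: assemble the 3 x 4 matrix in normalised frames, then
  # conjugate with the similarity transforms
  Pn <- rbind(c(Ln[1:4]), c(Ln[5:8]), c(Ln[9:11], 1))
  Ti <- rbind(c(1 / si, 0, ci[1]), c(0, 1 / si, ci[2]), c(0, 0, 1))
  Tw <- rbind(cbind(diag(3) * sw, -sw * cw), c(0, 0, 0, 1))
  P <- Ti %*% Pn %*% Tw
  P <- P / P[3, 4]
  cam <- dlt_camera(c(P[1, ], P[2, ], P[3, 1:3]))
  reproj <- project_points(cam, world)
  attr(cam, "rms_px") <- sqrt(mean((reproj - image)^2))
  cam
}

#' Triangulate a 3D point from two calibrated views
#'
#' Linear least-squares intersection of the two viewing rays in DLT form
#' (four equations in the three world coordinates per point).
#'
#' @param camera_a,camera_b Calibrated [dlt_camera()] objects.
#' @param image_a,image_b n x 2 observed pixel coordinates (or length-2
#'   vectors for a single point).
#' @return n x 3 matrix of world points (mm) with logical attribute
#'   `"ill_conditioned"` flagging near-parallel ray pairs.
#' @export
triangulate <- function(camera_a, camera_b, image_a, image_b) {
  stopifnot(inherits(camera_a, "dlt_camera"),
            inherits(camera_b, "dlt_camera"))
  if (is.null(dim(image_a))) image_a <- matrix(image_a, ncol = 2)
  if (is.null(dim(image_b))) image_b <- matrix(image_b, ncol = 2)
  stopifnot(nrow(image_a) == nrow(image_b))
  n <- nrow(image_a)
  La <- camera_a$L; Lb <- camera_b$L
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, linac_axes()))
  ill <- logical(n)
  for (k in seq_len(n)) {
    ua <- image_a[k, 1]; va <- image_a[k, 2]
    ub <- image_b[k, 1]; vb <- image_b[k, 2]
    if (!all(is.finite(c(ua, va, ub, vb)))) { ill[k] <- TRUE; next }
    A <- rbind(La[1:3] - ua * La[9:11],
               La[5:7] - va * La[9:11],
               Lb[1:3] - ub * Lb[9:11],
               Lb[5:7] - vb * Lb[9:11])
    bb <- c(ua - La[4], va - La[8], ub - Lb[4], vb - Lb[8])
    sv <- svd(A, nu = 0, nv = 0)$d
    if (sv[3] <= 1e-8 * sv[1]) ill[k] <- TRUE
    out[k, ] <- qr.solve(A, bb)
  }
  attr(out, "ill_conditioned") <- ill
  out
}

#' Reconstruction error summary
#'
#' 3D Euclidean errors between reconstructed and true marker positions,
#' summarised as median and 25th-75th percentiles with the same percentile
#' estimator used for the variability indices.
#'
#' @param reconstructed,truth Corresponding n x 3 point sets, mm.
#' @return List: `errors_mm`, `median_mm`, `q25_mm`, `q75_mm`.
#' @export
reconstruction_error_report <- function(reconstructed, truth) {
  r <- as_points(reconstructed)
  tr <- as_points(truth)
  if (nrow(r) != nrow(tr)) stop("point sets differ in size", call. = FALSE)
  e <- row_norms(r - tr)
  e_ok <- e[is.finite(e)]
  q <- stats::quantile(e_ok, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(errors_mm = e, median_mm = q[2], q25_mm = q[1], q75_mm = q[3])
}

#' Default stereo rig for the calibration fixture
#'
#' Two cameras mounted laterally above the treatment couch, about 2.9 m
#' from the isocenter with a 3 m baseline — a plausible dual-camera
#' optical-localizer geometry (the real rig's geometry is not prescribed;
#' these defaults are documented assumptions of the fixture).
#'
#' @return List with `camera_a`, `camera_b`.
#' @export
default_stereo_rig <- function() {
  list(
    camera_a = make_camera(c(-1500, 2200, 1200)),
    camera_b = make_camera(c(1500, 2200, 1200))
  )
}
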