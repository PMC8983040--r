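# Planar similarity transforms and the algebraic circle fit used for the
# triplet-ring landmarks.  A similarity maps a point p (column-wise xy) to
# s * R(theta) %*% p + t; these are the building blocks of the
# standardization chain and are exercised directly by the transform-identity
# checks.

#' Construct a 2-D similarity transform
#'
#' A similarity transform maps a point `p` to `scale * R(rotation) p +
#' translation`, with the rotation counterclockwise in the distal view.
#'
#' @param rotation_deg counterclockwise rotation in degrees.
#' @param scale positive scale factor.
#' @param translation numeric length-2 translation `(x, y)`.
#' @return an object of class `similarity2d`.
#' @export
similarity2d <- function(rotation_deg = 0, scale = 1, translation = c(0, 0)) {
  stopifnot(is.numeric(rotation_deg), length(rotation_deg) == 1,
            is.numeric(scale), length(scale) == 1,
            is.numeric(translation), length(translation) == 2)
  if (scale <= 0) .stopf("similarity scale must be > 0 (got %g)", scale)
  structure(list(rotation_deg = rotation_deg, scale = scale,
                 translation = as.numeric(translation)),
            class = "similarity2d")
}

#' Apply a similarity transform to points
#'
#' @param transform a [similarity2d()] object.
#' @param points numeric matrix with columns `(x, y)` (a length-2 vector is
#'   treated as a single point).
#' @return transformed points, same shape as the input.
#' @export
apply_similarity <- function(transform, points) {
  stopifnot(inherits(transform, "similarity2d"))
  single <- is.null(dim(points))
  p <- if (single) matrix(points, 1, 2) else as.matrix(points)
  t <- .deg2rad(transform$rotation_deg)
  R <- matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
  out <- transform$scale * (p %*% t(R))
  out[, 1] <- out[, 1] + transform$translation[1]
  out[, 2] <- out[, 2] + transform$translation[2]
  if (single) drop(out) else out
}

#' Compose two similarity transforms
#'
#' `compose_similarity(a, b)` returns the transform equivalent to applying
#' `b` first, then `a`.
#'
#' @param a,b [similarity2d()] objects.
#' @return a `similarity2d` object.
#' @export
compose_similarity <- function(a, b) {
  stopifnot(inherits(a, "similarity2d"), inherits(b, "similarity2d"))
  similarity2d(rotation_deg = a$rotation_deg + b$rotation_deg,
               scale = a$scale * b$scale,
               translation = apply_similarity(a, b$translation))
}

#' Invert a similarity transform
#'
#' @param transform a [similarity2d()] object.
#' @return the inverse `similarity2d`, such that composing the two yields the
#'   identity within numerical precision.
#' @export
invert_similarity <- function(transform) {
  stopifnot(inherits(transform, "similarity2d"))
  inv <- similarity2d(rotation_deg = -transform$rotation_deg,
                      scale = 1 / transform$scale,
                      translation = c(0, 0))
  inv$translation <- -apply_similarity(inv, transform$translation)
  inv
}

#' Least-squares circle fit to ring landmarks
#'
#' Fits a circle to the annotated triplet-ring points by the Kasa algebraic
#' least-squares method: solving the linear system `2ax + 2by + c = x^2 +
#' y^2` and recovering center `(a, b)` and radius `sqrt(c + a^2 + b^2)`.
#'
#' @param points numeric matrix with columns `(x, y)`, at least 3
#'   non-collinear points (voxel units).
#' @return an object of class `circle_fit` with fields `center`, `radius`,
#'   `rms_residual` and `n_points`.
#' @export
fit_reference_circle <- function(points) {
  p <- as.matrix(points)
  if (ncol(p) < 2) .stopf("ring points must have (x, y) columns")
  p <- p[, 1:2, drop = FALSE]
  n <- nrow(p)
  if (n < 3) .stopf("degenerate ring: ring_points >= 3 required (got %d)", n)
  A <- cbind(2 * p[, 1], 2 * p[, 2], 1)
  b <- p[, 1]^2 + p[, 2]^2
  qr_ <- qr(A)
  if (qr_$rank < 3) .stopf("degenerate ring: collinear ring points")
  sol <- qr.coef(qr_, b)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) .stopf("degenerate ring: collinear ring points")
  center <- c(sol[1], sol[2])
  radius <- sqrt(r2)
  d <- sqrt((p[, 1] - center[1])^2 + (p[, 2] - center[2])^2)
  structure(list(center = unname(center), radius = unname(radius),
                 rms_residual = sqrt(mean((d - radius)^2)), n_points = n),
            class = "circle_fit")
}
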