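# Internal numeric helpers: angles, circular summaries, rotations, trilinear
# sampling.  Angle convention throughout the package: degrees, measured
# counterclockwise from +x in the distal view (mathematically positive).

.deg2rad <- function(d) d * pi / 180
.rad2deg <- function(r) r * 180 / pi

#' Normalize angles to [0, 360)
#'
#' @param deg numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into `[0, 360)`.
#' @export
norm_angle <- function(deg) {
  out <- deg %% 360
  out[out == 360] <- 0
  out
}

# signed minimal angular difference a - b in (-180, 180]
.circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  d[d > 180] <- d[d > 180] - 360
  d
}

# weighted circular mean (degrees) and mean resultant length
.circ_stats <- function(deg, w = NULL) {
  if (is.null(w)) w <- rep(1, length(deg))
  sw <- sum(w)
  if (sw <= 0) return(list(mean = NA_real_, R = 0))
  th <- .deg2rad(deg)
  cs <- sum(w * cos(th)) / sw
  sn <- sum(w * sin(th)) / sw
  R <- sqrt(cs^2 + sn^2)
  m <- if (R < .Machine$double.eps^0.5) NA_real_ else norm_angle(.rad2deg(atan2(sn, cs)))
  list(mean = m, R = R)
}

# rotation matrices (act on column vectors, right-handed)
.rot_z <- function(deg) {
  t <- .deg2rad(deg)
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

# Rodrigues rotation about a unit axis
.rot_axis <- function(axis, deg) {
  t <- .deg2rad(deg)
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(t) * K + (1 - cos(t)) * (K %*% K)
}

# minimal rotation mapping unit vector v onto unit vector w
.rot_between <- function(v, w) {
  v <- v / sqrt(sum(v^2)); w <- w / sqrt(sum(w^2))
  c_ <- sum(v * w)
  ax <- c(v[2] * w[3] - v[3] * w[2],
          v[3] * w[1] - v[1] * w[3],
          v[1] * w[2] - v[2] * w[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any axis orthogonal to v
    o <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- c(v[2] * o[3] - v[3] * o[2],
            v[3] * o[1] - v[1] * o[3],
            v[1] * o[2] - v[2] * o[1])
    return(.rot_axis(ax, 180))
  }
  .rot_axis(ax / s, .rad2deg(atan2(s, c_)))
}

# Vectorized trilinear interpolation on a 3-D array.  Coordinates are 1-based
# voxel indices; points outside the array return NA (the caller decides
# whether NA means "masked" or "zero").
.trilinear <- function(vol, x, y, z) {
  d <- dim(vol)
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= nx & y >= 1 & y <= ny & z >= 1 & z <= nz &
    is.finite(x) & is.finite(y) & is.finite(z)
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  z0 <- pmin(floor(z), nz - 1L)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  # linear indices of the 8 corners
  base <- function(i, j, k) ((k - 1) * ny + (j - 1)) * nx + i
  v000 <- vol[base(x0,     y0,     z0)]
  v100 <- vol[base(x0 + 1, y0,     z0)]
  v010 <- vol[base(x0,     y0 + 1, z0)]
  v110 <- vol[base(x0 + 1, y0 + 1, z0)]
  v001 <- vol[base(x0,     y0,     z0 + 1)]
  v101 <- vol[base(x0 + 1, y0,     z0 + 1)]
  v011 <- vol[base(x0,     y0 + 1, z0 + 1)]
  v111 <- vol[base(x0 + 1, y0 + 1, z0 + 1)]
  c00 <- v000 * (1 - fx) + v100 * fx
  c10 <- v010 * (1 - fx) + v110 * fx
  c01 <- v001 * (1 - fx) + v101 * fx
  c11 <- v011 * (1 - fx) + v111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  out[ok] <- c0 * (1 - fz) + c1 * fz
  out
}

# Bilinear sampling on a single 2-D plane (matrix [x, y]).
.bilinear <- function(m, x, y) {
  nx <- nrow(m); ny <- ncol(m)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= nx & y >= 1 & y <= ny & is.finite(x) & is.finite(y)
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  id <- function(i, j) (j - 1) * nx + i
  v00 <- m[id(x0, y0)]; v10 <- m[id(x0 + 1, y0)]
  v01 <- m[id(x0, y0 + 1)]; v11 <- m[id(x0 + 1, y0 + 1)]
  out[ok] <- (v00 * (1 - fx) + v10 * fx) * (1 - fy) +
    (v01 * (1 - fx) + v11 * fx) * fy
  out
}

# Cubic-convolution (Keys, a = -0.5) sampling on a 2-D plane; clamped at the
# borders, NA outside.  Higher-order than bilinear, so resampling smooth
# images loses an order of magnitude less signal.
.bicubic <- function(m, x, y) {
  nx <- nrow(m); ny <- ncol(m)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= nx & y >= 1 & y <= ny & is.finite(x) & is.finite(y)
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  tx <- x - x0; ty <- y - y0
  wk <- function(t) {
    cbind(0.5 * (-t^3 + 2 * t^2 - t),
          0.5 * (3 * t^3 - 5 * t^2 + 2),
          0.5 * (-3 * t^3 + 4 * t^2 + t),
          0.5 * (t^3 - t^2))
  }
  wx <- wk(tx); wy <- wk(ty)
  acc <- numeric(length(x))
  for (j in 1:4) {
    yj <- pmin(pmax(y0 + j - 2L, 1L), ny)
    row <- numeric(length(x))
    for (i in 1:4) {
      xi <- pmin(pmax(x0 + i - 2L, 1L), nx)
      row <- row + wx[, i] * m[(yj - 1) * nx + xi]
    }
    acc <- acc + wy[, j] * row
  }
  out[ok] <- acc
  out
}

# deterministic per-particle seed derived from a master seed (documented
# splitting scheme: fixed odd multiplier, modulo the Mersenne prime 2^31-1,
# so any particle can be regenerated in isolation)
.derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + 48271 * as.numeric(index)) %% 2147483647)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
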