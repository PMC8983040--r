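# Standardization chain: verticalize each centriole, fit the triplet ring,
# fix a rotational reference azimuth, and resample the particle onto the
# canonical centriole frame.  This reproduces, headlessly, the manual
# realignment workflow used for single-particle averaging of U-ExM
# centrioles: vertical alignment first, then rotational registration on a
# reference point (marker centroid, basal foot, or one end of a C-shaped
# pattern).

#' Canonical centriole frame
#'
#' The fixed grid all particles are mapped onto before averaging: 96 x 96
#' lateral voxels at 5 nm pre-expansion pitch (ring radius 115 nm = 23
#' voxels), 64 axial planes spanning the normalized axial frame 0-1
#' (proximal to distal).  The reference azimuth maps to 0 degrees (+x).
#'
#' @param radius_nm canonical triplet-ring radius, pre-expansion nm.
#' @param grid_xy lateral grid size (voxels).
#' @param pitch_nm lateral pitch, pre-expansion nm.
#' @param n_planes number of axial planes.
#' @return an object of class `canonical_geometry`.
#' @export
canonical_geometry <- function(radius_nm = 115, grid_xy = 96L, pitch_nm = 5,
                               n_planes = 64L) {
  stopifnot(radius_nm > 0, pitch_nm > 0, grid_xy >= 8, n_planes >= 2)
  structure(list(radius_nm = radius_nm, grid_xy = as.integer(grid_xy),
                 pitch_nm = pitch_nm, n_planes = as.integer(n_planes),
                 radius_vox = radius_nm / pitch_nm,
                 center = rep((grid_xy + 1) / 2, 2)),
            class = "canonical_geometry")
}

# rotation verticalizing `axis` for this stack, or identity when the
# displacement it would cause is below the sampling resolution
.vert_rotation <- function(stack, axis) {
  axis <- axis / sqrt(sum(axis^2))
  d0 <- dim(stack$voxels)
  extent <- sqrt(sum((d0[1:3] / 2 * c(stack$pitch_lateral_nm,
                                      stack$pitch_lateral_nm,
                                      stack$pitch_axial_nm))^2))
  angle <- acos(max(-1, min(1, sum(axis * c(0, 0, 1)))))
  if (2 * sin(angle / 2) * extent < 0.5 * stack$pitch_lateral_nm) diag(3)
  else .rot_between(axis, c(0, 0, 1))
}

# unit axis (nm space) from annotation axis points (voxel coords)
.axis_from_annotation <- function(annotation, stack) {
  ap <- annotation$axis_points
  d <- (ap[2, ] - ap[1, ]) * c(stack$pitch_lateral_nm, stack$pitch_lateral_nm,
                               stack$pitch_axial_nm)
  d / sqrt(sum(d^2))
}

#' Estimate the centriole long axis from the wall channel
#'
#' Principal axis of the intensity-weighted second-moment tensor of the
#' thresholded wall channel, in physical (nm) coordinates so anisotropic z
#' sampling is handled.  Because the microscope PSF is anisotropic (axial
#' sigma larger than lateral), the raw image moments are biased toward the
#' optical axis; the blur covariance — a convolution adds its covariance to
#' the geometry's — is therefore subtracted before the eigendecomposition.
#' The default blur sigmas match the package's default imaging model
#' (80 nm lateral / 200 nm axial, expanded space); pass the values of the
#' acquisition at hand, or zeros to disable the correction.  The sign
#' points toward increasing z (proximal to distal when the stack follows
#' the distal-view convention).
#'
#' @param stack an [image_stack()].
#' @param channel channel role or index (default `"wall"`).
#' @param threshold_frac voxels above `threshold_frac * max` enter the
#'   moment tensor.
#' @param min_anisotropy minimal ratio of leading to second axis length;
#'   below it the axis is undefined and an error is raised.
#' @param blur_sigma_nm length-2 `(lateral, axial)` Gaussian blur sigma
#'   subtracted from the image moments (nm, expanded space).
#' @return unit 3-vector (x, y, z components, nm space).
#' @export
estimate_long_axis <- function(stack, channel = "wall", threshold_frac = 0.1,
                               min_anisotropy = 1.05,
                               blur_sigma_nm = c(80, 200)) {
  .require_pitch(stack, "axis estimation")
  ch <- .channel_index(stack, channel)
  v <- stack$voxels[, , , ch]
  thr <- threshold_frac * max(v)
  sel <- which(v >= thr & v > 0)
  if (length(sel) < 10) .stopf("no signal above threshold in channel %s", channel)
  d <- dim(v)
  ijk <- arrayInd(sel, d)
  xyz <- cbind(ijk[, 1] * stack$pitch_lateral_nm,
               ijk[, 2] * stack$pitch_lateral_nm,
               ijk[, 3] * stack$pitch_axial_nm)
  w <- v[sel]
  mu <- colSums(xyz * w) / sum(w)
  cc <- sweep(xyz, 2, mu)
  S <- crossprod(cc * sqrt(w / sum(w)))
  # blur covariance; a previously verticalized stack carries the rotation
  # that was applied to the volume, which rotates the blur with it
  D <- diag(c(blur_sigma_nm[1]^2, blur_sigma_nm[1]^2, blur_sigma_nm[2]^2))
  W <- attr(stack, "pre_rotation")
  if (!is.null(W)) D <- W %*% D %*% t(W)
  S <- S - D
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  if (sqrt(ev[1] / max(ev[2], .Machine$double.eps)) < min_anisotropy)
    .stopf("degenerate axis: moment tensor anisotropy %.3f < %.2f",
           sqrt(ev[1] / max(ev[2], .Machine$double.eps)), min_anisotropy)
  ax <- e$vectors[, 1]
  if (ax[3] < 0 || (ax[3] == 0 && ax[which(ax != 0)[1]] < 0)) ax <- -ax
  ax
}

#' Rotate a stack so a given axis becomes vertical
#'
#' Applies the minimal rotation sending `axis` to +z, resampling the volume
#' trilinearly about the stack center in physical coordinates.  If the
#' requested rotation would displace no voxel by more than half a lateral
#' voxel — the axis is already vertical to within the sampling resolution —
#' the input is returned unchanged (identity short-circuit), avoiding a
#' pure interpolation loss.  The applied rotation matrix is attached as
#' attribute `"pre_rotation"`.
#'
#' @param stack an [image_stack()].
#' @param axis unit 3-vector (nm space).
#' @return the verticalized [image_stack()].
#' @export
verticalize <- function(stack, axis) {
  .require_pitch(stack, "verticalization")
  W <- .vert_rotation(stack, axis)
  if (all(W == diag(3))) {
    attr(stack, "pre_rotation") <- diag(3)
    return(stack)
  }
  d <- dim(stack$voxels)
  ctr <- (d[1:3] + 1) / 2
  pit <- c(stack$pitch_lateral_nm, stack$pitch_lateral_nm, stack$pitch_axial_nm)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  q <- cbind((g$x - ctr[1]) * pit[1], (g$y - ctr[2]) * pit[2],
             (g$z - ctr[3]) * pit[3])
  p <- q %*% W                      # W^-1 q for each row (W orthogonal)
  sx <- p[, 1] / pit[1] + ctr[1]
  sy <- p[, 2] / pit[2] + ctr[2]
  sz <- p[, 3] / pit[3] + ctr[3]
  out <- stack$voxels
  for (ch in seq_len(d[4])) {
    vals <- .trilinear(stack$voxels[, , , ch], sx, sy, sz)
    vals[is.na(vals)] <- 0
    out[, , , ch] <- array(vals, d[1:3])
  }
  res <- stack
  res$voxels <- out
  attr(res, "pre_rotation") <- W
  res
}

#' Reference azimuth of a verticalized centriole
#'
#' Fixes the rotational registration angle: either the azimuth of an
#' annotated point about the fitted ring center (`point`,
#' `basal_foot_point`, `c_end_point` modes), or — operationalizing "the
#' brightest part of the signal" — the intensity centroid of the top-q
#' fraction of marker-channel voxels restricted to the distal part of the
#' axial frame (`brightest` mode).  Azimuths are degrees counterclockwise
#' from +x in the distal view; a proximal-view stack negates the result.
#'
#' @param stack verticalized [image_stack()].
#' @param annotation a [centriole_annotation()] (supplies ring points,
#'   reference point, z frame).
#' @param mode registration mode; defaults to the annotation's
#'   `reference_mode`.
#' @param circle optional precomputed [fit_reference_circle()] result.
#' @param channel marker channel role or index for `brightest` mode.
#' @param q top intensity fraction used by `brightest` mode.
#' @param distal_fraction fraction of the axial frame, at the distal end,
#'   searched in `brightest` mode.
#' @return azimuth in degrees, `[0, 360)`.
#' @export
reference_azimuth <- function(stack, annotation, mode = NULL, circle = NULL,
                              channel = "marker", q = 0.05,
                              distal_fraction = 0.3) {
  if (is.null(mode)) mode <- annotation$reference_mode
  if (is.null(circle)) circle <- fit_reference_circle(annotation$ring_points)
  flip <- identical(stack$view_convention, "proximal")
  az_of <- function(x, y) norm_angle(.rad2deg(atan2(y - circle$center[2],
                                                    x - circle$center[1])))
  if (mode %in% c("point", "basal_foot_point", "c_end_point")) {
    rp <- annotation$reference_point
    if (is.null(rp)) .stopf("reference_mode '%s' needs a reference_point", mode)
    a <- az_of(rp[1], rp[2])
    return(if (flip) norm_angle(-a) else a)
  }
  if (mode != "brightest") .stopf("unknown reference mode '%s'", mode)
  ch <- .channel_index(stack, channel)
  zf <- annotation$z_frame
  z_lo <- max(1, floor(zf[2] - distal_fraction * (zf[2] - zf[1])))
  z_hi <- min(dim(stack$voxels)[3], ceiling(zf[2]))
  sub <- stack$voxels[, , z_lo:z_hi, ch, drop = FALSE]
  if (max(sub) <= 0) .stopf("no signal in marker channel distal window")
  thr <- stats::quantile(sub, 1 - q, names = FALSE)
  sel <- which(sub >= thr & sub > 0)
  ijk <- arrayInd(sel, dim(sub))
  w <- sub[sel]
  a_vox <- az_of(ijk[, 1], ijk[, 2])
  cs <- .circ_stats(a_vox, w)
  a <- cs$mean
  if (!is.finite(a) || cs$R < 0.5) {
    # ambiguous (near-symmetric) top set: fall back to the brightest voxel,
    # exact ties resolved toward the lower azimuth (deterministic)
    top <- which(w == max(w))
    a <- min(a_vox[top])
  }
  if (flip) norm_angle(-a) else a
}

#' Compute the standardization transform from landmarks
#'
#' Composes (i) the verticalizing rotation from the annotated (or estimated)
#' long axis, (ii) the in-plane rotation sending the reference azimuth to
#' the canonical azimuth 0, (iii) the scaling sending the fitted ring radius
#' to the canonical radius, (iv) the translation sending the fitted center
#' onto the canonical axis, and (v) the axial map sending the z frame onto
#' the canonical axial frame.
#'
#' @inheritParams reference_azimuth
#' @param canonical a [canonical_geometry()].
#' @param register if `FALSE` the rotational registration is disabled (the
#'   reference azimuth is taken as 0): particles keep their native
#'   orientation.  Used for unregistered control averages.
#' @return an object of class `standardization_transform`.
#' @export
standardize_transform <- function(stack, annotation,
                                  canonical = canonical_geometry(),
                                  register = TRUE, q = 0.05,
                                  distal_fraction = 0.3) {
  .require_pitch(stack, "standardization")
  if (!is.null(annotation$axis_points)) {
    axis <- .axis_from_annotation(annotation, stack)
  } else {
    axis <- estimate_long_axis(stack)
  }
  W <- .vert_rotation(stack, axis)
  fit <- fit_reference_circle(annotation$ring_points)
  ref_az <- if (register) {
    # brightest mode needs the verticalized image; point modes do not
    if (annotation$reference_mode == "brightest") {
      vstack <- if (all(abs(W - diag(3)) < 1e-12)) stack else verticalize(stack, axis)
      reference_azimuth(vstack, annotation, circle = fit, q = q,
                        distal_fraction = distal_fraction)
    } else {
      reference_azimuth(stack, annotation, circle = fit)
    }
  } else 0
  scale <- canonical$radius_vox / fit$radius
  sim <- similarity2d(rotation_deg = -ref_az, scale = scale)
  sim$translation <- canonical$center - apply_similarity(sim, fit$center)
  # ring landmarks forward-mapped onto the canonical circle
  fwd <- apply_similarity(sim, annotation$ring_points[, 1:2, drop = FALSE])
  dd <- sqrt((fwd[, 1] - canonical$center[1])^2 +
               (fwd[, 2] - canonical$center[2])^2)
  structure(list(pre_rotation = W, axis = axis,
                 reference_mode = if (register) annotation$reference_mode else "none",
                 ref_azimuth_deg = ref_az,
                 in_plane_rotation_deg = norm_angle(-ref_az),
                 scale = scale, translation = sim$translation,
                 similarity = sim, fit = fit,
                 z_frame = annotation$z_frame,
                 landmark_rms = sqrt(mean((dd - canonical$radius_vox)^2)),
                 canonical = canonical),
            class = "standardization_transform")
}

#' Standardize a centriole onto the canonical frame
#'
#' Applies the full chain of [standardize_transform()] and resamples the
#' particle trilinearly onto the canonical grid in a single interpolation
#' pass (source voxels are fetched through the composed inverse map, so no
#' intermediate resampling loss accrues).  Canonical voxels whose source
#' location falls outside the stack are masked, not zero-filled.
#'
#' @inheritParams standardize_transform
#' @param channels channel roles (or indices) to resample; default all.
#' @param axial_mode `"rescale"` linearly maps the z frame onto the
#'   canonical axial frame; `"native"` preserves the source axial pitch
#'   (translation only), for length-sensitive analyses.
#' @param normalize if `TRUE`, scale the particle so its summed marker
#'   intensity is 1 before averaging.
#' @return a list with `particle` (class `standard_centriole`: `volume`
#'   `[x, y, z, channel]`, logical `mask`, provenance) and `transform`.
#' @export
standardize <- function(stack, annotation, canonical = canonical_geometry(),
                        channels = NULL, register = TRUE,
                        axial_mode = c("rescale", "native"),
                        normalize = FALSE, q = 0.05, distal_fraction = 0.3) {
  axial_mode <- match.arg(axial_mode)
  tr <- tryCatch(
    standardize_transform(stack, annotation, canonical, register, q,
                          distal_fraction),
    error = function(e) .stopf("particle '%s': %s", annotation$particle_id,
                               conditionMessage(e)))
  d <- dim(stack$voxels)
  if (is.null(channels)) channels <- seq_len(d[4])
  chi <- vapply(channels, function(ch) .channel_index(stack, ch), integer(1))
  G <- canonical$grid_xy; K <- canonical$n_planes
  inv <- invert_similarity(tr$similarity)

  # canonical lateral grid mapped back to the verticalized frame
  gxy <- expand.grid(x = seq_len(G), y = seq_len(G))
  src_xy <- apply_similarity(inv, as.matrix(gxy))
  zf <- tr$z_frame
  z_can <- seq_len(K)
  z_src <- if (axial_mode == "rescale") {
    zf[1] + (z_can - 1) / (K - 1) * (zf[2] - zf[1])
  } else {
    mean(zf) + (z_can - (K + 1) / 2)
  }

  ctr <- (d[1:3] + 1) / 2
  pit <- c(stack$pitch_lateral_nm, stack$pitch_lateral_nm, stack$pitch_axial_nm)
  W <- tr$pre_rotation
  identW <- all(abs(W - diag(3)) < 1e-12)

  nlat <- nrow(src_xy)
  vol <- array(NA_real_, c(G, G, K, length(chi)))
  mask <- array(FALSE, c(G, G, K))
  for (k in seq_len(K)) {
    if (identW) {
      sx <- src_xy[, 1]; sy <- src_xy[, 2]; sz <- rep(z_src[k], nlat)
    } else {
      q_ <- cbind((src_xy[, 1] - ctr[1]) * pit[1],
                  (src_xy[, 2] - ctr[2]) * pit[2],
                  rep((z_src[k] - ctr[3]) * pit[3], nlat))
      p_ <- q_ %*% W
      sx <- p_[, 1] / pit[1] + ctr[1]
      sy <- p_[, 2] / pit[2] + ctr[2]
      sz <- p_[, 3] / pit[3] + ctr[3]
    }
    for (j in seq_along(chi)) {
      vol[, , k, j] <- .trilinear(stack$voxels[, , , chi[j]], sx, sy, sz)
    }
    mask[, , k] <- !is.na(vol[, , k, 1])
  }
  vol[is.na(vol)] <- 0
  if (normalize) {
    mi <- match("marker", stack$channel_roles[chi])
    tot <- if (is.na(mi)) sum(vol) else sum(vol[, , , mi])
    if (tot > 0) vol <- vol / tot
  }
  particle <- structure(list(volume = vol, mask = mask,
                             channels = stack$channel_roles[chi],
                             canonical = canonical,
                             particle_id = annotation$particle_id,
                             transform = tr),
                        class = "standard_centriole")
  list(particle = particle, transform = tr)
}

#' Apply a planar similarity to every plane of a stack
#'
#' Utility for synthetic perturbation experiments: resamples each z plane
#' of every channel under the given [similarity2d()] (about the voxel
#' origin) with cubic-convolution interpolation, zero-filling outside.
#' Interpolation can push values slightly negative near sharp edges; these
#' are clamped to zero to keep the stack valid.
#'
#' @param stack an [image_stack()].
#' @param transform a [similarity2d()].
#' @return the transformed [image_stack()].
#' @export
apply_inplane_similarity <- function(stack, transform) {
  d <- dim(stack$voxels)
  inv <- invert_similarity(transform)
  g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  src <- apply_similarity(inv, as.matrix(g))
  out <- stack$voxels
  for (ch in seq_len(d[4])) for (z in seq_len(d[3])) {
    vals <- .bicubic(stack$voxels[, , z, ch], src[, 1], src[, 2])
    vals[is.na(vals)] <- 0
    out[, , z, ch] <- matrix(pmax(vals, 0), d[1], d[2])
  }
  res <- stack
  res$voxels <- out
  res
}
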