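# Non-averaging measurements: lateral interpeak asymmetry along a line
# profile, centriole length with gel-expansion calibration, and
# background-subtracted focus intensities.  All nm outputs are reported in
# pre-expansion units (divided by the gel coefficient of expansion measured
# for each sample).

#' Extract a multi-channel line profile
#'
#' Bilinear sampling along a user-defined segment on one transverse plane.
#' Positions are expanded-space nm along the segment.
#'
#' @param stack an [image_stack()].
#' @param p1,p2 segment endpoints, `(x, y)` voxel coordinates.
#' @param z plane index.
#' @param channels channel roles or indices; default all.
#' @param n_samples number of samples; default 2 per voxel of segment
#'   length.
#' @return an object of class `line_profile`: `position_nm` (strictly
#'   increasing), one intensity column per channel, `channels`.
#' @export
line_profile <- function(stack, p1, p2, z, channels = NULL,
                         n_samples = NULL) {
  .require_pitch(stack, "line profiles")
  d <- dim(stack$voxels)
  if (is.null(channels)) channels <- seq_len(d[4])
  chi <- vapply(channels, function(ch) .channel_index(stack, ch), integer(1))
  len_vox <- sqrt(sum((p2 - p1)^2))
  if (is.null(n_samples)) n_samples <- max(5L, ceiling(2 * len_vox) + 1L)
  if (n_samples < 5) .stopf("line profile needs >= 5 samples")
  t <- seq(0, 1, length.out = n_samples)
  xs <- p1[1] + t * (p2[1] - p1[1])
  ys <- p1[2] + t * (p2[2] - p1[2])
  z <- round(z)
  if (z < 1 || z > d[3]) .stopf("plane %d outside stack", z)
  ints <- vapply(chi, function(ch) {
    v <- .bilinear(stack$voxels[, , z, ch], xs, ys)
    v[is.na(v)] <- 0
    v
  }, numeric(n_samples))
  structure(list(position_nm = t * len_vox * stack$pitch_lateral_nm,
                 intensity = ints,
                 channels = stack$channel_roles[chi]),
            class = "line_profile")
}

# subpixel peak of a sampled profile: global maximum refined by 3-point
# parabolic interpolation; prominence guarded by a MAD threshold
.refine_peak <- function(pos, y, prominence_mads = 3) {
  i <- which.max(y)
  if (i == 1 || i == length(y))
    .stopf("peak at segment boundary: no parabolic neighborhood")
  baseline <- stats::median(y)
  s <- stats::mad(y)
  if (s > 0 && (y[i] - baseline) < prominence_mads * s)
    .stopf("no peak: prominence below %g MADs", prominence_mads)
  if (s == 0 && y[i] <= baseline)
    .stopf("no peak: flat profile")
  y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
  denom <- y0 - 2 * y1 + y2
  frac <- if (abs(denom) < .Machine$double.eps) 0 else 0.5 * (y0 - y2) / denom
  frac <- max(-0.5, min(0.5, frac))
  dp <- pos[i + 1] - pos[i]
  list(position = pos[i] + frac * dp,
       value = y1 - 0.25 * (y0 - y2) * frac,
       prominence = y1 - baseline)
}

#' Interpeak lateral distance between a protein and the centriole center
#'
#' Measures the lateral asymmetry readout: intensity profiles of the
#' protein channel and the centriole-center channel are extracted along the
#' same segment, each global peak is refined to subpixel position by
#' 3-point parabolic interpolation, and the interpeak distance `d` is the
#' absolute position difference calibrated back to pre-expansion nm.
#'
#' @inheritParams line_profile
#' @param protein_channel,center_channel channel roles or indices.
#' @param expansion_factor gel expansion coefficient; defaults to the
#'   stack's metadata.
#' @return an object of class `interpeak_result`: `d_nm` (pre-expansion),
#'   per-channel subpixel peak positions (expanded nm) and prominences.
#' @export
interpeak_distance <- function(stack, p1, p2, z, protein_channel = "marker",
                               center_channel = "center",
                               expansion_factor = stack$expansion_factor) {
  if (!is.finite(expansion_factor) || expansion_factor <= 1)
    .stopf("interpeak distance needs an expansion calibration (> 1)")
  prof <- line_profile(stack, p1, p2, z,
                       channels = list(protein_channel, center_channel))
  pk_p <- .refine_peak(prof$position_nm, prof$intensity[, 1])
  pk_c <- .refine_peak(prof$position_nm, prof$intensity[, 2])
  structure(list(d_nm = abs(pk_p$position - pk_c$position) / expansion_factor,
                 protein_peak_nm = pk_p$position,
                 center_peak_nm = pk_c$position,
                 prominences = c(protein = pk_p$prominence,
                                 center = pk_c$prominence),
                 expansion_factor = expansion_factor),
            class = "interpeak_result")
}

# axial intensity profile of a channel integrated over the ring annulus
.axial_wall_profile <- function(stack, channel, center, radius,
                                annulus_halfwidth_vox = 2.5) {
  d <- dim(stack$voxels)
  ch <- .channel_index(stack, channel)
  xs <- seq_len(d[1]) - center[1]
  ys <- seq_len(d[2]) - center[2]
  rr <- sqrt(outer(xs^2, ys^2, "+"))
  sel <- abs(rr - radius) <= annulus_halfwidth_vox
  if (!any(sel)) .stopf("empty ring annulus")
  vapply(seq_len(d[3]), function(z) mean(stack$voxels[, , z, ch][sel]),
         numeric(1))
}

# first/last crossing of a threshold, linearly interpolated
.half_crossings <- function(z, y, frac = 0.5) {
  thr <- frac * max(y)
  above <- y >= thr
  if (!any(above) || all(above))
    .stopf("no half-maximum crossing in axial profile")
  i1 <- which(above)[1]
  i2 <- max(which(above))
  up <- if (i1 == 1) z[1] else {
    z[i1 - 1] + (thr - y[i1 - 1]) / (y[i1] - y[i1 - 1]) * (z[i1] - z[i1 - 1])
  }
  down <- if (i2 == length(y)) z[length(y)] else {
    z[i2] + (y[i2] - thr) / (y[i2] - y[i2 + 1]) * (z[i2 + 1] - z[i2])
  }
  c(proximal = up, distal = down)
}

#' Measure centriole length
#'
#' Axial intensity profile of the wall channel integrated over the ring
#' annulus of a verticalized stack.  The proximal end is the proximal
#' half-maximum crossing of the wall staining; the distal end is the distal
#' half-maximum crossing (`mode = "daughter"`, wall extent) or the axial
#' peak of the appendage channel (`mode = "mother"`, wall-proximal-end to
#' distal-appendage distance).  The result is calibrated to pre-expansion
#' nm.
#'
#' @param stack verticalized [image_stack()].
#' @param annotation optional [centriole_annotation()]; supplies the ring
#'   (for the annulus), the z frame and the expansion factor.  Without it
#'   the ring is detected from the wall channel itself.
#' @param mode `"daughter"` or `"mother"`.
#' @param expansion_factor overrides the annotation / stack calibration.
#' @param wall_channel,appendage_channel channel roles or indices.
#' @param threshold_frac half-maximum fraction defining the staining ends.
#' @return length in pre-expansion nm.
#' @export
measure_length <- function(stack, annotation = NULL,
                           mode = c("daughter", "mother"),
                           expansion_factor = NULL,
                           wall_channel = "wall",
                           appendage_channel = "appendage",
                           threshold_frac = 0.5) {
  mode <- match.arg(mode)
  .require_pitch(stack, "length measurement")
  d <- dim(stack$voxels)
  if (is.null(expansion_factor))
    expansion_factor <- if (!is.null(annotation)) annotation$expansion_factor
                        else stack$expansion_factor
  if (!is.finite(expansion_factor) || expansion_factor <= 1)
    .stopf("length measurement needs an expansion calibration (> 1)")
  if (!is.null(annotation)) {
    if (diff(annotation$z_frame) < 1e-9)
      .stopf("degenerate z frame: z_proximal == z_distal")
    fit <- fit_reference_circle(annotation$ring_points)
    center <- fit$center; radius <- fit$radius
  } else {
    ch <- .channel_index(stack, wall_channel)
    mip <- apply(stack$voxels[, , , ch], c(1, 2), max)
    tot <- sum(mip)
    center <- c(sum(seq_len(d[1]) * rowSums(mip)) / tot,
                sum(seq_len(d[2]) * colSums(mip)) / tot)
    xs <- seq_len(d[1]) - center[1]; ys <- seq_len(d[2]) - center[2]
    rr <- sqrt(outer(xs^2, ys^2, "+"))
    rb <- floor(rr) + 1
    rad_prof <- tapply(mip, rb, mean)
    radius <- as.numeric(names(rad_prof)[which.max(rad_prof)]) - 0.5
  }
  zp <- .axial_wall_profile(stack, wall_channel, center, radius)
  z <- seq_len(d[3])
  if (!is.null(annotation)) {
    keep <- z >= floor(annotation$z_frame[1] - 2) &
      z <= ceiling(annotation$z_frame[2] + 2)
    z <- z[keep]; zp <- zp[keep]
  }
  ends <- .half_crossings(z, zp, threshold_frac)
  if (mode == "mother") {
    ap <- .axial_wall_profile(stack, appendage_channel, center, 1.6 * radius,
                              annulus_halfwidth_vox = 3.5)
    apz <- seq_len(d[3])
    pk <- .refine_peak(apz, ap, prominence_mads = 0)
    ends["distal"] <- pk$position
  }
  unname((ends["distal"] - ends["proximal"]) * stack$pitch_axial_nm /
           expansion_factor)
}

#' Background-subtracted focus intensity
#'
#' Sums the intensity in a disk around a focus across the z series and
#' subtracts the local background, estimated as the median intensity of the
#' surrounding annulus times the disk voxel count.  By construction the
#' result is invariant to adding a constant to the whole stack.
#'
#' @param stack an [image_stack()].
#' @param center `(x, y)` voxel center of the focus.
#' @param inner_radius disk radius (voxels).
#' @param outer_radius outer radius of the background annulus (voxels);
#'   must exceed `inner_radius`.
#' @param channel channel role or index.
#' @param z_planes optional plane subset; default all.
#' @return a list: `intensity` (background-subtracted sum), `background`
#'   (median annulus level), `n_voxels`, `clipped` (TRUE when the annulus
#'   ran into the stack boundary).
#' @export
quantify_focus_intensity <- function(stack, center, inner_radius,
                                     outer_radius, channel = 1,
                                     z_planes = NULL) {
  if (outer_radius <= inner_radius)
    .stopf("outer_radius must exceed inner_radius")
  d <- dim(stack$voxels)
  ch <- .channel_index(stack, channel)
  if (is.null(z_planes)) z_planes <- seq_len(d[3])
  xs <- seq_len(d[1]) - center[1]
  ys <- seq_len(d[2]) - center[2]
  rr <- sqrt(outer(xs^2, ys^2, "+"))
  disk <- rr <= inner_radius
  ann <- rr > inner_radius & rr <= outer_radius
  clipped <- (center[1] - outer_radius < 1) || (center[1] + outer_radius > d[1]) ||
    (center[2] - outer_radius < 1) || (center[2] + outer_radius > d[2])
  total <- 0; bg_vals <- NULL
  for (z in z_planes) {
    plane <- stack$voxels[, , z, ch]
    total <- total + sum(plane[disk])
    bg_vals <- c(bg_vals, plane[ann])
  }
  bg <- if (length(bg_vals)) stats::median(bg_vals) else 0
  n_disk <- sum(disk) * length(z_planes)
  list(intensity = total - bg * n_disk, background = bg,
       n_voxels = n_disk, clipped = clipped)
}
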