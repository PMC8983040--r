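# Synthetic U-ExM centriole generator.  Renders expanded-space fluorescence
# stacks of a ninefold triplet cylinder with an asymmetric distal luminal
# marker, optional basal foot / appendage / axial-core channels and an
# optional orthogonal procentriole, then blurs (Gaussian PSF), poses and
# noises them.  Every generated particle carries a ground-truth record so
# downstream stages can be validated without any external data.
#
# Geometry convention: distal view, azimuths counterclockwise from +x;
# the unposed centriole axis is +z with the distal end at +z.

#' Parameters of the synthetic centriole generator
#'
#' Defaults describe a human centrosomal centriole as imaged by U-ExM:
#' triplet ring radius 115 nm and mother length 427 nm pre-expansion, a
#' distal luminal marker enriched on two consecutive triplets with the first
#' labeled 1.5x more than its counterclockwise neighbor, plus a faint
#' full-length wall-associated component on all triplets.  Geometry is
#' rendered in expanded space (gel expansion factor, default 4) on an
#' Airyscan-like grid (30 nm lateral / 100 nm axial voxels, Gaussian PSF of
#' 80 / 200 nm sigma).  Noise is Poisson photon noise plus Gaussian read
#' noise; the default photon scale puts the marker peak at SNR ~ 10.
#'
#' @param ring_radius_nm pre-expansion radius of the triplet ring (nm).
#' @param centriole_length_nm pre-expansion centriole length (nm).
#' @param n_triplets number of wall units (9 for a centriole; any n >= 3).
#' @param marker_azimuth_deg azimuth of triplet 1 (degrees, counterclockwise
#'   in distal view).
#' @param marker_intensity_ratio triplet-1 / triplet-2 marker intensity
#'   (>= 1).
#' @param marker_axial_fraction fraction of the length occupied by the
#'   distal marker (0-1].
#' @param marker_radial_fraction radial position of the luminal marker as a
#'   fraction of the ring radius.
#' @param marker_arc_halfwidth_deg angular half-width of each marker arc.
#' @param marker_triplets,marker_weights triplet indices carrying the
#'   asymmetric marker and their relative intensities; default triplets
#'   `c(1, 2)` with weights `c(marker_intensity_ratio, 1)`.
#' @param wall_component_fraction amplitude of the faint full-length
#'   wall-associated marker component, as a fraction of the triplet-1 peak.
#' @param basal_foot logical; add a basal-foot reference channel.
#' @param basal_foot_azimuth_offset_deg clockwise offset of the basal foot
#'   from the axis opposite the marker (degrees).
#' @param appendage_channel logical; add a distal-appendage ring channel at
#'   the distal end (mother-centriole length measurements).
#' @param center_channel logical; add a symmetric axial-core channel
#'   (centriole-center reference for interpeak profiles).
#' @param procentriole_length_nm pre-expansion procentriole length (nm).
#' @param expansion_factor gel expansion coefficient (> 1).
#' @param voxel_pitch_nm,voxel_pitch_axial_nm expanded-space voxel size (nm).
#' @param psf_sigma_nm,psf_sigma_axial_nm Gaussian PSF sigma, lateral and
#'   axial, expanded space (nm).
#' @param struct_sigma_nm,struct_sigma_axial_nm label/structure spread added
#'   in quadrature to the PSF (nm).
#' @param noise logical; apply Poisson + Gaussian noise.
#' @param photon_scale photons per intensity unit for the Poisson component.
#' @param read_noise_sd additive Gaussian read noise, in photons.
#' @param tilt_deg,tilt_direction_deg pose tilt: angle away from vertical and
#'   azimuth toward which the distal end leans.
#' @param rotation_deg in-plane (about-axis) pose rotation, counterclockwise.
#' @param translation_nm length-3 pose translation (expanded-space nm).
#' @param emitter_spacing_nm spacing of point emitters along rendered
#'   structures (expanded nm); smaller is smoother and slower.
#' @param dims optional fixed stack dimensions `c(nx, ny, nz)`; `NULL` sizes
#'   the stack to the posed geometry.
#' @param seed integer PRNG seed for the noise draw.
#' @return a validated object of class `generator_params`.
#' @export
generator_params <- function(ring_radius_nm = 115,
                             centriole_length_nm = 427,
                             n_triplets = 9L,
                             marker_azimuth_deg = 0,
                             marker_intensity_ratio = 1.5,
                             marker_axial_fraction = 0.25,
                             marker_radial_fraction = 0.8,
                             marker_arc_halfwidth_deg = 8,
                             marker_triplets = NULL,
                             marker_weights = NULL,
                             wall_component_fraction = 0.1,
                             basal_foot = FALSE,
                             basal_foot_azimuth_offset_deg = 25,
                             appendage_channel = FALSE,
                             center_channel = FALSE,
                             procentriole_length_nm = 100,
                             expansion_factor = 4,
                             voxel_pitch_nm = 30,
                             voxel_pitch_axial_nm = 100,
                             psf_sigma_nm = 80,
                             psf_sigma_axial_nm = 200,
                             struct_sigma_nm = 30,
                             struct_sigma_axial_nm = 30,
                             noise = TRUE,
                             photon_scale = 150,
                             read_noise_sd = 2,
                             tilt_deg = 0,
                             tilt_direction_deg = 0,
                             rotation_deg = 0,
                             translation_nm = c(0, 0, 0),
                             emitter_spacing_nm = 15,
                             dims = NULL,
                             seed = 1L) {
  p <- list(ring_radius_nm = ring_radius_nm,
            centriole_length_nm = centriole_length_nm,
            n_triplets = as.integer(n_triplets),
            marker_azimuth_deg = marker_azimuth_deg,
            marker_intensity_ratio = marker_intensity_ratio,
            marker_axial_fraction = marker_axial_fraction,
            marker_radial_fraction = marker_radial_fraction,
            marker_arc_halfwidth_deg = marker_arc_halfwidth_deg,
            marker_triplets = marker_triplets,
            marker_weights = marker_weights,
            wall_component_fraction = wall_component_fraction,
            basal_foot = isTRUE(basal_foot),
            basal_foot_azimuth_offset_deg = basal_foot_azimuth_offset_deg,
            appendage_channel = isTRUE(appendage_channel),
            center_channel = isTRUE(center_channel),
            procentriole_length_nm = procentriole_length_nm,
            expansion_factor = expansion_factor,
            voxel_pitch_nm = voxel_pitch_nm,
            voxel_pitch_axial_nm = voxel_pitch_axial_nm,
            psf_sigma_nm = psf_sigma_nm,
            psf_sigma_axial_nm = psf_sigma_axial_nm,
            struct_sigma_nm = struct_sigma_nm,
            struct_sigma_axial_nm = struct_sigma_axial_nm,
            noise = isTRUE(noise),
            photon_scale = photon_scale,
            read_noise_sd = read_noise_sd,
            tilt_deg = tilt_deg,
            tilt_direction_deg = tilt_direction_deg,
            rotation_deg = rotation_deg,
            translation_nm = as.numeric(translation_nm),
            emitter_spacing_nm = emitter_spacing_nm,
            dims = if (is.null(dims)) NULL else as.integer(dims),
            seed = as.integer(seed))
  class(p) <- "generator_params"
  validate_generator_params(p)
  p
}

#' Validate generator parameters
#'
#' @param params a `generator_params` object.
#' @return the params, invisibly, or an error naming the offending field.
#' @export
validate_generator_params <- function(params) {
  p <- params
  chk <- function(ok, msg, ...) if (!ok) .stopf(paste0("invalid parameter: ", msg), ...)
  chk(p$ring_radius_nm > 0, "ring_radius_nm must be > 0")
  chk(p$centriole_length_nm > 0, "centriole_length_nm must be > 0")
  chk(p$procentriole_length_nm > 0, "procentriole_length_nm must be > 0")
  chk(p$n_triplets >= 3, "n_triplets must be >= 3 (got %d)", p$n_triplets)
  chk(p$marker_intensity_ratio >= 1, "marker_intensity_ratio must be >= 1")
  chk(p$marker_axial_fraction > 0 && p$marker_axial_fraction <= 1,
      "marker_axial_fraction must be in (0, 1]")
  chk(p$expansion_factor > 1, "expansion_factor must be > 1")
  chk(p$voxel_pitch_nm > 0 && p$voxel_pitch_axial_nm > 0,
      "voxel pitches must be > 0")
  chk(p$psf_sigma_nm > 0 && p$psf_sigma_axial_nm > 0, "PSF sigmas must be > 0")
  chk(p$photon_scale > 0, "photon_scale must be > 0")
  chk(p$read_noise_sd >= 0, "read_noise_sd must be >= 0")
  chk(p$emitter_spacing_nm > 0, "emitter_spacing_nm must be > 0")
  chk(length(p$translation_nm) == 3, "translation_nm must have length 3")
  if (!is.null(p$marker_triplets)) {
    chk(length(p$marker_triplets) == length(p$marker_weights),
        "marker_triplets and marker_weights lengths differ")
    chk(all(p$marker_triplets >= 1 & p$marker_triplets <= p$n_triplets),
        "marker_triplets must index 1..n_triplets")
  }
  if (!is.null(p$dims)) chk(length(p$dims) == 3 && all(p$dims >= 4),
                            "dims must be three values >= 4")
  invisible(params)
}

#' Preset generator parameter sets
#'
#' `"centriole"` is a centrosomal centriole with the default two-triplet
#' marker; `"diplosome"` is the same parent geometry intended for
#' [generate_diplosome()]; `"mcc"` emulates a multiciliated-cell basal body:
#' a basal-foot reference channel offset 25 degrees clockwise from the axis
#' opposite the marker, and marker mass spread over triplets 9, 1 and 2
#' (brightest on 1).
#'
#' @param preset one of `"centriole"`, `"diplosome"`, `"mcc"`.
#' @param ... overrides passed to [generator_params()].
#' @return a `generator_params` object.
#' @export
preset_params <- function(preset = c("centriole", "diplosome", "mcc"), ...) {
  preset <- match.arg(preset)
  over <- list(...)
  base <- switch(preset,
    centriole = list(),
    diplosome = list(),
    mcc = list(basal_foot = TRUE,
               marker_triplets = c(1L, 2L, 9L),
               marker_weights = c(1.5, 1.0, 0.7)))
  do.call(generator_params, utils::modifyList(base, over))
}

# resolved marker triplet/weight sets
.marker_spec <- function(p) {
  if (is.null(p$marker_triplets)) {
    list(triplets = c(1L, 2L), weights = c(p$marker_intensity_ratio, 1))
  } else {
    list(triplets = as.integer(p$marker_triplets), weights = p$marker_weights)
  }
}

# channel layout for a parameter set
.channel_roles <- function(p) {
  roles <- c("wall", "marker")
  if (p$basal_foot) roles <- c(roles, "reference")
  if (p$appendage_channel) roles <- c(roles, "appendage")
  if (p$center_channel) roles <- c(roles, "center")
  roles
}

# Emitter table for one (unposed) centriole, coordinates in expanded nm
# centered on the centriole mid-point.  Emitter amplitudes are normalized so
# that extended structures render with peak intensity close to the nominal
# channel amplitude (rod interiors exactly, short arcs attenuated by the PSF).
.centriole_emitters <- function(p, length_nm = p$centriole_length_nm) {
  ex <- p$expansion_factor
  R <- p$ring_radius_nm * ex
  L <- length_nm * ex
  ds <- p$emitter_spacing_nm
  sx <- sqrt(p$psf_sigma_nm^2 + p$struct_sigma_nm^2)
  sz <- sqrt(p$psf_sigma_axial_nm^2 + p$struct_sigma_axial_nm^2)
  roles <- .channel_roles(p)
  ch_of <- function(role) match(role, roles)
  tri_az <- norm_angle(p$marker_azimuth_deg +
                         (seq_len(p$n_triplets) - 1) * 360 / p$n_triplets)
  rod_amp <- ds / (sqrt(2 * pi) * sz)   # line-density normalization along z
  zs <- seq(-L / 2, L / 2, by = ds)

  out <- list()
  add <- function(x, y, z, amp, ch, sxe = sx, sze = sz) {
    out[[length(out) + 1L]] <<- data.frame(x = x, y = y, z = z, amp = amp,
                                           ch = ch, sx = sxe, sz = sze)
  }

  # wall: n rods of equal intensity on the ring
  for (az in tri_az) {
    t <- .deg2rad(az)
    add(rep(R * cos(t), length(zs)), rep(R * sin(t), length(zs)), zs,
        rep(rod_amp, length(zs)), ch_of("wall"))
  }

  # marker: luminal arcs on the stated triplets, distal axial window
  ms <- .marker_spec(p)
  rm_ <- p$marker_radial_fraction * R
  z_hi <- L / 2
  z_lo <- L / 2 - p$marker_axial_fraction * L
  zm <- seq(z_lo, z_hi, by = ds)
  d_ang <- .rad2deg(ds / max(rm_, ds))   # on-axis markers collapse to a point
  arc_amp <- ds / (sqrt(2 * pi) * sx)   # tangential line-density factor
  for (i in seq_along(ms$triplets)) {
    az0 <- tri_az[ms$triplets[i]]
    angs <- seq(az0 - p$marker_arc_halfwidth_deg,
                az0 + p$marker_arc_halfwidth_deg, by = d_ang)
    t <- .deg2rad(angs)
    grid <- expand.grid(a = seq_along(t), z = zm)
    add(rm_ * cos(t)[grid$a], rm_ * sin(t)[grid$a], grid$z,
        rep(ms$weights[i] * arc_amp * rod_amp, nrow(grid)),
        ch_of("marker"))
  }

  # faint full-length wall-associated marker component on all triplets
  if (p$wall_component_fraction > 0) {
    fa <- p$wall_component_fraction * max(ms$weights)
    for (az in tri_az) {
      t <- .deg2rad(az)
      add(rep(R * cos(t), length(zs)), rep(R * sin(t), length(zs)), zs,
          rep(fa * rod_amp, length(zs)), ch_of("marker"))
    }
  }

  # basal foot: lateral lobe at mid-height, clockwise offset from the axis
  # opposite the marker
  if (p$basal_foot) {
    bf_az <- norm_angle(p$marker_azimuth_deg + 180 -
                          p$basal_foot_azimuth_offset_deg)
    t <- .deg2rad(bf_az)
    bf_r <- 1.5 * R
    add(bf_r * cos(t), bf_r * sin(t), 0, 1,
        ch_of("reference"),
        sxe = sqrt(sx^2 + 60^2), sze = sqrt(sz^2 + 60^2))
  }

  # distal appendage ring at the distal end
  if (p$appendage_channel) {
    ra <- 1.6 * R
    angs <- seq(0, 360 - .rad2deg(ds / ra), by = .rad2deg(ds / ra))
    t <- .deg2rad(angs)
    add(ra * cos(t), ra * sin(t), rep(L / 2, length(t)),
        rep(ds / (sqrt(2 * pi) * sx), length(t)), ch_of("appendage"))
  }

  # symmetric axial core (centriole-center reference)
  if (p$center_channel) {
    add(rep(0, length(zs)), rep(0, length(zs)), zs,
        rep(rod_amp, length(zs)), ch_of("center"))
  }

  em <- do.call(rbind, out)
  attr(em, "triplet_azimuths_deg") <- tri_az
  em
}

# pose rotation matrix: in-plane rotation about z, then tilt of the axis
# toward azimuth tilt_direction_deg
.pose_rotation <- function(p) {
  Rz <- .rot_z(p$rotation_deg)
  tilt_axis <- c(-sin(.deg2rad(p$tilt_direction_deg)),
                 cos(.deg2rad(p$tilt_direction_deg)), 0)
  Rt <- .rot_axis(tilt_axis, p$tilt_deg)
  Rt %*% Rz
}

.pose_points <- function(em, Rm, translation_nm) {
  xyz <- t(Rm %*% t(as.matrix(em[, c("x", "y", "z")])))
  em$x <- xyz[, 1] + translation_nm[1]
  em$y <- xyz[, 2] + translation_nm[2]
  em$z <- xyz[, 3] + translation_nm[3]
  em
}

# stack dimensions fitting the posed emitters (odd sizes; integer center voxel)
.auto_dims <- function(em, p) {
  mlat <- 3.5 * max(em$sx) + 2 * p$voxel_pitch_nm
  max_ <- 3.5 * max(em$sz) + 2 * p$voxel_pitch_axial_nm
  hx <- max(abs(em$x)) + mlat
  hy <- max(abs(em$y)) + mlat
  hz <- max(abs(em$z)) + max_
  n_of <- function(h, pitch) 2L * as.integer(ceiling(h / pitch)) + 1L
  c(n_of(max(hx, hy), p$voxel_pitch_nm), n_of(max(hx, hy), p$voxel_pitch_nm),
    n_of(hz, p$voxel_pitch_axial_nm))
}

.check_extent <- function(em, p, dims) {
  cx <- (dims + 1) / 2
  half <- (dims - 1) / 2 * c(p$voxel_pitch_nm, p$voxel_pitch_nm,
                             p$voxel_pitch_axial_nm)
  lim <- c(max(abs(em$x)) + 3 * max(em$sx),
           max(abs(em$y)) + 3 * max(em$sx),
           max(abs(em$z)) + 3 * max(em$sz))
  bad <- which(lim > half)
  if (length(bad))
    .stopf("stack extent too small for the posed centriole along axis %s",
           paste(c("x", "y", "z")[bad], collapse = ", "))
  invisible(cx)
}

# Gaussian splatting of point emitters into a (nx, ny, nz, nc) volume.
# Emitters sharing the same lateral position and widths (the z samples of a
# vertical rod) are collapsed into one lateral kernel times a summed axial
# profile, which makes the common untilted render an order of magnitude
# cheaper than per-point splatting; tilted poses fall back to singleton
# groups transparently.
.render_emitters <- function(em, dims, p, n_channels) {
  vol <- array(0, c(dims, n_channels))
  cx <- (dims[1] + 1) / 2; cy <- (dims[2] + 1) / 2; cz <- (dims[3] + 1) / 2
  px <- p$voxel_pitch_nm; pz <- p$voxel_pitch_axial_nm
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  key <- paste(em$ch, em$x, em$y, em$sx, em$sz, sep = "|")
  for (g in split(seq_len(nrow(em)), key)) {
    xv <- em$x[g[1]] / px + cx; yv <- em$y[g[1]] / px + cy
    sxv <- em$sx[g[1]] / px; szv <- em$sz[g[1]] / pz
    zv <- em$z[g] / pz + cz
    rx <- ceiling(3 * sxv); rz <- ceiling(3 * szv)
    ix <- max(1, floor(xv - rx)):min(nx, ceiling(xv + rx))
    iy <- max(1, floor(yv - rx)):min(ny, ceiling(yv + rx))
    iz <- max(1, floor(min(zv) - rz)):min(nz, ceiling(max(zv) + rz))
    if (!length(ix) || !length(iy) || !length(iz)) next
    gx <- exp(-0.5 * ((ix - xv) / sxv)^2)
    gy <- exp(-0.5 * ((iy - yv) / sxv)^2)
    gz <- as.numeric(exp(-0.5 * (outer(iz, zv, "-") / szv)^2) %*% em$amp[g])
    ch <- em$ch[g[1]]
    vol[ix, iy, iz, ch] <- vol[ix, iy, iz, ch] + gx %o% gy %o% gz
  }
  vol
}

# Poisson photon noise plus Gaussian read noise, clamped at zero
.apply_noise <- function(vol, p) {
  n <- length(vol)
  photons <- stats::rpois(n, lambda = as.numeric(vol) * p$photon_scale)
  noisy <- (photons + stats::rnorm(n, 0, p$read_noise_sd)) / p$photon_scale
  array(pmax(noisy, 0), dim(vol))
}

# assemble the ground-truth record shared by single centrioles and diplosomes
.make_truth <- function(p, em, Rm, dims, vol_clean) {
  ex <- p$expansion_factor
  L <- p$centriole_length_nm * ex
  tri_az <- attr(em, "triplet_azimuths_deg")
  ms <- .marker_spec(p)
  cm <- .circ_stats(tri_az[ms$triplets], ms$weights)
  t_vert <- as.numeric(t(.pose_rotation(list(rotation_deg = 0,
                                             tilt_direction_deg = p$tilt_direction_deg,
                                             tilt_deg = p$tilt_deg))) %*%
                         p$translation_nm)
  cz <- (dims[3] + 1) / 2
  roles <- .channel_roles(p)
  peaks <- vapply(seq_along(roles),
                  function(ch) max(vol_clean[, , , ch]), numeric(1))
  names(peaks) <- roles
  structure(list(
    params = unclass(p),
    axis_vector = as.numeric(Rm %*% c(0, 0, 1)),
    triplet_azimuths_deg = tri_az,
    marker_centroid_azimuth_deg = cm$mean,
    marker_triplets = ms$triplets,
    marker_weights = ms$weights,
    ring_center_vox = c((dims[1] + 1) / 2 + t_vert[1] / p$voxel_pitch_nm,
                        (dims[2] + 1) / 2 + t_vert[2] / p$voxel_pitch_nm),
    ring_radius_vox = p$ring_radius_nm * ex / p$voxel_pitch_nm,
    z_range = c(proximal = cz + (t_vert[3] - L / 2) / p$voxel_pitch_axial_nm,
                distal = cz + (t_vert[3] + L / 2) / p$voxel_pitch_axial_nm),
    vert_translation_nm = t_vert,
    channel_peaks = peaks,
    dims = dims,
    seed = p$seed,
    warnings = character(0)),
    class = "ground_truth")
}

#' Generate a synthetic centriole stack with ground truth
#'
#' Renders the triplet wall, the asymmetric distal luminal marker and any
#' optional channels as Gaussian-blurred point emitters, applies the pose,
#' then (optionally) Poisson + Gaussian noise.  The returned ground truth
#' records the generative geometry: unposed triplet azimuths, the
#' amplitude-weighted marker centroid azimuth, the posed axis vector, and
#' the ring center / radius and axial frame in the verticalized stack frame
#' (the frame obtained by undoing the tilt only, which is where annotations
#' are defined).
#'
#' @param params a [generator_params()] object.
#' @return a list with elements `stack` ([image_stack()]) and `truth`
#'   (`ground_truth`).
#' @export
generate_centriole <- function(params) {
  validate_generator_params(params)
  p <- params
  em <- .centriole_emitters(p)
  Rm <- .pose_rotation(p)
  tri_az <- attr(em, "triplet_azimuths_deg")
  emp <- .pose_points(em, Rm, p$translation_nm)
  attr(emp, "triplet_azimuths_deg") <- tri_az
  dims <- if (is.null(p$dims)) .auto_dims(emp, p) else p$dims
  .check_extent(emp, p, dims)
  roles <- .channel_roles(p)
  vol <- .render_emitters(emp, dims, p, length(roles))
  truth <- .make_truth(p, emp, Rm, dims, vol)
  if (p$noise) {
    set.seed(p$seed)
    vol <- .apply_noise(vol, p)
  }
  stack <- image_stack(vol, pitch_lateral_nm = p$voxel_pitch_nm,
                       pitch_axial_nm = p$voxel_pitch_axial_nm,
                       channel_roles = roles, view_convention = "distal",
                       expansion_factor = p$expansion_factor)
  list(stack = stack, truth = truth)
}

#' Generate an orthogonal centriole pair (diplosome)
#'
#' The parent is rendered as in [generate_centriole()]; the procentriole
#' (default 100 nm pre-expansion) is rendered orthogonal to the parent long
#' axis, attached at the stated azimuth near the parent's proximal end, with
#' its own distal marker at `procentriole_marker_azimuth_deg` measured around
#' the procentriole axis starting from the parent long-axis (distal)
#' direction.
#'
#' @param params parent [generator_params()].
#' @param procentriole_azimuth_deg azimuth of the attachment site around the
#'   parent (degrees, counterclockwise in distal view); values outside
#'   `[0, 360)` are normalized.
#' @param procentriole_marker_azimuth_deg azimuth of the procentriole marker
#'   about the procentriole axis, from the parent distal direction.
#' @param contact_gap_nm expanded-space gap between the parent wall and the
#'   proximal end of the procentriole; gaps below 20 nm flag a
#'   geometry-overlap warning in the ground truth.
#' @return list with `stack` and `truth`; the truth gains
#'   `procentriole_azimuth_deg`, `procentriole_marker_azimuth_deg` and
#'   `procentriole_axis`.
#' @export
generate_diplosome <- function(params, procentriole_azimuth_deg,
                               procentriole_marker_azimuth_deg = 0,
                               contact_gap_nm = 40) {
  validate_generator_params(params)
  p <- params
  phi <- norm_angle(procentriole_azimuth_deg)
  psi <- norm_angle(procentriole_marker_azimuth_deg)
  ex <- p$expansion_factor
  R <- p$ring_radius_nm * ex
  L <- p$centriole_length_nm * ex
  Lp <- p$procentriole_length_nm * ex

  em_parent <- .centriole_emitters(p)
  tri_az <- attr(em_parent, "triplet_azimuths_deg")

  # procentriole rendered in its own frame, then mapped: its axis ez points
  # radially outward at azimuth phi, and azimuth zero about that axis is the
  # parent distal (+z) direction
  pp <- p
  pp$marker_azimuth_deg <- psi
  pp$basal_foot <- FALSE; pp$appendage_channel <- FALSE
  pp$center_channel <- FALSE
  pp$marker_axial_fraction <- min(1, p$marker_axial_fraction * 2)
  em_pro <- .centriole_emitters(pp, length_nm = p$procentriole_length_nm)
  em_pro <- em_pro[em_pro$ch <= 2, ]    # wall + marker only
  t <- .deg2rad(phi)
  ez <- c(cos(t), sin(t), 0)
  ex_ <- c(0, 0, 1)
  ey <- c(sin(t), -cos(t), 0)
  M <- cbind(ex_, ey, ez)
  xyz <- t(M %*% t(as.matrix(em_pro[, c("x", "y", "z")])))
  d_center <- R + contact_gap_nm + Lp / 2
  offset <- ez * d_center + c(0, 0, -L / 2 + R)
  em_pro$x <- xyz[, 1] + offset[1]
  em_pro$y <- xyz[, 2] + offset[2]
  em_pro$z <- xyz[, 3] + offset[3]

  em <- rbind(em_parent, em_pro)
  attr(em, "triplet_azimuths_deg") <- tri_az
  Rm <- .pose_rotation(p)
  emp <- .pose_points(em, Rm, p$translation_nm)
  attr(emp, "triplet_azimuths_deg") <- tri_az
  dims <- if (is.null(p$dims)) .auto_dims(emp, p) else p$dims
  .check_extent(emp, p, dims)
  roles <- .channel_roles(p)
  vol <- .render_emitters(emp, dims, p, length(roles))
  truth <- .make_truth(p, emp, Rm, dims, vol)
  truth$procentriole_azimuth_deg <- phi
  truth$procentriole_marker_azimuth_deg <- psi
  truth$procentriole_axis <- as.numeric(Rm %*% ez)
  truth$procentriole_length_nm <- p$procentriole_length_nm
  if (contact_gap_nm < 20)
    truth$warnings <- c(truth$warnings, "procentriole-parent wall contact below tolerance")
  if (p$noise) {
    set.seed(p$seed)
    vol <- .apply_noise(vol, p)
  }
  stack <- image_stack(vol, pitch_lateral_nm = p$voxel_pitch_nm,
                       pitch_axial_nm = p$voxel_pitch_axial_nm,
                       channel_roles = roles, view_convention = "distal",
                       expansion_factor = p$expansion_factor)
  list(stack = stack, truth = truth)
}

#' Add microscope noise to a rendered stack
#'
#' Applies the generator's noise model — Poisson photon noise at the given
#' photon scale plus Gaussian read noise, clamped at zero — to an existing
#' (typically noiseless) stack.  Useful for pairing a noiseless render with
#' noisy realizations of the same geometry.
#'
#' @param stack an [image_stack()].
#' @param photon_scale photons per intensity unit.
#' @param read_noise_sd Gaussian read noise SD, photons.
#' @param seed PRNG seed.
#' @return the noisy [image_stack()].
#' @export
add_noise <- function(stack, photon_scale = 150, read_noise_sd = 2, seed = 1L) {
  stopifnot(inherits(stack, "image_stack"), photon_scale > 0,
            read_noise_sd >= 0)
  set.seed(seed)
  res <- stack
  res$voxels <- .apply_noise(stack$voxels,
                             list(photon_scale = photon_scale,
                                  read_noise_sd = read_noise_sd))
  res
}

#' Default cohort jitter specification
#'
#' @param in_plane_rotation `"uniform"` draws the in-plane pose rotation
#'   uniformly on `[0, 360)`; `"none"` keeps the base value.
#' @param tilt_sd_deg SD of the pose tilt (degrees, half-normal).
#' @param length_sd_nm SD of the pre-expansion centriole length (nm).
#' @param radius_sd_frac fractional SD of the ring radius.
#' @param intensity_sd_frac fractional SD of a global intensity factor
#'   (applied to the marker weights).
#' @param translation_sd_nm SD of lateral pose translation (expanded nm).
#' @return a list understood by [generate_cohort()].
#' @export
cohort_jitter <- function(in_plane_rotation = c("uniform", "none"),
                          tilt_sd_deg = 0, length_sd_nm = 0,
                          radius_sd_frac = 0, intensity_sd_frac = 0,
                          translation_sd_nm = 0) {
  list(in_plane_rotation = match.arg(in_plane_rotation),
       tilt_sd_deg = tilt_sd_deg, length_sd_nm = length_sd_nm,
       radius_sd_frac = radius_sd_frac, intensity_sd_frac = intensity_sd_frac,
       translation_sd_nm = translation_sd_nm)
}

#' Generate a cohort of jittered synthetic centrioles
#'
#' Draws `n` independent particles around `base_params`.  Per-particle seeds
#' derive deterministically from the master seed (see the splitting scheme in
#' the package internals), so any particle can be regenerated in isolation.
#'
#' @param base_params a [generator_params()] object.
#' @param n number of particles (>= 1).
#' @param jitter a [cohort_jitter()] list of per-parameter spreads.
#' @param seed master seed; defaults to `base_params$seed`.
#' @return a list of `n` elements, each `list(stack, truth)`, with a
#'   `cohort_index` attribute (data.frame of per-particle draws).
#' @export
generate_cohort <- function(base_params, n, jitter = cohort_jitter(),
                            seed = base_params$seed) {
  stopifnot(n >= 1)
  bad <- vapply(jitter[-1], function(x) x < 0, logical(1))
  if (any(bad)) .stopf("jitter SDs must be >= 0")
  out <- vector("list", n)
  idx <- data.frame(particle_id = sprintf("p%03d", seq_len(n)),
                    rotation_deg = NA_real_, tilt_deg = NA_real_,
                    length_nm = NA_real_, ring_radius_nm = NA_real_,
                    intensity_factor = NA_real_, seed = NA_integer_)
  for (i in seq_len(n)) {
    si <- .derive_seed(seed, i)
    set.seed(si)
    pi_ <- base_params
    if (jitter$in_plane_rotation == "uniform")
      pi_$rotation_deg <- stats::runif(1, 0, 360)
    if (jitter$tilt_sd_deg > 0) {
      pi_$tilt_deg <- abs(stats::rnorm(1, 0, jitter$tilt_sd_deg))
      pi_$tilt_direction_deg <- stats::runif(1, 0, 360)
    }
    if (jitter$length_sd_nm > 0)
      pi_$centriole_length_nm <-
        max(50, stats::rnorm(1, base_params$centriole_length_nm, jitter$length_sd_nm))
    if (jitter$radius_sd_frac > 0)
      pi_$ring_radius_nm <-
        base_params$ring_radius_nm * max(0.2, stats::rnorm(1, 1, jitter$radius_sd_frac))
    fint <- 1
    if (jitter$intensity_sd_frac > 0) {
      fint <- max(0.1, stats::rnorm(1, 1, jitter$intensity_sd_frac))
      ms <- .marker_spec(pi_)
      pi_$marker_triplets <- ms$triplets
      pi_$marker_weights <- ms$weights * fint
    }
    if (jitter$translation_sd_nm > 0)
      pi_$translation_nm <- c(stats::rnorm(2, 0, jitter$translation_sd_nm), 0)
    pi_$seed <- .derive_seed(si, 7919L)
    out[[i]] <- generate_centriole(pi_)
    out[[i]]$truth$particle_id <- idx$particle_id[i]
    idx$rotation_deg[i] <- pi_$rotation_deg
    idx$tilt_deg[i] <- pi_$tilt_deg
    idx$length_nm[i] <- pi_$centriole_length_nm
    idx$ring_radius_nm[i] <- pi_$ring_radius_nm
    idx$intensity_factor[i] <- fint
    idx$seed[i] <- pi_$seed
  }
  attr(out, "cohort_index") <- idx
  out
}
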