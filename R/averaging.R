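# Mask-aware particle averaging on the canonical grid, and the azimuthal
# profile that turns the average into the per-triplet readout (which triplet
# carries the marker, and how much more than its neighbors).

#' Average standardized centrioles
#'
#' Voxelwise mean and SD over particles, honoring each particle's validity
#' mask: a canonical voxel only accumulates particles whose source data
#' covered it.  Moments are accumulated with Welford's one-pass update, so
#' the SD is numerically stable at any cohort size.
#'
#' @param particles list of `standard_centriole` objects on one canonical
#'   grid (see [standardize()]).
#' @param channels optional subset of channel roles to average.
#' @return an object of class `average_model`: `mean`, `sd`, `count`
#'   arrays, `n_particles`, `particle_ids`, `channels`, `canonical`,
#'   `reference_mode`.
#' @export
average_standardized <- function(particles, channels = NULL) {
  if (length(particles) < 1) .stopf("need at least one particle")
  ref <- particles[[1]]
  dref <- dim(ref$volume)
  if (is.null(channels)) channels <- ref$channels
  chi <- match(channels, ref$channels)
  if (anyNA(chi)) .stopf("channel '%s' absent from particles",
                         channels[which(is.na(chi))[1]])
  dd <- c(dref[1:3], length(chi))
  n_arr <- array(0, dref[1:3])
  mean_arr <- array(0, dd)
  m2_arr <- array(0, dd)
  ids <- character(length(particles))
  for (i in seq_along(particles)) {
    p <- particles[[i]]
    if (!identical(dim(p$volume)[1:3], dref[1:3]) ||
        !identical(p$channels, ref$channels))
      .stopf("particle '%s' is not on the shared canonical grid",
             if (is.null(p$particle_id)) as.character(i) else p$particle_id)
    ids[i] <- if (is.null(p$particle_id)) sprintf("particle_%d", i) else p$particle_id
    m <- p$mask
    n_arr <- n_arr + m
    for (j in seq_along(chi)) {
      x <- p$volume[, , , chi[j]]
      delta <- x - mean_arr[, , , j]
      upd <- ifelse(n_arr > 0, delta / pmax(n_arr, 1), 0) * m
      mean_arr[, , , j] <- mean_arr[, , , j] + upd
      m2_arr[, , , j] <- m2_arr[, , , j] + delta * (x - mean_arr[, , , j]) * m
    }
  }
  sd_arr <- m2_arr
  for (j in seq_along(chi)) {
    v <- ifelse(n_arr > 1, m2_arr[, , , j] / pmax(n_arr - 1, 1), 0)
    sd_arr[, , , j] <- sqrt(pmax(v, 0))
    mean_arr[, , , j][n_arr == 0] <- NA_real_
  }
  structure(list(mean = mean_arr, sd = sd_arr, count = n_arr,
                 n_particles = length(particles), particle_ids = ids,
                 channels = ref$channels[chi], canonical = ref$canonical,
                 reference_mode = ref$transform$reference_mode),
            class = "average_model")
}

#' @export
print.average_model <- function(x, ...) {
  cat(sprintf("<average_model> %d particles, channels [%s], grid %s\n",
              x$n_particles, paste(x$channels, collapse = ", "),
              paste(dim(x$mean)[1:3], collapse = " x ")))
  invisible(x)
}

#' Azimuthal intensity profile of an average model
#'
#' Mean intensity per angular bin within a radial annulus (default
#' 0.6-1.0 of the canonical radius, the luminal side of the wall) and an
#' axial window (default the distal 30%).  The peak azimuth is the circular
#' centroid of the contiguous top-bin cluster (bins above half the maximum
#' containing the global maximum), and each bin is assigned to its nearest
#' triplet so per-triplet masses and the top-triplet set can be read off.
#'
#' Triplet numbering follows the distal-view counterclockwise convention:
#' with `numbering = "peak"` triplet 1 is anchored at the recovered peak
#' azimuth (numbered counterclockwise from the marker signal); with
#' `"reference"` triplet 1 sits at the canonical 0-degree azimuth.
#'
#' @param model an [average_standardized()] result.
#' @param channel channel role or index to profile (default `"marker"`).
#' @param annulus radial window as fractions of the canonical radius.
#' @param axial_window axial window as fractions of the canonical frame
#'   (0 proximal, 1 distal).
#' @param bin_deg angular bin width, degrees.
#' @param n_triplets triplet count for index assignment.
#' @param numbering `"peak"` or `"reference"` (see above).
#' @param stability_threshold minimal circular resultant of the bin-weight
#'   distribution below which the peak azimuth is flagged unstable.
#' @return an object of class `azimuthal_profile`: `angle_deg`,
#'   `mean_intensity`, `peak_azimuth_deg`, `peak_triplet`,
#'   `triplet_azimuths_deg`, `triplet_mass`, `top_triplets`, `stable`.
#' @export
azimuthal_profile <- function(model, channel = "marker",
                              annulus = c(0.6, 1.0),
                              axial_window = c(0.7, 1.0), bin_deg = 1,
                              n_triplets = 9L,
                              numbering = c("peak", "reference"),
                              stability_threshold = 0.05) {
  numbering <- match.arg(numbering)
  stopifnot(inherits(model, "average_model"))
  j <- match(channel, model$channels)
  if (is.na(j)) j <- as.integer(channel)
  can <- model$canonical
  G <- can$grid_xy; K <- dim(model$mean)[3]
  xs <- seq_len(G) - can$center[1]
  ys <- seq_len(G) - can$center[2]
  rr <- sqrt(outer(xs^2, ys^2, "+"))
  az <- norm_angle(.rad2deg(atan2(rep(ys, each = G), rep(xs, G))))
  dim(az) <- c(G, G)
  r_in <- annulus[1] * can$radius_vox
  r_out <- annulus[2] * can$radius_vox
  sel_lat <- rr >= r_in & rr <= r_out
  if (!any(sel_lat)) .stopf("empty annulus")
  z_lo <- max(1L, ceiling(axial_window[1] * (K - 1) + 1))
  z_hi <- min(K, floor(axial_window[2] * (K - 1) + 1))
  if (z_hi < z_lo) .stopf("empty axial window")

  nb <- as.integer(round(360 / bin_deg))
  bin_of <- pmin(nb, floor(az[sel_lat] / (360 / nb)) + 1L)
  sub <- model$mean[, , z_lo:z_hi, j, drop = FALSE]
  m <- matrix(sub, G * G, z_hi - z_lo + 1L)[which(sel_lat), , drop = FALSE]
  tot <- rowSums(m, na.rm = TRUE)
  nok <- rowSums(!is.na(m))
  rs <- rowsum(cbind(tot, nok), bin_of)
  sums <- numeric(nb); cnts <- numeric(nb)
  present <- as.integer(rownames(rs))
  sums[present] <- rs[, 1]; cnts[present] <- rs[, 2]
  prof <- ifelse(cnts > 0, sums / cnts, NA_real_)
  centers <- (seq_len(nb) - 0.5) * 360 / nb
  # narrow bins can be geometrically empty on a discrete annulus; fill them
  # by circular linear interpolation from their populated neighbors
  if (anyNA(prof)) {
    ok <- which(!is.na(prof))
    if (!length(ok)) .stopf("no populated angular bins in annulus")
    prof <- stats::approx(c(centers[ok] - 360, centers[ok], centers[ok] + 360),
                          rep(prof[ok], 3), xout = centers)$y
  }

  # peak: circular centroid of the contiguous above-half-max cluster that
  # contains the global maximum
  pk <- which.max(prof)
  half <- prof[pk] / 2
  above <- !is.na(prof) & prof >= half
  cl <- rep(FALSE, nb)
  i <- pk
  repeat { cl[i] <- TRUE; i <- if (i == 1) nb else i - 1; if (!above[i] || cl[i]) break }
  i <- pk %% nb + 1
  while (above[i] && !cl[i]) { cl[i] <- TRUE; i <- i %% nb + 1 }
  pcs <- .circ_stats(centers[cl], prof[cl])
  peak_az <- pcs$mean
  # a near-symmetric profile has no defined cluster centroid; anchor at the
  # argmax bin (the stability flag below marks the peak as unreliable)
  if (!is.finite(peak_az)) peak_az <- centers[pk]

  # stability: resultant of the full bin-weight distribution
  w <- prof - min(prof, na.rm = TRUE)
  w[is.na(w)] <- 0
  stable <- .circ_stats(centers, w)$R >= stability_threshold

  tri_az <- if (numbering == "peak") {
    norm_angle(peak_az + (seq_len(n_triplets) - 1) * 360 / n_triplets)
  } else {
    (seq_len(n_triplets) - 1) * 360 / n_triplets
  }
  dmat <- abs(outer(centers, tri_az, .circ_diff))
  nearest <- max.col(-dmat)
  mass <- vapply(seq_len(n_triplets),
                 function(t) sum(prof[nearest == t], na.rm = TRUE), numeric(1))
  peak_triplet <- nearest[pk]
  structure(list(angle_deg = centers, mean_intensity = prof,
                 bin_counts = cnts,
                 peak_azimuth_deg = peak_az, peak_triplet = peak_triplet,
                 triplet_azimuths_deg = tri_az, triplet_mass = mass,
                 top_triplets = order(mass, decreasing = TRUE)[seq_len(min(3, n_triplets))],
                 stable = stable, annulus = annulus,
                 axial_window = axial_window),
            class = "azimuthal_profile")
}

#' Marker enhancement ratio between two triplets
#'
#' Ratio of baseline-subtracted bin means at two triplet positions.  The
#' baseline is the median of the azimuthal profile, which estimates the
#' rotationally symmetric component (the faint full-length wall-associated
#' staining present on all triplets); subtracting it isolates the
#' asymmetric marker enhancement whose triplet-to-triplet ratio is the
#' quantity of interest.
#'
#' @param profile an [azimuthal_profile()].
#' @param triplet_a,triplet_b triplet indices to compare (numerator /
#'   denominator).
#' @param window_deg angular half-window around each triplet azimuth.
#' @return the enhancement ratio (dimensionless).
#' @export
marker_enhancement_ratio <- function(profile, triplet_a = 1, triplet_b = 2,
                                     window_deg = 12) {
  tb <- triplet_bin_means(profile, window_deg)
  base <- stats::median(profile$mean_intensity, na.rm = TRUE)
  num <- tb[triplet_a] - base
  den <- tb[triplet_b] - base
  if (!is.finite(den) || den <= 0)
    .stopf("triplet %d has no enhancement above baseline", triplet_b)
  unname(num / den)
}

#' Mean intensity at each triplet position
#'
#' Convenience readout: the azimuthal-profile bin means averaged over a
#' window around each triplet azimuth (default +/- half the inter-triplet
#' spacing, i.e. nearest-triplet assignment).
#'
#' @param profile an [azimuthal_profile()].
#' @param window_deg half-width of the angular window around each triplet.
#' @return named numeric vector of per-triplet mean bin intensities.
#' @export
triplet_bin_means <- function(profile, window_deg = 12) {
  tri <- profile$triplet_azimuths_deg
  out <- vapply(seq_along(tri), function(t) {
    sel <- abs(.circ_diff(profile$angle_deg, tri[t])) <= window_deg
    mean(profile$mean_intensity[sel], na.rm = TRUE)
  }, numeric(1))
  names(out) <- as.character(seq_along(tri))
  out
}
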