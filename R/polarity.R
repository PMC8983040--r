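# Angular statistics of rotational polarity: relative angles under an
# explicit chirality convention, quadrant binning with a Pearson chi-squared
# test against uniformity, circular summaries (including the axial,
# angle-doubled summary for bimodal alignment), two-sample
# Kolmogorov-Smirnov comparison, and Monte-Carlo calibration of the
# quadrant test.

#' Relative angle under an explicit orientation
#'
#' Normalized angular difference between a subject azimuth and a reference
#' azimuth.  Azimuths are mathematical (counterclockwise-positive in distal
#' view); with `orientation = "clockwise"` the returned angle grows in the
#' clockwise direction, matching quadrant definitions stated as "degrees
#' clockwise from the reference".
#'
#' @param subject_azimuth_deg,reference_azimuth_deg azimuths in degrees.
#' @param orientation `"clockwise"` or `"counterclockwise"`.
#' @return angle(s) in `[0, 360)`.
#' @export
relative_angle <- function(subject_azimuth_deg, reference_azimuth_deg,
                           orientation = c("clockwise", "counterclockwise")) {
  orientation <- match.arg(orientation)
  if (orientation == "clockwise") {
    norm_angle(reference_azimuth_deg - subject_azimuth_deg)
  } else {
    norm_angle(subject_azimuth_deg - reference_azimuth_deg)
  }
}

#' Quadrant binning and chi-squared test against uniformity
#'
#' Angles (already relative to the reference, growing clockwise) are binned
#' into four 90-degree quadrants: Q1 = [-45, 45), Q2 = [45, 135), Q3 =
#' [135, 225), Q4 = [225, 315).  Edges are half-open and left-inclusive, so
#' a boundary angle (exactly 45, 135, ...) falls into the higher quadrant.
#' The Pearson chi-squared statistic is computed against the uniform
#' expectation n/4 per quadrant (df = 3) with the upper-tail p-value from
#' the chi-squared survival function.
#'
#' @param angles_deg numeric vector of relative angles (degrees); values are
#'   normalized, so adding multiples of 360 never changes the binning.
#' @return a list with `counts` (named Q1-Q4), `n`, `chi2`, `df`, `p`,
#'   `expected`, and `small_sample` (TRUE when expected counts drop below
#'   5, i.e. n < 20).
#' @export
quadrant_chi2 <- function(angles_deg) {
  if (length(angles_deg) < 1) .stopf("need at least one angle")
  a <- norm_angle(angles_deg)
  # shift by +45 so quadrant k is simply floor(a/90)
  qd <- floor(norm_angle(a + 45) / 90) + 1L
  counts <- tabulate(qd, nbins = 4L)
  names(counts) <- paste0("Q", 1:4)
  n <- length(a)
  expected <- rep(n / 4, 4)
  chi2 <- sum((counts - expected)^2 / expected)
  list(counts = counts, n = n, chi2 = chi2, df = 3L,
       p = stats::pchisq(chi2, df = 3, lower.tail = FALSE),
       expected = expected, small_sample = n < 20)
}

#' Circular summary of angles
#'
#' Vector-sum circular mean and mean resultant length, plus the axial
#' (angle-doubled) summary that captures bimodal alignment along an axis
#' (e.g. concentrations in opposite quadrants Q1 and Q3).  When the
#' resultant is exactly zero the mean is undefined and flagged.
#'
#' @param angles_deg numeric vector of angles in degrees.
#' @return a list: `mean_deg`, `R`, `mean_defined`, `axial_mean_deg` (the
#'   doubled-angle mean halved back to [0, 180)), `axial_R`.
#' @export
circular_summary <- function(angles_deg) {
  if (length(angles_deg) < 1) .stopf("need at least one angle")
  cs <- .circ_stats(norm_angle(angles_deg))
  ax <- .circ_stats(norm_angle(2 * angles_deg))
  list(mean_deg = cs$mean, R = cs$R,
       mean_defined = is.finite(cs$mean),
       axial_mean_deg = if (is.finite(ax$mean)) norm_angle(ax$mean / 2) %% 180
                        else NA_real_,
       axial_R = ax$R)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Two-sided two-sample KS statistic, as used to compare
#' interpeak-distance distributions between markers.  The p-value is exact
#' for small tie-free samples and asymptotic otherwise (the asymptotic
#' approximation is markedly conservative at the cohort sizes typical
#' here, a few dozen cells).
#'
#' @param values_a,values_b numeric samples (each >= 2 values).
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    .stopf("both samples need >= 2 values")
  kt <- suppressWarnings(stats::ks.test(values_a, values_b))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Monte-Carlo calibration of the quadrant chi-squared test
#'
#' Simulates cohorts of quadrant memberships from the stated probabilities
#' and reports the fraction rejected at level `alpha` — the type-I error
#' when the probabilities are uniform, the power otherwise (e.g. for a
#' quadrant depleted fourfold relative to the others).
#'
#' @param quadrant_probs length-4 probabilities (must sum to 1).
#' @param n cohort size per replicate.
#' @param reps number of replicates.
#' @param alpha rejection level.
#' @param seed PRNG seed.
#' @return a list: `rate`, `ci` (95% Clopper-Pearson interval), `reps`,
#'   `ncp` (the noncentral-chi-squared approximation parameter
#'   `n * sum((p - 1/4)^2) / (1/4)`), `power_approx` (approximate power
#'   from the noncentral chi-squared distribution).
#' @export
mc_calibrate <- function(quadrant_probs, n, reps, alpha = 0.05, seed = 1L) {
  if (length(quadrant_probs) != 4 || abs(sum(quadrant_probs) - 1) > 1e-9)
    .stopf("quadrant_probs must be 4 probabilities summing to 1")
  stopifnot(n >= 1, reps >= 1)
  set.seed(seed)
  crit <- stats::qchisq(1 - alpha, df = 3)
  draws <- stats::rmultinom(reps, size = n, prob = quadrant_probs)
  expected <- n / 4
  chi2 <- colSums((draws - expected)^2 / expected)
  rej <- sum(chi2 > crit)
  ci <- stats::binom.test(rej, reps)$conf.int
  ncp <- n * sum((quadrant_probs - 0.25)^2) / 0.25
  list(rate = rej / reps, ci = as.numeric(ci), reps = reps, ncp = ncp,
       power_approx = stats::pchisq(crit, df = 3, ncp = ncp,
                                    lower.tail = FALSE))
}

#' Azimuth of a procentriole around its parent
#'
#' Locates the procentriole in a (verticalized) diplosome stack as the
#' wall-channel intensity centroid outside the parent ring within the
#' proximal axial window, and returns its azimuth about the ring center.
#' Combined with the parent marker azimuth this yields the
#' procentriole-position-vs-marker angle (measured clockwise from the
#' marker centroid in the distal view).
#'
#' @param stack verticalized diplosome [image_stack()].
#' @param annotation parent [centriole_annotation()] (ring + z frame).
#' @param channel wall channel role or index.
#' @param r_min_factor only voxels beyond this multiple of the ring radius
#'   count as procentriole signal.
#' @param proximal_fraction fraction of the axial frame, at the proximal
#'   end, searched for the procentriole.
#' @return azimuth in degrees `[0, 360)` (counterclockwise, distal view).
#' @export
procentriole_azimuth <- function(stack, annotation, channel = "wall",
                                 r_min_factor = 1.3,
                                 proximal_fraction = 0.5) {
  ch <- .channel_index(stack, channel)
  fit <- fit_reference_circle(annotation$ring_points)
  d <- dim(stack$voxels)
  zf <- annotation$z_frame
  z_lo <- max(1, floor(zf[1] - 2))
  z_hi <- min(d[3], ceiling(zf[1] + proximal_fraction * (zf[2] - zf[1])))
  xs <- seq_len(d[1]) - fit$center[1]
  ys <- seq_len(d[2]) - fit$center[2]
  rr <- sqrt(outer(xs^2, ys^2, "+"))
  sel <- rr > r_min_factor * fit$radius
  if (!any(sel)) .stopf("no voxels outside the parent ring")
  az <- .rad2deg(atan2(rep(ys, each = d[1]), rep(xs, d[1])))
  dim(az) <- c(d[1], d[2])
  wsum <- 0; vx <- 0; vy <- 0
  for (z in z_lo:z_hi) {
    plane <- stack$voxels[, , z, ch]
    w <- plane[sel]
    th <- .deg2rad(az[sel])
    vx <- vx + sum(w * cos(th)); vy <- vy + sum(w * sin(th))
    wsum <- wsum + sum(w)
  }
  if (wsum <= 0) .stopf("no procentriole signal outside the parent ring")
  a <- norm_angle(.rad2deg(atan2(vy, vx)))
  if (identical(stack$view_convention, "proximal")) norm_angle(-a) else a
}
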