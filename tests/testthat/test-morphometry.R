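# Interpeak asymmetry, length morphometry, focus intensities.

# two-channel stack whose profiles along y = mid are Gaussians at known
# sample positions
nf_profile_stack <- function(mu_a, mu_b, sigma = 2, nx = 101) {
  xs <- seq_len(nx)
  v <- array(0, c(nx, 9, 3, 2))
  for (z in 1:3) for (y in 1:9) {
    v[, y, z, 1] <- exp(-0.5 * ((xs - mu_a) / sigma)^2)
    v[, y, z, 2] <- exp(-0.5 * ((xs - mu_b) / sigma)^2)
  }
  image_stack(v, 10, 50, c("marker", "center"), expansion_factor = 2)
}

test_that("interpeak distance resolves subpixel offsets and is zero for identical profiles", {
  stk <- nf_profile_stack(51, 54)
  r <- interpeak_distance(stk, c(1, 5), c(101, 5), 2)
  # 3 sample pitches of 10 nm, calibrated by expansion factor 2
  expect_equal(r$d_nm * r$expansion_factor / 10, 3, tolerance = 0.1)

  same <- nf_profile_stack(51, 51)
  expect_equal(interpeak_distance(same, c(1, 5), c(101, 5), 2)$d_nm, 0,
               tolerance = 1e-9)

  # invariant to uniform intensity scaling of either channel
  scaled <- stk
  scaled$voxels[, , , 1] <- 5 * scaled$voxels[, , , 1]
  expect_identical(interpeak_distance(scaled, c(1, 5), c(101, 5), 2)$d_nm,
                   r$d_nm)
})

test_that("interpeak errors on boundary peaks and missing calibration", {
  edge <- nf_profile_stack(1, 54)
  expect_error(interpeak_distance(edge, c(1, 5), c(101, 5), 2),
               "boundary")
  stk <- nf_profile_stack(51, 54)
  stk$expansion_factor <- NA_real_
  expect_error(interpeak_distance(stk, c(1, 5), c(101, 5), 2),
               "expansion")
})

test_that("a programmed 60 nm lateral offset survives the render-measure-calibrate chain", {
  p <- generator_params(noise = FALSE, center_channel = TRUE,
                        marker_radial_fraction = 60 / 115,
                        marker_arc_halfwidth_deg = 4,
                        marker_triplets = 1L, marker_weights = 1,
                        wall_component_fraction = 0, marker_azimuth_deg = 0)
  g <- generate_centriole(p)
  d <- dim(g$stack$voxels); ctr <- (d[1:3] + 1) / 2
  z <- round(g$truth$z_range[2] - 0.1 * diff(range(g$truth$z_range)))
  r <- interpeak_distance(g$stack, c(1, ctr[2]), c(d[1], ctr[2]), z)
  expect_equal(r$d_nm, 60, tolerance = 0.1 * 60)
})

test_that("length measurement recovers rods, respects calibration, and rejects degenerate frames", {
  g <- nf_clean(centriole_length_nm = 432)
  ann <- annotations_from_truth(g$truth)
  len <- measure_length(g$stack, ann)
  expect_equal(len, 432, tolerance = 25 / 432)  # one calibrated axial voxel

  # calibration linearity: nm outputs scale as 1 / expansion_factor
  len2 <- measure_length(g$stack, ann, expansion_factor = 8)
  expect_equal(len2, len / 2, tolerance = 1e-9)

  bad <- ann; bad$z_frame <- c(12, 12 + 1e-12)
  expect_error(measure_length(g$stack, bad), "degenerate z frame")
})

test_that("mother-mode length runs proximal wall end to the appendage peak", {
  g <- nf_clean(centriole_length_nm = 427, appendage_channel = TRUE)
  ann <- annotations_from_truth(g$truth)
  len <- measure_length(g$stack, ann, mode = "mother")
  expect_equal(len, 427, tolerance = 25 / 427)
  no_app <- nf_clean(centriole_length_nm = 427)
  expect_error(measure_length(no_app$stack, annotations_from_truth(no_app$truth),
                              mode = "mother"), "appendage")
})

test_that("length is invariant to in-plane rotation of the stack", {
  g <- nf_clean(centriole_length_nm = 400)
  ctr <- (dim(g$stack$voxels)[1:2] + 1) / 2
  sim <- similarity2d(35, 1)
  sim$translation <- ctr - apply_similarity(sim, ctr)
  rot <- apply_inplane_similarity(g$stack, sim)
  l0 <- measure_length(g$stack)     # ring auto-detected from the wall channel
  l1 <- measure_length(rot)
  expect_lt(abs(l1 - l0), 100 / 4)  # one calibrated axial voxel
})

test_that("length cohort reproduces the generative mean within sampling error", {
  coh <- generate_cohort(generator_params(seed = 61), 12,
                         cohort_jitter(length_sd_nm = 56), seed = 61)
  lens <- vapply(coh, function(g)
    measure_length(g$stack, annotations_from_truth(g$truth)), numeric(1))
  expect_lt(abs(mean(lens) - 427), 3 * 56 / sqrt(12) + 5)
})

test_that("focus intensity matches the closed form and its invariances", {
  v <- array(2, c(31, 31, 3, 1))
  xs <- seq_len(31) - 16
  rr <- sqrt(outer(xs^2, xs^2, "+"))
  for (z in 1:3) { pl <- v[, , z, 1]; pl[rr <= 5] <- 5; v[, , z, 1] <- pl }
  stk <- image_stack(v, 30, 100)
  qf <- quantify_focus_intensity(stk, c(16, 16), 5, 10)
  expect_equal(qf$intensity, 3 * sum(rr <= 5) * 3, tolerance = 1e-12)
  expect_false(qf$clipped)

  # exact invariance to adding a constant everywhere
  stk2 <- stk; stk2$voxels <- stk$voxels + 7
  expect_equal(quantify_focus_intensity(stk2, c(16, 16), 5, 10)$intensity,
               qf$intensity, tolerance = 1e-9)

  empty <- image_stack(array(0, c(31, 31, 3, 1)), 30, 100)
  expect_equal(quantify_focus_intensity(empty, c(16, 16), 5, 10)$intensity, 0)

  expect_true(quantify_focus_intensity(stk, c(3, 3), 5, 10)$clipped)
  expect_error(quantify_focus_intensity(stk, c(16, 16), 10, 5), "outer_radius")
})

test_that("focus recovery under noise is unbiased within 5%", {
  nx <- 41
  xs <- seq_len(nx) - 21
  spot <- exp(-0.5 * outer(xs^2, xs^2, "+") / 2^2)
  truth_sum <- sum(spot[sqrt(outer(xs^2, xs^2, "+")) <= 8])
  v <- array(0.5, c(nx, nx, 1, 1))
  v[, , 1, 1] <- v[, , 1, 1] + spot
  stk <- image_stack(v, 30, 100)
  rec <- vapply(1:40, function(s) {
    noisy <- add_noise(stk, photon_scale = 150, seed = s)
    quantify_focus_intensity(noisy, c(21, 21), 8, 14)$intensity
  }, numeric(1))
  expect_equal(mean(rec), truth_sum, tolerance = 0.05)
})
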