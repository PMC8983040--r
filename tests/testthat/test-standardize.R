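# Axis estimation, verticalization, reference azimuth, and the full
# landmark-driven standardization chain.

test_that("long axis is recovered from the moment tensor", {
  g0 <- nf_clean()
  ax0 <- estimate_long_axis(g0$stack)
  expect_lt(acos(min(1, sum(ax0 * c(0, 0, 1)))) * 180 / pi, 0.5)

  gt <- nf_clean(tilt_deg = 30, tilt_direction_deg = 90)
  axt <- estimate_long_axis(gt$stack)
  expect_lt(acos(min(1, sum(axt * gt$truth$axis_vector))) * 180 / pi, 2)

  set.seed(3)
  # cubic physical support (1200 nm each way) so only the content matters
  noise_only <- image_stack(array(runif(40 * 40 * 12), c(40, 40, 12, 1)),
                            30, 100, "wall")
  expect_error(estimate_long_axis(noise_only, channel = 1), "degenerate axis")
})

test_that("verticalize short-circuits, undoes tilt, and is idempotent", {
  g0 <- nf_clean()
  v0 <- verticalize(g0$stack, c(0, 0, 1))
  expect_identical(v0$voxels, g0$stack$voxels)

  gt <- nf_clean(tilt_deg = 30, tilt_direction_deg = 45)
  v1 <- verticalize(gt$stack, estimate_long_axis(gt$stack))
  ax <- estimate_long_axis(v1)
  expect_lt(acos(min(1, sum(ax * c(0, 0, 1)))) * 180 / pi, 1)

  # total intensity survives the resampling within the leakage bound
  expect_lt(abs(sum(v1$voxels) / sum(gt$stack$voxels) - 1), 0.02)

  # applying the (now trivial) verticalization again changes little
  v2 <- verticalize(v1, estimate_long_axis(v1))
  expect_lt(sqrt(mean((v2$voxels - v1$voxels)^2)) /
              sqrt(mean(v1$voxels^2)), 0.01)
})

test_that("reference azimuth matches hand-computable configurations", {
  v <- array(0, c(21, 21, 8, 1))
  # circle center at (11, 11); single bright voxel at azimuth 90
  v[11, 16, 7, 1] <- 1
  stk <- image_stack(v, 30, 100, "marker")
  th <- (0:8) * 40 * pi / 180
  ann <- centriole_annotation("t", cbind(11 + 6 * cos(th), 11 + 6 * sin(th)),
                              reference_mode = "brightest", z_frame = c(1, 8),
                              expansion_factor = 4)
  expect_equal(reference_azimuth(stk, ann), 90, tolerance = 1e-9)

  # two equal voxels at 80 and 100 degrees: circular centroid is 90
  v2 <- array(0, c(41, 41, 8, 1))
  r <- 12
  for (a in c(80, 100)) {
    x <- round(21 + r * cos(a * pi / 180)); y <- round(21 + r * sin(a * pi / 180))
    v2[x, y, 7, 1] <- 1
  }
  stk2 <- image_stack(v2, 30, 100, "marker")
  ann2 <- centriole_annotation("t2", cbind(21 + r * cos(th), 21 + r * sin(th)),
                               reference_mode = "brightest", z_frame = c(1, 8),
                               expansion_factor = 4)
  az <- reference_azimuth(stk2, ann2)
  expect_lt(abs(nf_circ_diff(az, 90)), 2.5)  # voxel rounding of the two spots

  # annotated-point mode: azimuth of the point about the fitted center
  ann3 <- centriole_annotation("t3", cbind(21 + r * cos(th), 21 + r * sin(th)),
                               reference_point = c(21, 33, 4),
                               reference_mode = "point", z_frame = c(1, 8),
                               expansion_factor = 4)
  expect_equal(reference_azimuth(stk2, ann3), 90, tolerance = 1e-9)

  # chirality: a proximal-view stack negates the azimuth exactly
  stk_flip <- stk2
  stk_flip$view_convention <- "proximal"
  expect_equal(reference_azimuth(stk_flip, ann3), 270, tolerance = 1e-9)

  # all-zero channel
  v2[,,,] <- 0
  expect_error(reference_azimuth(image_stack(v2, 30, 100, "marker"), ann2),
               "no signal")
})

test_that("recovered azimuth tracks the generator truth under noise", {
  errs <- vapply(1:8, function(i) {
    g <- generate_centriole(generator_params(marker_azimuth_deg = 215,
                                             rotation_deg = 0, seed = 50 + i))
    ann <- annotations_from_truth(g$truth, "brightest")
    az <- reference_azimuth(g$stack, ann)
    nf_circ_diff(az, g$truth$marker_centroid_azimuth_deg)
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 10)
})

test_that("a particle already in canonical pose yields the identity transform", {
  can <- canonical_geometry()
  th <- (0:8) * 40 * pi / 180
  ring <- cbind(can$center[1] + can$radius_vox * cos(th),
                can$center[2] + can$radius_vox * sin(th))
  ann <- centriole_annotation("id", ring,
                              reference_point = c(can$center[1] + can$radius_vox,
                                                  can$center[2], 32),
                              reference_mode = "point",
                              axis_points = rbind(c(48.5, 48.5, 1), c(48.5, 48.5, 64)),
                              z_frame = c(1, 64), expansion_factor = 4)
  stk <- image_stack(array(1, c(96, 96, 64, 1)), 20, 20, "marker")
  tr <- standardize_transform(stk, ann, can)
  expect_lt(abs(tr$ref_azimuth_deg), 1e-6)
  expect_equal(tr$scale, 1, tolerance = 1e-6)
  expect_lt(max(abs(tr$translation)), 1e-6)
})

test_that("a known pose is recovered through the standardization chain", {
  g <- nf_clean(rotation_deg = 30, ring_radius_nm = 0.8 * 115,
                translation_nm = c(150, -90, 0))
  ann <- annotations_from_truth(g$truth, "marker")
  can <- canonical_geometry()
  tr <- standardize_transform(g$stack, ann, can)
  true_az <- (g$truth$marker_centroid_azimuth_deg + 30) %% 360
  expect_lt(abs(nf_circ_diff(tr$ref_azimuth_deg, true_az)), 1)
  expect_equal(tr$scale, can$radius_vox / g$truth$ring_radius_vox,
               tolerance = 0.02)
  expect_equal(tr$fit$center, g$truth$ring_center_vox, tolerance = 1e-6)
  # landmark forward-mapping residual obeys the scale bound
  expect_lte(tr$landmark_rms, tr$fit$rms_residual * tr$scale + 1e-6)
})

test_that("standardization composes with a known similarity (group property)", {
  g <- nf_clean()
  ann <- annotations_from_truth(g$truth, "marker")
  can <- canonical_geometry()
  t0 <- standardize_transform(g$stack, ann, can)
  S <- similarity2d(25, 1.1, c(3, -2))
  ann2 <- ann
  ann2$ring_points <- apply_similarity(S, ann$ring_points)
  ann2$reference_point <- c(apply_similarity(S, ann$reference_point[1:2]),
                            ann$reference_point[3])
  t1 <- standardize_transform(g$stack, ann2, can)
  # t1 maps S-transformed landmarks to canonical: t1 o S == t0 on points
  pts <- ann$ring_points
  lhs <- apply_similarity(t1$similarity, apply_similarity(S, pts))
  rhs <- apply_similarity(t0$similarity, pts)
  expect_lt(max(abs(lhs - rhs)), 1e-6)
})

test_that("standardized marker mass sits at azimuth zero and outside voxels are masked", {
  g <- nf_clean(rotation_deg = 123)
  ann <- annotations_from_truth(g$truth, "marker")
  s <- standardize(g$stack, ann, channels = "marker")
  pr <- azimuthal_profile(average_standardized(list(s$particle)))
  # registration brings the marker intensity centroid to azimuth zero
  w <- pmax(pr$mean_intensity - min(pr$mean_intensity), 0)
  th <- pr$angle_deg * pi / 180
  centroid <- atan2(sum(w * sin(th)), sum(w * cos(th))) * 180 / pi
  expect_lt(abs(nf_circ_diff(centroid, 0)), 10)
  # corners of the canonical grid fall outside the source stack
  expect_true(any(!s$particle$mask))
  expect_true(all(s$particle$mask[48, 48, ]))
  # intensity where masked is zero-filled but flagged invalid
  expect_true(all(s$particle$volume[!s$particle$mask] == 0))
})
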