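# Mask-aware averaging and azimuthal profiling on the canonical grid.

test_that("averaging copies of one particle returns it with zero SD", {
  p <- nf_canonical_particle(40)
  av <- average_standardized(list(p, p, p))
  expect_equal(av$mean[, , , 1], p$volume[, , , 1], tolerance = 1e-12)
  expect_true(all(av$sd == 0))
  expect_true(all(av$count == 3))
})

test_that("registration collapses antipodal markers into one full-amplitude peak", {
  a <- nf_canonical_particle(0)
  b <- nf_canonical_particle(180)
  # no rotational registration: two antipodal peaks at half amplitude
  avu <- azimuthal_profile(average_standardized(list(a, b)))
  bins <- avu$mean_intensity
  pk0 <- max(bins[abs(nf_circ_diff(avu$angle_deg, 0)) < 10])
  pk180 <- max(bins[abs(nf_circ_diff(avu$angle_deg, 180)) < 10])
  single <- max(azimuthal_profile(average_standardized(list(a)))$mean_intensity)
  expect_equal(pk0, single / 2, tolerance = 0.05)
  expect_equal(pk180, single / 2, tolerance = 0.05)
  # registration (both markers brought to azimuth 0) restores full amplitude
  avr <- azimuthal_profile(average_standardized(list(a, a)))
  expect_equal(max(avr$mean_intensity), single, tolerance = 1e-12)
})

test_that("averaging is permutation-invariant and linear", {
  set.seed(21)
  ps <- lapply(c(10, 130, 250), nf_canonical_particle)
  av1 <- average_standardized(ps)
  av2 <- average_standardized(ps[c(3, 1, 2)])
  expect_equal(av1$mean, av2$mean, tolerance = 1e-12)
  expect_equal(av1$sd, av2$sd, tolerance = 1e-9)

  x <- nf_canonical_particle(77)
  xa <- x; xa$volume <- 2 * x$volume
  xb <- x; xb$volume <- 4 * x$volume
  av <- average_standardized(list(xa, xb))
  expect_equal(av$mean[, , , 1], 3 * x$volume[, , , 1], tolerance = 1e-12)
})

test_that("masks gate which particles contribute per voxel", {
  a <- nf_canonical_particle(0)
  b <- nf_canonical_particle(0, amplitude = 3)
  b$mask[1:10, , ] <- FALSE
  b$volume[1:10, , , ] <- 0
  av <- average_standardized(list(a, b))
  expect_true(all(av$count[1:10, , ] == 1))
  expect_true(all(av$count[11:96, , ] == 2))
  expect_equal(av$mean[1:10, , , 1], a$volume[1:10, , , 1], tolerance = 1e-12)
  expect_true(all(av$sd[1:10, , , 1] == 0))   # SD zero where count is 1
  d0 <- dim(a$volume)
  bad <- a; bad$volume <- array(0, c(10, 10, 4, 1)); bad$mask <- array(TRUE, c(10, 10, 4))
  expect_error(average_standardized(list(a, bad)), "canonical grid")
})

test_that("unregistered averages of rotated particles flatten as n grows", {
  cvs <- vapply(c(4, 16, 64), function(n) {
    set.seed(100 + n)
    ps <- lapply(runif(n, 0, 360), nf_canonical_particle)
    pr <- azimuthal_profile(average_standardized(ps))
    stats::sd(pr$mean_intensity) / mean(pr$mean_intensity)
  }, numeric(1))
  expect_true(all(diff(cvs) < 0))
})

test_that("azimuthal profile localizes peaks and flags symmetric rings unstable", {
  p <- nf_canonical_particle(100)
  pr <- azimuthal_profile(average_standardized(list(p)))
  expect_lt(abs(nf_circ_diff(pr$peak_azimuth_deg, 100)), 2)
  expect_true(pr$stable)
  expect_equal(pr$peak_triplet, 1)   # peak anchors triplet numbering
  expect_equal(sort(unique(diff(pr$angle_deg))), 1)

  ring <- nf_canonical_particle(0, ring = TRUE)
  # wider bins average out the radial discretization of the annulus
  prr <- azimuthal_profile(average_standardized(list(ring)), bin_deg = 6)
  expect_false(prr$stable)
  rng <- range(prr$mean_intensity)
  expect_lt((rng[2] - rng[1]) / mean(prr$mean_intensity), 0.2)

  expect_error(azimuthal_profile(average_standardized(list(p)),
                                 annulus = c(3, 4)), "empty annulus")
})

test_that("triplet bin means recover the programmed two-triplet enhancement", {
  g <- nf_clean(seed = 31)
  ann <- annotations_from_truth(g$truth, "marker")
  s <- standardize(g$stack, ann, channels = "marker")
  pr <- azimuthal_profile(average_standardized(list(s$particle)))
  expect_equal(marker_enhancement_ratio(pr), 1.5, tolerance = 0.1)
  tb <- triplet_bin_means(pr)
  expect_equal(unname(which.max(tb)), 1)
  expect_gt(tb[2], max(tb[4:8]) * 1.2)  # triplet 2 well above the floor
})
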