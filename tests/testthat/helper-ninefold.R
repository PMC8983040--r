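# Shared fixtures, all generated in code.

# quiet noiseless default particle
nf_clean <- function(...) generate_centriole(generator_params(noise = FALSE, ...))

# synthetic standard_centriole built directly on the canonical grid: a
# Gaussian blob at the given azimuth on the ring annulus, spanning the
# distal axial window.  Lets averaging be tested without any rendering.
nf_canonical_particle <- function(azimuth_deg, amplitude = 1,
                                  can = canonical_geometry(),
                                  sigma_vox = 3, id = "synthetic",
                                  ring = FALSE) {
  G <- can$grid_xy; K <- can$n_planes
  r <- 0.8 * can$radius_vox
  xs <- seq_len(G) - can$center[1]
  ys <- seq_len(G) - can$center[2]
  plane <- matrix(0, G, G)
  if (ring) {
    rr <- sqrt(outer(xs^2, ys^2, "+"))
    plane <- amplitude * exp(-0.5 * ((rr - r) / sigma_vox)^2)
  } else {
    t <- azimuth_deg * pi / 180
    cx <- r * cos(t); cy <- r * sin(t)
    plane <- amplitude * exp(-0.5 * (outer((xs - cx)^2, (ys - cy)^2, "+")) /
                               sigma_vox^2)
  }
  vol <- array(0, c(G, G, K, 1))
  z_sel <- ceiling(0.7 * K):K
  for (k in z_sel) vol[, , k, 1] <- plane
  structure(list(volume = vol, mask = array(TRUE, c(G, G, K)),
                 channels = "marker", canonical = can, particle_id = id,
                 transform = list(reference_mode = "point")),
            class = "standard_centriole")
}

# circular difference helper for expectations
nf_circ_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}
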