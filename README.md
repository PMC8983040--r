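# ninefold

Centrioles are built from microtubule triplets in a ninefold-symmetric
barrel, yet some luminal proteins decorate only one or two consecutive
triplets — a *rotational asymmetry* that ultrastructure expansion microscopy
(U-ExM) can resolve. Demonstrating it quantitatively requires averaging many
individual centrioles in a common frame: each particle must be cropped,
verticalized, registered rotationally on a reference (the brightest part of
the asymmetric signal, a basal foot, or one end of a C-shaped pattern),
rescaled to a canonical ring radius, and averaged voxelwise; the average is
then read out as an azimuthal intensity profile over the nine triplets.
`ninefold` implements that pipeline for R, together with the accompanying
measurements (lateral interpeak asymmetry, centriole length with gel
expansion calibration, background-subtracted focus intensities) and the
angular statistics used to relate procentriole position to centriole
polarity (quadrant binning with a χ² test against uniformity, circular
summaries, Kolmogorov–Smirnov comparisons).

Because public U-ExM centriole stacks are not available as raw volumes, the
package includes a first-class synthetic-stack generator with exhaustive
ground truth: a ninefold wall, a distal luminal marker enriched on
consecutive triplets (1.5:1 by default), an optional basal foot and
orthogonal procentriole, gel expansion, anisotropic Gaussian PSF, and
Poisson + Gaussian noise. Every downstream stage is validated end to end
against that ground truth.

## Core quantities

- **Standardization transform.** For particle $i$ with fitted ring center
  $c_i$, radius $r_i$ and reference azimuth $\theta_i$, the map to the
  canonical frame is $p \mapsto s_i R(-\theta_i)(p - c_i) + c_0$ with
  $s_i = r_0 / r_i$ (canonical radius $r_0$ = 115 nm), composed with the
  verticalizing rotation and a linear axial map of the annotated z-frame.
- **Average model.** Mask-aware voxelwise mean, SD and count over
  standardized particles (Welford accumulation).
- **Azimuthal profile.** Mean intensity per 1° bin in a luminal annulus
  (0.6–1.0 $r_0$) and distal axial window; triplets numbered
  counterclockwise from the recovered peak.
- **Quadrant test.** Relative angles measured clockwise from the reference;
  quadrants $Q_1 = [-45°, 45°), \dots$; Pearson
  $\chi^2 = \sum_q (O_q - n/4)^2 / (n/4)$ with 3 df against uniformity.

## Worked example

```r
library(ninefold)

# a cohort of 34 synthetic centrioles, random in-plane rotations, SNR ~ 10
coh <- generate_cohort(generator_params(seed = 11), 34,
                       cohort_jitter(radius_sd_frac = 0.05,
                                     translation_sd_nm = 30), seed = 11)

# standardize each particle, registering on the brightest marker signal
parts <- lapply(coh, function(g)
  standardize(g$stack, annotations_from_truth(g$truth, "brightest"),
              channels = "marker")$particle)

avg  <- average_standardized(parts)
prof <- azimuthal_profile(avg)
prof$peak_triplet
#> [1] 1
marker_enhancement_ratio(prof)
#> [1] 1.492434
```

The peak lands on triplet 1 and the baseline-subtracted triplet-1 /
triplet-2 enhancement ratio recovers the generative 1.5 within 1% — i.e.
the average correctly reports a marker labeling one triplet ~50% more than
its counterclockwise neighbor.

```r
# is a procentriole-position quadrant depleted fourfold detectable at n = 50?
mc_calibrate(c(4, 1, 4, 4) / 13, n = 50, reps = 1000, seed = 3)$rate
#> [1] 0.753
```

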