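---
title: "Quantifying centriole rotational asymmetry by particle averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying centriole rotational asymmetry by particle averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ninefold)
```

## The problem

Centrioles are ninefold-symmetric barrels of microtubule triplets, but some
luminal proteins bind only one or two consecutive triplets. In single U-ExM
(ultrastructure expansion microscopy) images this asymmetry is noisy and
pose-confounded: centrioles lie at arbitrary orientations, gels expand by a
factor measured per sample, and the axial point-spread function is several
times wider than the lateral one. The accepted remedy is single-particle
averaging: map every centriole onto a canonical frame using landmarks, then
average voxelwise. `ninefold` implements that chain — and, because no public
raw stacks exist for this assay, a synthetic-stack generator with complete
ground truth against which every stage is validated.

## The generator and what it emulates

`generator_params()` renders, in expanded space, Gaussian-profiled rods for
the nine triplets on a ring of pre-expansion radius 115 nm (a standard
centriole dimension; the canonical frame uses the same value), a distal
luminal marker occupying the distal quarter of the barrel on triplets 1 and
2 at an intensity ratio of 1.5 (the first triplet labeled ~50% more than
its counterclockwise neighbor), and a faint full-length component on all
nine triplets (10% of the peak) mirroring the weak wall staining seen for
such markers. Optional channels add a basal foot (a lateral lobe offset 25°
clockwise from the axis opposite the marker — reported offsets exceed 20°),
a distal-appendage ring, a symmetric axial core, and an orthogonal
procentriole (100 nm long pre-expansion) at a chosen azimuth.

Defaults not fixed by published numbers are documented assumptions chosen
once: mother length 427 nm and daughter 320 nm pre-expansion, expansion
factor 4.0 (typical U-ExM; gels are measured per sample in practice), 30 nm
lateral / 100 nm axial voxels and an 80 / 200 nm PSF in expanded space
(Airyscan-like sampling), and a photon scale putting the marker peak near
SNR 10 with 2-photon read noise. Poses are a tilt (direction + angle), an
in-plane rotation, and a translation; cohorts draw the rotation uniformly —
in real samples centrioles face the objective at arbitrary spin — plus
configurable jitter on length, radius, intensity and centering. One master
seed derives per-particle seeds through a fixed affine-mod-prime scheme, so
any particle is regenerable in isolation.

What the generator does *not* emulate: ninefold-bladed appendage
substructure, vectorial or depth-dependent PSFs, background cellular
staining, chromatic offsets, and gel distortions (expansion is modeled as a
single isotropic factor). Passing tests therefore demonstrate correctness
of the measurement chain under a faithful geometric and noise model, not
robustness to every artifact of real acquisitions.

## The standardization chain

Four steps, mirroring the manual workflow this replaces, each with an
automatic and an annotation-driven route:

1. **Verticalization.** The long axis comes from annotated axis points or
   from the principal axis of the intensity-weighted second-moment tensor
   of the wall channel (in nm coordinates, so anisotropic z sampling is
   handled). Because a convolution adds its covariance to the geometry's,
   the anisotropic blur biases the raw moments toward the optical axis by
   several degrees at 30° tilt; `estimate_long_axis()` therefore subtracts
   the blur covariance (rotated alongside any prior resampling) before the
   eigendecomposition. Volumes are rotated trilinearly; rotations that
   would displace no voxel by more than half a voxel are skipped, so
   repeated verticalization does not accumulate interpolation loss.
2. **Ring fit.** Kasa algebraic least squares on the annotated ring points;
   collinear configurations are rejected as degenerate.
3. **Reference azimuth.** Mode `point` (and its `basal_foot_point` /
   `c_end_point` synonyms) takes the annotated point's azimuth about the
   fitted center. Mode `brightest` operationalizes "the brightest part of
   the signal" as the intensity centroid of the top-5% voxels of the marker
   channel in the distal 30% of the axial frame; if that set is so
   dispersed that its circular resultant drops below 0.5 (two equal
   antipodal patches, say), the brightest single voxel wins, exact ties
   resolving to the lower azimuth — deterministic by construction. A
   proximal-view stack negates azimuths (chirality).
4. **Resampling.** The canonical frame is 96×96 lateral voxels at 5 nm
   pre-expansion pitch (ring radius = 23 voxels) and 64 axial planes over
   the normalized z-frame. The composed inverse map (canonical → rotation →
   scale → translation → verticalization) is applied in a *single*
   trilinear pass from the original stack, so no intermediate resampling
   loss accrues; canonical voxels falling outside the source are masked,
   not zero-filled. The axial frame is linearly rescaled by default — the
   z-framing is read as defining the axial extent — with a `native` mode
   preserving the source axial pitch for length-sensitive work.

## Averaging and the azimuthal readout

`average_standardized()` accumulates mask-aware voxelwise means and SDs by
Welford's one-pass update (stable at any cohort size; SD is exactly zero
where only one particle contributed). `azimuthal_profile()` bins the mean
intensity per degree in a luminal annulus (0.6–1.0 of the canonical radius,
where the distal marker sits) and distal axial window (top 30%); bins that
are geometrically empty on the discrete annulus are filled by circular
interpolation. The peak azimuth is the circular centroid of the contiguous
above-half-maximum cluster containing the global maximum; a profile whose
bin-weight resultant falls below 0.05 is flagged rotationally unstable
(symmetric signal — no meaningful peak). Triplets are numbered
counterclockwise from the peak, matching the convention of numbering from
the marker signal.

Two readouts matter downstream. `triplet_bin_means()` reports raw per-
triplet bin means. `marker_enhancement_ratio()` subtracts the profile
median — the symmetric full-length wall component contributes a floor to
*every* triplet, which would otherwise bias the triplet-1/triplet-2 ratio
low — and then forms the ratio, recovering the generative 1.5 within a few
percent at cohort scale.

The unregistered control (`standardize(..., register = FALSE)`) quantifies
what rotational registration adds: with uniform random spins the profile's
expected residual structure is the rotational sampling noise,
`sqrt(var(registered bins) / n)`, and the measured unregistered profile SD
sits at about that floor, while the registered profile's contrast exceeds
it many-fold.

## Morphometry

Interpeak distance `d`: profiles of the protein and centriole-center
channels are sampled along one segment (bilinear, 2 samples per voxel),
each global maximum refined by 3-point parabolic interpolation (peaks at
the segment boundary or below 3 profile-MADs of prominence are errors, not
numbers), and the position difference divided by the gel expansion
coefficient. Length: the wall channel's axial profile over the ring annulus
is thresholded at half maximum; daughter mode takes both crossings, mother
mode replaces the distal end with the appendage channel's axial peak; a
degenerate z-frame is an error rather than a zero. Focus intensities
subtract the median of a surrounding annulus times the disk voxel count —
median, not mean, to resist bleed-through from a neighboring focus — which
makes the result exactly invariant to constant offsets.

## Angular statistics

Relative angles carry an explicit orientation; the clockwise convention in
distal view (mathematically negative) matches quadrant definitions stated
as "degrees clockwise from the reference". Quadrants are half-open and
left-inclusive, so a boundary angle falls into the higher quadrant —
a documented tie rule. The Pearson χ² against uniform n/4 expectations
(df 3) reports the upper-tail p from the χ² survival function; p-values are
raw, as single-panel analyses report them, with Bonferroni left to the
caller for multi-panel runs. `circular_summary()` adds the angle-doubled
(axial) resultant for bimodal opposite-quadrant alignment.
`mc_calibrate()` simulates the test's operating characteristics: type-I
error ≈ 0.04–0.05 at n = 40, and power ≈ 0.75 at n = 50 for a quadrant
depleted fourfold (probabilities 4/13, 1/13, 4/13, 4/13), bracketing the
noncentral-χ² approximation (λ = n·Σ(p−¼)²/¼ ≈ 8, power ≈ 0.65), which is
known to be conservative for skewed alternatives at these sizes. The
two-sample Kolmogorov–Smirnov comparison uses the exact p for small
tie-free samples; at a few dozen values per group the statistic is
discrete, so the achievable test size sits *below* the nominal level — a
property of the statistic, not the implementation.

## Numerical choices and degenerate inputs

- Trilinear interpolation for volume resampling (speed; single-pass
  composition keeps its loss to one application); cubic-convolution (Keys)
  interpolation for the planar similarity utility, where bilinear's ~1.4%
  RMS smoothing would dominate the render/rotate commutation error.
- Stacks are stored as 16-bit TIFF pages with an intensity scale in a JSON
  sidecar (values snapped to the 16-bit grid before writing, so re-saving
  is bit-stable); ground truth is serialized at 17 significant digits and
  round-trips exactly.
- Readers are strict: malformed annotations are rejected with the particle
  id and field named; stacks without pitch metadata load but refuse
  nm-valued operations.
- Degenerate cases are errors, not numbers: collinear ring points, axes
  with moment-tensor anisotropy below 1.05, all-zero marker channels,
  zero-extent z-frames, peaks without a parabolic neighborhood.

## Problem sizes used in validation

The self-validation experiments run at the cohort sizes of the assays they
emulate: 100 posed particles for pose recovery, 34 particles for the
centrosome averaging experiment, 20 replicate cohorts of 35 for the
basal-foot-referenced (multiciliated-cell) preset, 2000/1000 replicates for
χ² calibration, 40 mothers for length morphometry, and replicate cohorts of
130 rendered diplosomes for the end-to-end quadrant-depletion recovery.

## Known limitations

- Registration is reference-point-based, as in the workflow it reproduces;
  there is no iterative reference-free (expectation–maximization) alignment
  and no symmetry-expansion averaging.
- The axial PSF model is a separable Gaussian; real confocal/Airyscan PSFs
  have structured sidelobes the generator does not produce.
- `brightest`-mode registration assumes the marker's asymmetric component
  dominates its distal window; markers with equal-intensity antipodal pools
  fall back to a deterministic but arbitrary choice and should be
  registered from an annotated point instead.
- Whether real analyses rescaled z or only cropped it is ambiguous in the
  workflows this follows; both behaviors exist (`axial_mode`), rescaling is
  the default.
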