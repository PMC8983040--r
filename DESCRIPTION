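Package: ninefold
Title: Quantifying Centriole Rotational Asymmetry from Expansion Microscopy Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting and quantifying rotational asymmetry in
    centrioles imaged by ultrastructure expansion microscopy (U-ExM).
    Provides a synthetic-stack generator with exhaustive ground truth
    (ninefold triplet wall, asymmetric distal luminal marker, basal foot,
    orthogonal procentriole, PSF blur, Poisson and Gaussian noise),
    landmark-based standardization of individual centrioles (verticalization,
    circle fitting, rotational registration to a reference azimuth),
    mask-aware 3D particle averaging with azimuthal profiling, intensity
    morphometry (interpeak lateral asymmetry, centriole length with gel
    expansion calibration, background-subtracted focus intensities), and
    angular statistics (quadrant chi-squared tests against uniformity,
    circular summaries, Kolmogorov-Smirnov comparisons, Monte-Carlo
    calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
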