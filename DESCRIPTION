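Package: emgspecvar
Title: Spectral Pattern Variability Analysis for Surface EMG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying intra- and inter-individual variability of
    surface electromyography (sEMG) power spectra recorded during repeated
    isometric contractions. Provides a synthetic two-channel sEMG cohort
    generator with ground-truth annotations, contraction segmentation by
    summed-channel peak detection with RMS-envelope boundary refinement,
    smoothed normalized power spectra via a moving trend filter (local
    polynomial smoothing), Minkowski-distance variability tables,
    Wilcoxon signed-rank posture comparisons, and probabilistic modelling of
    inter-subject distance distributions (normal, Laplace, Maxwell-Boltzmann)
    with chi-square goodness-of-fit assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
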