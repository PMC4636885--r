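Package: sonopore
Title: Acoustic Field Planning and Image-Based Quantification for
    Sonoporation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for planning and quantifying in vitro sonoporation
    experiments on adherent cell cultures. Simulates the continuous-wave
    near field of flat circular piston transducers (Rayleigh-Sommerfeld
    quadrature with an on-axis closed form), selects a near-field
    treatment plane by minimizing field heterogeneity, computes exposure
    dosimetry (duty cycle, pulse repetition frequency, microbubble dose
    arithmetic, session timing), segments three-channel fluorescence
    micrographs (Otsu thresholding, connected components, seeded
    propagation) and scores transfection and apoptosis with a
    background-referenced intensity criterion, quantifies cell
    detachment from marker images, and routes replicate-level responses
    through a Shapiro-Wilk/Bartlett decision tree to two-way ANOVA with
    Tukey HSD or Kruskal-Wallis with pairwise Wilcoxon tests. Seeded
    generators produce planar scans, synthetic micrographs with ground
    truth, marker images, and replicate tables so the full pipeline can
    be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    grDevices,
    EBImage,
    tiff,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
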