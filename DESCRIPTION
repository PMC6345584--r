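Package: fluorquant
Title: Quantitative Analysis of Fluorescence Microscopy Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reproducible quantitative analysis of receptor-trafficking
    fluorescence microscopy experiments. Detects diffraction-limited
    vesicles by undecimated B3-spline (a trous) wavelet filtering,
    MAD-based thresholding and seeded watershed segmentation; quantifies
    two-channel colocalization by Pearson correlation and object-pixel
    overlap; measures surface and total receptor levels within cell and
    membrane-band regions of interest; fits fluorescence recovery after
    photobleaching (FRAP) traces with photofading correction to a
    mono-exponential model yielding half-time and mobile fraction;
    summarises single-cell migration-track speeds; estimates binding
    affinity from microscale thermophoresis titrations with the quadratic
    mass-action (ligand depletion) model; and derives FRET efficiency
    from time-domain fluorescence-lifetime decays. A seeded synthetic-data
    generator produces every input type with known ground truth so the
    whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    stats,
    utils,
    tools,
    graphics
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
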