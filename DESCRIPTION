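Package: tandemEMU
Title: Simulation and Natural-Abundance Correction of Tandem MS Data for
    13C Metabolic Flux Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for incorporating tandem mass spectrometry (MS/MS)
    measurements into 13C metabolic flux analysis based on the elementary
    metabolite unit (EMU) framework. Provides the compact tandem MS matrix
    as the central data structure, forward simulation of labeling patterns
    by 2D-convolution, correction of measured tandem MS data for natural
    isotope abundances by 2D-deconvolution, EMU decomposition of
    atom-transition network models with daughter-fragment atom tracking,
    cascade solving of EMU balance equations, a brute-force isotopomer
    simulator used as an independent correctness oracle, and least-squares
    flux estimation from tandem MS measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
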