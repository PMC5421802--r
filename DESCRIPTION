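Package: ctcflow
Title: Circulating Tumor Cell Enumeration and Purity-Adjusted Somatic Variant Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the two downstream analyses of microfluidically enriched
    circulating tumor cell (CTC) samples: (1) immunofluorescence image analysis
    for CTC identification, enumeration and purity estimation from DAPI,
    CK/EpCAM and CD45 channels, including a synthetic fixture generator with
    known ground truth, nucleus segmentation, size/shape filtering,
    intensity gating and gallery export; and (2) an amplicon deep-sequencing
    model with a random diversifier sequence, a tumor/normal pileup simulator
    for spike-in dilution series, a purity-adjusted one-tailed Fisher's exact
    somatic test with consensus calling across technical replicates, and the
    linearity and PPV/FDR/sensitivity benchmarks used to validate them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Biostrings,
    jsonlite,
    png,
    tiff,
    withr,
    yaml,
    stats,
    utils,
    grDevices,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vcfR
Config/testthat/edition: 3
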