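Package: twinscope
Title: Imaging-Genetics Co-Segregation and Similarity Analysis for
    Discordant-Twin Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for single-family imaging-genetics
    case studies of specific reading disability (SRD). Implements SNP
    co-segregation filtering over a reading-gene panel with GenCall-style
    quality control, pairwise intraclass correlations (ICC) of regional
    cortical morphometry, hemispheric asymmetry indices with direction
    classification, and a region-of-interest mask luminosity-composite
    technique with quantile-quantile comparison of luminosity distributions.
    Includes a fully deterministic synthetic-family generator (genotypes,
    morphometry, template-space region masks) with a recorded ground truth so
    every stage is testable without access to protected subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    png,
    RNifti,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
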