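Package: irifq
Title: Ionizing-Radiation-Induced Foci Quantification and PARP-Inhibitor
    Resistance Alteration Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated quantification of ionizing-radiation-induced foci
    (IRIF) such as RAD51 and 53BP1 foci from two-channel confocal image
    stacks: nucleus segmentation by thresholding and watershed, maximum-
    intensity projection, difference-of-Gaussians background subtraction,
    adaptive per-image foci detection and per-cell positivity calling.
    Aggregates cell records into per-area summaries and classifies tumor
    homologous-recombination (HR) status, with the cohort statistics used
    in PARP-inhibitor resistance studies (exact Mann-Whitney U,
    Benjamini-Hochberg correction, two-sided Fisher exact tests) and
    tabular resistance-alteration calling: resistance-specific genomic
    calls, a matched-pair two-fold transcriptional rule, subgroup-outlier
    scoring with permutation tests, expression filtering, overlap
    summaries and gene-set over-representation. Includes synthetic
    microscopy-field and multi-omics generators with ground truth so the
    whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
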