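Package: sasome
Title: Senescence-Associated Surfaceome Screen and Transcriptome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for flow-cytometry surfaceome screens and bulk
    transcriptomes of therapy-induced senescent tumor cells. Normalizes
    per-antigen median fluorescent intensities (MFI) against isotype-control
    baselines, switching to a Gaussian kernel-density-mode baseline for large
    shared-isotype marker sets; selects differentially expressed surface
    antigens by fold change with Venn partitioning and ternary
    relative-contribution coordinates; flags bimodal marker distributions
    nonparametrically via smoothed quantile density functions normalized
    against a screen-wide reference; scores preranked gene-set enrichment with
    bootstrap z-scores; and triages plasma-membrane-annotated, consistently
    upregulated transcripts as candidate surface targets. Includes a synthetic
    screen and transcriptome generator with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
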