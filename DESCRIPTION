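Package: beadmeth
Title: Mouse Methylation BeadChip Signal Processing and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained toolkit for two-channel Infinium mouse
    methylation array data: out-of-band detection p-values (pOOBAH),
    normal-exponential background subtraction (noob), nonlinear dye-bias
    correction, and beta-value summarization with quality masking;
    human/mouse DNA fraction estimation for patient-derived xenografts via
    channel-switch variant probes and cross-array intensity ratios with
    LOESS standard curves; maximum-likelihood mouse strain genotyping,
    mixed-background detection and backcross tracing from SNP probes;
    differential methylation by multivariate regression with F-tests,
    one-vs-rest tissue signatures, human-mouse effect decomposition,
    region-set enrichment and mono-allelic methylation calling; an
    elastic-net epigenetic age clock; and a synthetic-data generator that
    emulates two-channel signals with background, dye bias, titration and
    species mixtures, strain genotypes and tissue/age methylome structure,
    so every stage is testable without array downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    jsonlite,
    ape,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
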