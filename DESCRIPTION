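Package: epiConcord
Title: Integrative Methylome-Transcriptome Concordance Analysis for
    Two-Group Array Studies
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates Infinium-style CpG beta-value methylation profiles
    with log2 expression-array profiles for a two-group (case/control)
    design. Calls differentially methylated probes and genes using
    detection-p masking, a signed DiffScore p-value transformation with the
    |DiffScore| >= 13 gate, and the percent-methylation-change statistic;
    calls differentially expressed genes with an intensity-based moderated
    t-statistic under Benjamini-Hochberg FDR control; classifies
    directional methylation-expression concordance (hypo-methylated/
    up-regulated and hyper-methylated/down-regulated epigenes); performs
    hypergeometric gene-set over-representation on GMT collections; and
    provides the small-sample validation statistics used in targeted
    follow-up (median +/- 1.5 IQR outlier exclusion, equal-variance
    t-tests from raw values or mean/SEM/n summaries, group-mean fold
    changes, 2^-ddCt qPCR quantification, pyrosequencing region means).
    Includes a seeded synthetic-data generator with planted truth for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
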