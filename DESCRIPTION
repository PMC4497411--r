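Package: mirlineage
Title: Lineage-Specific miRNA Signatures of Mammary Epithelial Subsets
Version: 0.1.0
Authors@R:
    person("Alex", "Whitfield", email = "alex.whitfield@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis pipeline linking miRNA expression
    signatures of sorted mammary epithelial subsets (MaSC/basal, luminal
    progenitor, mature luminal, stroma) to their predicted target mRNAs,
    to breast-tumor miRNA-seq profiles, and to histone-mark ChIP-seq.
    Covers TaqMan array Ct preprocessing with housekeeping-weighted cyclic
    loess normalization, probe-wise linear models with empirical-Bayes
    moderated t- and F-statistics, directional rotation gene-set tests of
    miRNA/target inverse correlation, TMM-normalized logCPM signature
    scoring of tumors by intrinsic subtype, and negative-binomial ChIP
    fold changes regressed through the origin against expression fold
    changes. Includes a synthetic-data generator that emulates every
    pipeline input with known ground truth for calibration and recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    withr
Config/testthat/edition: 3
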