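Package: line1meth
Title: Locus-Specific LINE-1 Promoter Methylation Pattern Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of locus-specific LINE-1 retrotransposon promoter
    methylation from bisulfite amplicon sequencing. Simulates bisulfite
    reads with known epiallele architectures (uniform, allelic, patchy),
    aligns reads with bisulfite-aware scoring and calls per-read per-CpG
    methylation states, computes per-CpG methylation profiles and
    sliding-window methylation entropy, classifies read-level methylation
    architectures, detects recurrent hypomethylation hotspots on a
    consensus CpG coordinate system, and runs a paired tumor-normal
    biomarker cascade (Wilcoxon signed-rank, Benjamini-Hochberg FDR,
    penalized multivariate logistic regression, ROC/AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
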