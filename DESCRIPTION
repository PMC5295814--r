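Package: spinasym
Title: Left-Right Multi-Omic Asymmetry Calling for Paired Tissue Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls left-versus-right asymmetries in paired transcriptomic,
    miRNA and CpG methylation data from the same specimens, and integrates
    the three layers. Gene expression asymmetry uses an FPKM abundance
    filter with a fold-change-of-means rule; miRNA asymmetry uses a
    read-count filter, RPKM normalisation and the same fold-change rule;
    differential CpG methylation uses per-site Fisher exact tests with FDR
    correction and a joint significance/magnitude rule, followed by a
    cross-sample consensus. An integration step assigns consensus CpG sites
    to genes (gene body plus a strand-aware upstream promoter window),
    computes a per-gene methylation laterality quotient, and partitions
    asymmetrically expressed genes into methylation-explained,
    miRNA-explained, both, or unexplained categories. A synthetic-data
    generator produces paired left/right fixtures with planted ground truth
    so the whole pipeline can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
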