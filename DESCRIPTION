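Package: cernet
Title: Competing Endogenous RNA Network Inference on Two-Group RNA-Seq Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers mRNA-miRNA-lncRNA competing endogenous RNA (ceRNA)
    regulatory triplets from matched count matrices of the three RNA classes
    in a two-group design. Provides median-of-ratios normalization, FPKM,
    Welch-t differential expression with fold-change thresholds, lncRNA
    candidate filtering with coding-potential verdict intersection,
    miranda-style miRNA target-site scanning and lncRNA-mRNA duplex scanning
    on a Turner nearest-neighbor energy model, sign-constrained Pearson
    co-expression networks, cis/trans lncRNA target assignment, triplet
    assembly, and hypergeometric enrichment with Benjamini-Hochberg
    correction. A synthetic-data module generates annotation, sequences and
    negative-binomial counts with planted ground truth so the whole pipeline
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
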