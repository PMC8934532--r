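Package: omegascreen
Title: Screening for Lineage-Specific Positive Selection with Branch-Site
    Codon Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide screens of lineage-specific
    positive selection on protein-coding genes. Provides single-copy
    orthogroup filtering with deterministic paralog pruning, protein-guided
    back-translation into codon alignments with masking and edge-trimming
    quality control, maximum-likelihood fitting of site-class (Goldman-Yang)
    codon substitution models with an optional foreground branch, the
    branch likelihood-ratio test for elevated nonsynonymous rates, and the
    downstream genomic statistics used to characterise hits: a discrete
    Kolmogorov-Smirnov test of genomic clustering in megabase windows, a
    fixed-grid cluster scan, a single-exon association test, and
    tissue-expression bias statistics (peak-tissue enrichment and
    per-tissue mean comparisons after tissue decorrelation). A synthetic
    data module simulates codon alignments under the same site-class
    models, gene landscapes with optional planted clusters, and expression
    matrices with correlated tissue pairs, so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    knitr,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
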