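Package: pleiocfdr
Title: Conditional and Conjunction FDR Analysis of Cross-Trait Pleiotropy
    in GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies genetic variants shared between two complex traits
    from genome-wide association study (GWAS) summary statistics using the
    empirical conditional false discovery rate (cFDR) and its conjunction
    (ccFDR). Provides reading, validation and allele harmonization of
    summary-statistic files, genomic-control correction, sliding-window
    linkage-disequilibrium (LD) pruning against a reference genotype panel,
    stratified conditional quantile-quantile enrichment curves, exact
    per-SNP cFDR/ccFDR computation in both trait orderings, a simplified
    shared-single-causal-variant fine-mapping model based on approximate
    Bayes factors, two-sample Mendelian randomization (inverse-variance
    weighted and maximum likelihood), offline SNP-to-gene annotation and
    novelty flagging, and a synthetic two-trait generator with known
    ground truth for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
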