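Package: lcsgwas
Title: Multi-Trait Mixed-Model GWAS and QTL Mapping for Low-Coverage Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of quantitative
    traits from low-coverage sequencing genotypes. Implements imputation
    accuracy metrics (genotype concordance and dosage correlation), variant
    quality control with an exact Hardy-Weinberg test, LD pruning and decay
    summaries, the VanRaden genomic relationship matrix, restricted maximum
    likelihood for Kronecker-structured multi-trait linear mixed models by
    average information with an EM fallback, multivariate and conditional
    Wald chi-square association scans, simulation-based drop-log(P) QTL
    confidence intervals, QTL heritability by lead-SNP adjustment, and
    sliding-window nucleotide diversity and Weir-Cockerham FST. A synthetic
    data generator with haplotype-copying linkage disequilibrium and a
    read-sampling low-coverage dosage model supports end-to-end testing
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
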