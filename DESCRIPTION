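Package: mqtlsmoke
Title: Cis-mQTL Mapping and Attribution for Smoking-Related CpG Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A two-panel cis-mQTL analysis pipeline for smoking-related CpG
    sites: simulation of a discovery/validation cohort with known
    genotype-methylation-phenotype structure, SNP quality control
    (missingness, Hardy-Weinberg exact test, minor allele frequency, linkage
    disequilibrium pruning), SNP-CpG pairing within a +/-50 kb cis window,
    reference-based leukocyte deconvolution by constrained projection,
    two-stage discovery/validation association testing with batch
    random-effect linear models and Benjamini-Hochberg FDR, quantification
    of each mQTL's percentage contribution to smoking-associated methylation
    change, SNP-by-smoking interaction models, and scans of mQTLs against
    smoking indicators and all-cause mortality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    survival,
    quadprog,
    jsonlite,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
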