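Package: cllstrat
Title: Whole-Genome Stratification of Chronic Lymphocytic Leukemia Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for stratifying chronic lymphocytic
    leukemia (CLL) cohorts from whole-genome sequencing derived lesions:
    somatic SNV/indel, copy-number and structural-variant filtering with
    cancer-cell-fraction estimation; coding driver discovery by
    multi-algorithm FDR voting, weighted Stouffer and weighted harmonic-mean
    p-value combination, and focality/recurrence integration of copy-number
    alterations; a regulatory-element catalog with enhancer-target linking
    inside topologically associated domains and binomial mutation-recurrence
    tests; assembly of a 186-feature binary genomic alteration matrix;
    multiple correspondence analysis over 17 genome-wide binary measures
    defining eight genomic-complexity groups; an offset non-negative matrix
    factorization subgroup classifier with cophenetic rank selection,
    deconvolution-based sample assignment and hold-out validation; and
    survival/enrichment statistics (Kaplan-Meier, log-rank, Cox, Fisher).
    A synthetic-cohort generator with planted subgroup structure makes the
    whole pipeline testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    mclust,
    yaml,
    jsonlite,
    IRanges,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
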