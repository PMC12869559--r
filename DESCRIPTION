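Package: ccspectrum
Title: Case-Case and Shared-Effect Analysis of Genetically Opposed Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for jointly analysing GWAS summary statistics of two
    genetically anticorrelated diseases, motivated by the dilated versus
    hypertrophic cardiomyopathy spectrum. Provides harmonisation and quality
    control of summary statistics; a liability-threshold simulator for paired
    case-control data with block linkage disequilibrium, shared controls and
    correlated endophenotypes; minimal LD score regression estimators of
    heritability, genetic correlation and overlap intercepts with a simplified
    regional scan; reconstruction of case-case association statistics with
    ordinary and exact liability-scale weighting; a multi-trait generalised
    least squares update; two-stage fixed/random-effects shared-effect
    meta-analysis; approximate Bayes factor credible sets, locus definition and
    cross-study consolidation with gene-score aggregation; ancestry-standardised
    polygenic score discrimination metrics; and exact replication statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    metafor,
    pROC
Config/testthat/edition: 3
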