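Package: kaspqc
Title: Validation and Cross-Fidelity Analysis of KASP SNP Genotyping Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating bi-allelic KASP (Kompetitive allele-specific
    PCR) SNP genotyping assays in plant populations and for quality control of
    controlled crosses. Filters putative SNP candidates from transcriptome
    variant calls by coverage, allele frequency and flanking-window criteria and
    emits assay-ready context sequences; classifies assay outcomes (failed,
    monomorphic, polymorphic) across a germplasm collection and summarizes
    within-population polymorphism by cytotype; concatenates two-letter SNP
    codes into DNA-like fingerprints and infers bootstrapped maximum-parsimony
    trees; verifies F1 hybrids and F2 selfs in tetraploid crosses with
    informative-marker rules and chi-square tests of disomic Mendelian
    segregation; and simulates KASP call data under disomic inheritance with
    configurable selfing, outcrossing, genotyping-error and missing-call rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    vcfR,
    stats,
    utils
Suggests:
    phangorn,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
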