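Package: milkgwas
Title: Genome-Wide Association of Breast-Milk Fatty-Acid Composition via
    Maternal Genotypes Imputed from Infants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide association analysis of compositional
    breast-milk fatty-acid phenotypes in mother-infant dyad cohorts where
    only the infants are genotyped.  Maternal genotype posteriors are
    derived from infant genotypes under Mendelian transmission and
    Hardy-Weinberg equilibrium, and tested against log- or
    square-root-transformed fatty-acid fractions with a missing-data score
    test that carries the full genotype probability distribution rather
    than a point dosage.  Includes Oxford GEN/SAMPLE and minimal VCF
    readers and writers, an IMPUTE-style information score, exact
    Hardy-Weinberg filtering, eigenvalue-based effective-test correction
    of the multiplicity burden across correlated phenotypes, fixed-effects
    inverse-variance meta-analysis across studies, conditional regional
    scans, locus grouping, and a synthetic dyad-cohort generator so the
    whole pipeline is testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
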