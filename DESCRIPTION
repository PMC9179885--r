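Package: snptrace
Title: Reduced SNP Panel Selection and Breed Assignment for Livestock
    Traceability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to build small, breed-diagnostic SNP panels from
    medium-density genotyping data and to assign individuals to breeds
    (or flag them as likely first-generation hybrids). Reads and writes
    PLINK text (PED/MAP) and binary (BED/BIM/FAM) genotypes, applies
    call-rate and Hardy-Weinberg exact-test quality control, ranks
    markers by the delta statistic (the absolute difference of an
    allele's frequency between two populations), selects per-breed-pair
    panels with deterministic tie-breaking, simulates purebred and F1
    hybrid genotypes from population allele frequencies, and classifies
    individuals with a shared-covariance canonical discriminant model
    and a minimum-posterior threshold that reassigns low-confidence
    calls to a hybrid class. A Balding-Nichols synthetic-study generator
    makes the whole pipeline testable without access to real herd data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
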