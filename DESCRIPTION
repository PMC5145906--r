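Package: pedavoid
Title: Pedigree Inbreeding, Marker-Based Heterozygosity and Tests of
    Inbreeding Avoidance in Group-Living Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying inbreeding in group-living animal
    populations with multi-generational pedigrees. Computes
    depth-truncated pedigree inbreeding coefficients via the recursive
    kinship algorithm, classifies inbreeding cases by the kin type and
    kin line connecting the parents, and validates the recursion with a
    gene-dropping Monte-Carlo oracle. Implements three multilocus
    marker-based inbreeding estimators (standardized heterozygosity,
    internal relatedness and homozygosity by loci) for codominant
    genotypes with missing data, and a one-sided permutation test of
    inbreeding avoidance against a simulated null of sire assignment
    under male reproductive skew, extra-group paternity and natal
    breeding. A demographic population simulator with female philopatry,
    male natal dispersal, tunable kin-avoidant mate choice and Mendelian
    gene-dropped genotypes makes every stage testable without restricted
    colony data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
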