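Package: polycrossGS
Title: Genomic Selection Training Analysis for Polycross Half-Sib Breeding Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for building and validating genomic selection training sets
    in outbred forage-crop breeding programmes that evaluate half-sib families
    from polycross mating. Provides simulation of multi-population founder
    genotypes, polycross families, row-column field trials and low-depth
    genotyping-by-sequencing (GBS) read counts; SNP filtering and mean
    imputation; standard and read-depth-adjusted genomic relationship
    matrices; EM-REML variance component and family BLUP estimation with
    family-mean repeatability; GBLUP and ridge-regression genomic prediction
    with tenfold and population-balanced cross-validation; linkage
    disequilibrium decay modelling; and deterministic prediction of genetic
    gain from combined among-family phenotypic and within-family genomic
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite
Config/testthat/edition: 3
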