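Package: haplopheno
Title: Candidate-Gene Haplo-Pheno Analysis for Inbred Crop Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Haplotype-based breeding support for candidate-gene panels in
    inbred crops. From a variant table (VCF), gene models and multi-environment
    phenotypes, the package hard-filters variants, estimates variance
    components, broad-sense heritability and per-accession BLUPs, builds a
    centered kinship matrix and runs an exact mixed-model association scan per
    environment and on BLUPs, applies a cross-environment consistency rule to
    declare trait-associated variants, calls per-gene haplotypes and multi-gene
    haplotype combinations, ranks haplotype groups with Student's t, Duncan's
    multiple range test and variance-explained statistics, and selects a
    minimal discriminating marker panel for a target haplotype. A synthetic
    panel generator with planted haplotype effects provides fully inbred test
    populations with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
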