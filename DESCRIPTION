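Package: ystrata
Title: Mapping Evolutionary Strata on Young Plant Sex Chromosomes
Version: 0.1.0
Authors@R: person("ystrata", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Locates evolutionary strata and the pseudoautosomal boundary on a
    young sex chromosome from transcriptome variant data. Detects Y-linked SNPs
    by segregation in a genetic cross and by male-specificity in wild samples,
    reconstructs Y-linked gametolog coding sequences from allele-tagged reads,
    computes per-gene X:Y synonymous divergence (Nei-Gojobori with Jukes-Cantor
    correction), nucleotide diversity at fourfold degenerate sites and Kelly's
    ZnS linkage disequilibrium, and infers stratum boundaries from per-gene
    evidence tables. Includes a coalescent-based synthetic data generator so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
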