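Package: genomevuln
Title: Genome Vulnerability Indices from Transcriptome Variant Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes comparative genome-vulnerability indices for congeneric
    plant species from de novo transcriptome assemblies, variant calls,
    protein homology tables and variant effect-score tables: heterozygous
    synonymous SNVs per kb of coding sequence, the proportion of
    nonsynonymous SNVs, the proportion of nonsense (loss-of-function) SNVs,
    PROVEAN- and SIFT-based deleterious-variant fractions, and the
    proportion of duplicated genes (P_D).  Adds an interspecies
    deleterious-substitution analysis on reciprocal-best-hit ortholog
    pairs, a statistical comparison layer (per-gene Welch t tests within
    genera and exact binomial sign tests across genera), and a fully
    deterministic synthetic-data generator for testing and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
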