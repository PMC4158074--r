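Package: minifrag
Title: Comparative Analysis of Fragmented Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of fragmented mitochondrial
    genomes composed of minichromosomes, as found in blood-sucking lice
    (Anoplura). Parses and round-trips minichromosome gene-arrangement
    tables, computes gene censuses and cross-species homolog pairings,
    extracts ordered gene-run characters and infers ancestral arrangements
    under a two-clade presence rule, detects genus-specific (candidate
    synapomorphic) minichromosomes, tests shared identical sequence
    segments between genes against a composition-preserving permutation
    null, characterises non-coding regions (AT-rich/GC-rich boundary
    motifs, tandem repeats, conserved flanks), dissects chimeric
    minichromosomes (partial-gene parentage and junction microhomology),
    and simulates fragmented genomes with known planted truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
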