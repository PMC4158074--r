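#' Bundled Hoplopleura minichromosome fixtures
#'
#' The package ships the published minichromosome arrangements of the two
#' Hoplopleura rodent lice (Ho. akanezumi, 10 minichromosomes plus one
#' chimeric; Ho. kitti, 11 minichromosomes) as a genome table, together with
#' the per-minichromosome Illumina read counts.
#'
#' @return `hoplopleura_genomes()`: named list of two [fragmented_genome()]
#'   objects.
#' @export
hoplopleura_genomes <- function() {
  read_genome_table(system.file("extdata", "hoplopleura_minichromosomes.tsv",
                                package = "minifrag", mustWork = TRUE))
}

#' @rdname hoplopleura_genomes
#' @return `hoplopleura_read_counts()`: data frame with `taxon`, `mini_id`,
#'   `coding_len`, `n_reads`.
#' @export
hoplopleura_read_counts <- function() {
  utils::read.delim(system.file("extdata", "hoplopleura_read_counts.tsv",
                                package = "minifrag", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Published presence/absence matrix of candidate ancestral run characters
#'
#' Presence/absence of nine gene-arrangement characters across 17 taxa (ten
#' blood-sucking lice plus outgroup lice, a barklouse and a hypothetical
#' insect ancestor), with clade assignments for the Anoplura taxa: the two
#' Hoplopleura species in one major clade, the human/pig/horse/Polyplax lice
#' in the other. Outgroup taxa carry `NA` clades and are ignored by
#' [infer_ancestral_characters()].
#'
#' @return List with `matrix` (logical, taxa x characters) and `clade_map`
#'   (named character vector; `NA` for outgroups).
#' @export
anoplura_character_table <- function() {
  tab <- utils::read.delim(system.file("extdata", "anoplura_characters.tsv",
                                       package = "minifrag", mustWork = TRUE),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = "NA")
  m <- as.matrix(tab[, setdiff(names(tab), c("taxon", "clade"))]) == "+"
  rownames(m) <- tab$taxon
  list(matrix = m, clade_map = stats::setNames(tab$clade, tab$taxon))
}

#' Published genus-level minichromosome presence table
#'
#' Full-minichromosome arrangements recorded across the ten blood-sucking
#' louse species investigated to date, with genus labels, for genus-specific
#' (candidate synapomorphic) minichromosome detection.
#'
#' @return List with `presence` (logical, taxa x arrangements) and `genus_map`.
#' @export
anoplura_genus_table <- function() {
  tab <- utils::read.delim(system.file("extdata", "anoplura_genus_minichromosomes.tsv",
                                       package = "minifrag", mustWork = TRUE),
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, setdiff(names(tab), c("taxon", "genus"))]) == "+"
  rownames(m) <- tab$taxon
  list(presence = m, genus_map = stats::setNames(tab$genus, tab$taxon))
}
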