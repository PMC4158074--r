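#' Census of unique genes and gene occurrences in a fragmented genome
#'
#' Counts gene occurrences and unique gene identities across a genome's
#' minichromosomes. Paralogous copies (e.g. trnY1/trnY2) collapse to one
#' identity, so a genome carrying both still counts tyrosine tRNA once.
#' Chimeric minichromosomes and partial genes are excluded unless
#' `include_partial = TRUE`.
#'
#' @param genome A [fragmented_genome()].
#' @param include_partial Include chimeric minichromosomes and partial genes.
#' @return A list of class `gene_census`: `n_unique`, `n_occurrences`,
#'   `by_class` (unique identities per functional class) and
#'   `n_minichromosomes`.
#' @export
unique_gene_census <- function(genome, include_partial = FALSE) {
  occ <- genome_occurrences(genome, include_chimeric = include_partial)
  if (!include_partial) occ <- occ[!occ$partial, , drop = FALSE]
  ids <- unique(occ$identity)
  by_class <- table(factor(gene_class(ids), c("protein", "rRNA", "tRNA")))
  structure(list(taxon = genome$taxon,
                 n_unique = length(ids),
                 n_occurrences = nrow(occ),
                 by_class = stats::setNames(as.integer(by_class), names(by_class)),
                 n_minichromosomes = length(core_minis(genome, include_partial))),
            class = "gene_census")
}

#' @export
print.gene_census <- function(x, ...) {
  cat("<gene_census> ", x$taxon, ": ", x$n_unique, " unique genes (",
      x$n_occurrences, " occurrences) on ", x$n_minichromosomes,
      " minichromosomes\n  by class: ",
      paste(names(x$by_class), x$by_class, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Canonical mitochondrial genes absent from a genome
#'
#' @param genome A [fragmented_genome()].
#' @return Sorted character vector: the 37-gene canon minus the identities
#'   found on non-chimeric minichromosomes (partial genes do not count as
#'   found).
#' @export
missing_canonical_genes <- function(genome) {
  occ <- genome_occurrences(genome)
  found <- unique(occ$identity[!occ$partial])
  sort(setdiff(mt_gene_set(), found))
}

#' tRNA census of a fragmented genome
#'
#' @param genome A [fragmented_genome()].
#' @return List with `n_unique` (tRNA identities, paralogs collapsed),
#'   `n_occurrences`, `n_minis_with_trna` and `n_minis` (chimeras excluded
#'   throughout).
#' @export
trna_census <- function(genome) {
  minis <- core_minis(genome)
  occ <- genome_occurrences(genome)
  trna <- occ[!occ$partial & occ$identity %in% MT_TRNA_GENES, , drop = FALSE]
  list(n_unique = length(unique(trna$identity)),
       n_occurrences = nrow(trna),
       n_minis_with_trna = length(unique(trna$mini)),
       n_minis = length(minis))
}
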