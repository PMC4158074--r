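#' Test whether two minichromosome arrangements are identical
#'
#' Identity requires equal gene count and position-wise equal gene identity
#' (paralog labels collapsed) and transcription orientation.
#'
#' @param a,b `minichromosome` objects, `arrangement` objects or arrangement
#'   strings.
#' @return Logical.
#' @export
#' @examples
#' arrangements_identical("atp8-atp6-N", "atp8-atp6-N")   # TRUE
#' arrangements_identical("D-Y-cox2", "D-Y-cox2-T")       # FALSE
arrangements_identical <- function(a, b) {
  as_arr <- function(x) {
    if (inherits(x, "minichromosome")) return(x$genes)
    if (is.character(x)) return(parse_arrangement(x))
    x
  }
  a <- as_arr(a); b <- as_arr(b)
  nrow(a) == nrow(b) &&
    all(a$identity == b$identity) &&
    all(a$strand == b$strand) &&
    all(a$partial == b$partial)
}

# Anchor of a minichromosome: the set of its protein-coding and rRNA gene
# identities, as a sorted key string. Empty for tRNA-only minichromosomes.
anchor_key <- function(mini) {
  ids <- unique(mini$genes$identity[!mini$genes$partial])
  ids <- ids[gene_class(ids) %in% c("protein", "rRNA")]
  paste(sort(ids), collapse = ",")
}

#' Pair homologous minichromosomes between two genomes
#'
#' Minichromosomes are paired across taxa by their anchor: the set of
#' protein-coding and rRNA gene identities they carry (tRNA content and gene
#' order are ignored for pairing, so e.g. D-Y-cox2 pairs with D-Y-cox2-T and
#' the pair then compares as non-identical). Chimeric minichromosomes never
#' participate. Minichromosomes without a counterpart are reported with `NA`
#' on the missing side.
#'
#' @param genome_a,genome_b [fragmented_genome()] objects.
#' @return A data frame of class `homolog_pairing` with columns `anchor`,
#'   `mini_a`, `mini_b`, `arrangement_a`, `arrangement_b`, `identical`, plus
#'   attributes `n_identical` and `n_differing`. `n_differing` counts, on the
#'   `genome_b` side, paired minichromosomes that are not identical plus
#'   B minichromosomes with no anchor match in A.
#' @export
pair_homologs <- function(genome_a, genome_b) {
  side <- function(g) {
    minis <- core_minis(g)
    keys <- vapply(minis, anchor_key, "")
    pairable <- nzchar(keys)
    if (anyDuplicated(keys[pairable])) {
      stop("duplicate minichromosome anchors within '", g$taxon, "': ",
           paste(unique(keys[pairable][duplicated(keys[pairable])]),
                 collapse = "; "))
    }
    list(minis = minis, keys = keys, pairable = pairable)
  }
  A <- side(genome_a); B <- side(genome_b)
  anchors <- union(A$keys[A$pairable], B$keys[B$pairable])
  rows <- lapply(anchors, function(k) {
    ia <- which(A$keys == k & A$pairable)
    ib <- which(B$keys == k & B$pairable)
    ma <- if (length(ia)) A$minis[[ia]] else NULL
    mb <- if (length(ib)) B$minis[[ib]] else NULL
    data.frame(
      anchor = k,
      mini_a = if (is.null(ma)) NA_character_ else ma$id,
      mini_b = if (is.null(mb)) NA_character_ else mb$id,
      arrangement_a = if (is.null(ma)) NA_character_ else
        format_arrangement(ma$genes, collapse_paralogs = TRUE),
      arrangement_b = if (is.null(mb)) NA_character_ else
        format_arrangement(mb$genes, collapse_paralogs = TRUE),
      identical = if (is.null(ma) || is.null(mb)) NA else
        arrangements_identical(ma, mb),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$anchor), , drop = FALSE]
  rownames(out) <- NULL
  n_identical <- sum(out$identical %in% TRUE)
  n_differing <- sum(out$identical %in% FALSE) + sum(is.na(out$mini_a))
  structure(out, class = c("homolog_pairing", "data.frame"),
            taxon_a = genome_a$taxon, taxon_b = genome_b$taxon,
            n_identical = n_identical, n_differing = n_differing)
}

#' @export
print.homolog_pairing <- function(x, ...) {
  cat("<homolog_pairing> ", attr(x, "taxon_a"), " vs ", attr(x, "taxon_b"),
      ": ", attr(x, "n_identical"), " identical, ", attr(x, "n_differing"),
      " differing (", attr(x, "taxon_b"), " side)\n", sep = "")
  print.data.frame(x)
  invisible(x)
}
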