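# Canonical character string for a run of gene occurrences: paralog labels
# collapsed, orientation marks kept, hyphen-joined.
run_key <- function(arr, i, j) {
  format_arrangement(arr[i:j, , drop = FALSE], collapse_paralogs = TRUE)
}

#' Extract ordered gene-run characters from a genome
#'
#' A gene-run character is a contiguous, ordered, orientation-sensitive run of
#' genes on one minichromosome, read in the majority-strand direction on the
#' NCR-anchored linearization. Runs never span the NCR (the NCR breaks gene
#' adjacency on the circle) and chimeric minichromosomes are excluded.
#' Paralog labels are collapsed, so `D-Y1-cox2` yields the character
#' `D-Y-cox2`.
#'
#' @param genome A [fragmented_genome()].
#' @param min_len,max_len Run length bounds (genes); `min_len` must be >= 2.
#' @return Sorted character vector of distinct run characters.
#' @export
#' @examples
#' # an arrangement of three genes has three runs of length >= 2
extract_run_characters <- function(genome, min_len = 2L, max_len = Inf) {
  if (min_len < 2L) stop("min_len must be >= 2 (a run is at least two genes)")
  runs <- character()
  for (m in core_minis(genome)) {
    L <- nrow(m$genes)
    if (L < min_len) next
    for (len in min_len:min(L, max_len)) {
      for (i in seq_len(L - len + 1L)) {
        runs <- c(runs, run_key(m$genes, i, i + len - 1L))
      }
    }
  }
  sort(unique(runs))
}

#' Build a presence/absence matrix of run characters across taxa
#'
#' @param genomes List of [fragmented_genome()] objects.
#' @param characters Character vector of run-character strings (columns).
#' @param extra_rows Optional logical matrix of precomputed presence rows
#'   (taxa whose full arrangements are not machine-readable), with column
#'   names matching `characters`.
#' @return Logical matrix, taxa in rows, characters in columns.
#' @export
build_character_matrix <- function(genomes, characters, extra_rows = NULL) {
  if (inherits(genomes, "fragmented_genome")) genomes <- list(genomes)
  characters <- as.character(characters)
  cells <- matrix(FALSE, nrow = length(genomes), ncol = length(characters),
                  dimnames = list(vapply(genomes, `[[`, "", "taxon"), characters))
  for (i in seq_along(genomes)) {
    if (length(characters) == 0L) break
    have <- extract_run_characters(genomes[[i]])
    cells[i, ] <- characters %in% have
  }
  if (!is.null(extra_rows)) {
    extra_rows <- as.matrix(extra_rows)
    if (!setequal(colnames(extra_rows), characters)) {
      stop("extra_rows columns must match `characters`")
    }
    cells <- rbind(cells, extra_rows[, characters, drop = FALSE] == TRUE)
  }
  if (anyDuplicated(rownames(cells))) stop("duplicate taxon names in matrix")
  cells
}

# Validate a clade map against matrix rows; returns the map restricted to
# taxa present in the matrix, dropping unassigned (outgroup) taxa.
resolve_clades <- function(taxa, clade_map) {
  clade_map <- clade_map[!is.na(clade_map)]
  unknown <- setdiff(names(clade_map), taxa)
  if (length(unknown)) {
    stop("clade map names unknown taxa: ", paste(unknown, collapse = ", "))
  }
  map <- clade_map[intersect(taxa, names(clade_map))]
  clades <- unique(map)
  if (length(clades) != 2L) {
    stop("exactly two clades with at least one taxon each are required; got ",
         length(clades))
  }
  map
}

#' Infer ancestral gene-arrangement characters under the two-clade rule
#'
#' A run character is inferred to be ancestral for a group that diversified
#' into two major clades when it is present in at least one taxon from each
#' clade: a shared arrangement on both sides of the basal split is most
#' parsimoniously inherited from the most recent common ancestor.
#'
#' @param matrix Logical presence/absence matrix (taxa x characters), e.g.
#'   from [build_character_matrix()].
#' @param clade_map Named character vector mapping taxa to one of two clade
#'   labels. Taxa absent from the map (or mapped to `NA`) are outgroups and
#'   are ignored.
#' @return Character vector of ancestral characters, in column order.
#' @export
infer_ancestral_characters <- function(matrix, clade_map) {
  map <- resolve_clades(rownames(matrix), clade_map)
  clades <- unique(map)
  in_a <- matrix[names(map)[map == clades[1]], , drop = FALSE]
  in_b <- matrix[names(map)[map == clades[2]], , drop = FALSE]
  ancestral <- apply(in_a, 2, any) & apply(in_b, 2, any)
  colnames(matrix)[ancestral]
}

# Is run `small` a contiguous ordered sub-run of `big` (orientation kept)?
run_contained <- function(small, big) {
  if (identical(small, big)) return(TRUE)
  s <- strsplit(small, "-", fixed = TRUE)[[1]]
  b <- strsplit(big, "-", fixed = TRUE)[[1]]
  k <- length(s); n <- length(b)
  if (k >= n) return(FALSE)
  for (i in seq_len(n - k + 1L)) {
    if (all(b[i:(i + k - 1L)] == s)) return(TRUE)
  }
  FALSE
}

#' Maximal ancestral gene runs across two clades
#'
#' Applies the two-clade rule to all run characters extractable from the
#' supplied genomes and removes characters contained within a longer ancestral
#' character that is witnessed by exactly the same taxa (a shorter run adds no
#' information when every taxon carrying it carries the longer run too).
#'
#' @param genomes List of [fragmented_genome()] objects.
#' @param clade_map Named character vector mapping taxa to two clade labels.
#' @return Sorted character vector of maximal ancestral run characters.
#' @export
find_maximal_shared_runs <- function(genomes, clade_map) {
  if (inherits(genomes, "fragmented_genome")) genomes <- list(genomes)
  all_runs <- sort(unique(unlist(lapply(genomes, extract_run_characters))))
  mat <- build_character_matrix(genomes, all_runs)
  ancestral <- infer_ancestral_characters(mat, clade_map)
  if (length(ancestral) == 0L) return(character())
  witnesses <- lapply(ancestral, function(ch) rownames(mat)[mat[, ch]])
  n_tokens <- lengths(strsplit(ancestral, "-", fixed = TRUE))
  keep <- vapply(seq_along(ancestral), function(i) {
    !any(vapply(seq_along(ancestral), function(j) {
      i != j && n_tokens[j] > n_tokens[i] &&
        run_contained(ancestral[i], ancestral[j]) &&
        setequal(witnesses[[i]], witnesses[[j]])
    }, NA))
  }, NA)
  sort(ancestral[keep])
}

#' Genus-specific (candidate synapomorphic) minichromosome arrangements
#'
#' A full-minichromosome arrangement is genus-specific when it is present in
#' every sampled member of exactly one genus and absent from all other taxa.
#' Such arrangements are candidate synapomorphies for that genus.
#'
#' @param genomes List of [fragmented_genome()] objects, or `NULL` when
#'   `presence` is supplied.
#' @param genus_map Named character vector mapping taxa to genera; defaults to
#'   the genomes' own `genus` fields.
#' @param presence Optional logical matrix (taxa x arrangements) of
#'   precomputed full-arrangement presence, used instead of `genomes`.
#' @return Named list mapping each genus to its sorted genus-specific
#'   arrangements (genera with none are omitted). With a single genus, every
#'   arrangement shared by all its members is returned, with a warning.
#' @export
find_genus_specific_minichromosomes <- function(genomes = NULL, genus_map = NULL,
                                                presence = NULL) {
  if (is.null(presence)) {
    if (inherits(genomes, "fragmented_genome")) genomes <- list(genomes)
    arrangements <- sort(unique(unlist(lapply(genomes, function(g) {
      vapply(core_minis(g), function(m) {
        format_arrangement(m$genes, collapse_paralogs = TRUE)
      }, "")
    }))))
    taxa <- vapply(genomes, `[[`, "", "taxon")
    presence <- matrix(FALSE, length(taxa), length(arrangements),
                       dimnames = list(taxa, arrangements))
    for (i in seq_along(genomes)) {
      have <- vapply(core_minis(genomes[[i]]), function(m) {
        format_arrangement(m$genes, collapse_paralogs = TRUE)
      }, "")
      presence[i, ] <- arrangements %in% have
    }
    if (is.null(genus_map)) {
      genus_map <- stats::setNames(vapply(genomes, `[[`, "", "genus"), taxa)
    }
  }
  taxa <- rownames(presence)
  genus_map <- genus_map[taxa]
  if (anyNA(genus_map)) stop("every taxon needs a genus label")
  genera <- unique(genus_map)
  if (length(genera) < 2L) {
    warning("only one genus supplied; every arrangement shared by all its ",
            "members is reported")
  }
  out <- lapply(genera, function(g) {
    members <- taxa[genus_map == g]
    others <- setdiff(taxa, members)
    hits <- vapply(colnames(presence), function(a) {
      all(presence[members, a]) &&
        (length(others) == 0L || !any(presence[others, a]))
    }, NA)
    sort(colnames(presence)[hits])
  })
  names(out) <- genera
  out[vapply(out, length, 0L) > 0L]
}
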