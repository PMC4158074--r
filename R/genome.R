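#' Construct a minichromosome record
#'
#' A minichromosome is a small circular mitochondrial chromosome consisting of
#' a coding region and a non-coding region (NCR). It is represented here
#' linearized at the NCR/coding boundary: position 0 is the first base of the
#' coding region, the NCR follows the coding region, and gene order is read
#' 5'-to-3' in the majority transcription orientation. Coordinates are 0-based
#' and half-open. A minichromosome is chimeric when its arrangement contains
#' partial genes (tokens with the `p` prefix).
#'
#' @param id Minichromosome label (unique within a taxon).
#' @param arrangement An `arrangement` object or an arrangement string.
#' @param coding_len,ncr_len Optional lengths in bp.
#' @param sequence Optional nucleotide sequence of the full (linearized)
#'   minichromosome; when both lengths are given its length must equal
#'   `coding_len + ncr_len`.
#' @param seq_id Optional identifier linking the record to a FASTA entry.
#' @return An object of class `minichromosome`.
#' @export
minichromosome <- function(id, arrangement, coding_len = NA_integer_,
                           ncr_len = NA_integer_, sequence = NULL,
                           seq_id = NA_character_) {
  if (is.character(arrangement)) arrangement <- parse_arrangement(arrangement)
  if (nrow(arrangement) == 0L) stop("minichromosome '", id, "' has no genes")
  if (!is.na(coding_len) && coding_len < 0) stop("coding_len must be >= 0")
  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (!is.na(coding_len) && !is.na(ncr_len) &&
        nchar(sequence) != coding_len + ncr_len) {
      stop("sequence length (", nchar(sequence), ") of minichromosome '", id,
           "' does not equal coding_len + ncr_len (", coding_len + ncr_len, ")")
    }
  }
  structure(list(id = as.character(id), genes = arrangement,
                 coding_len = as.integer(coding_len),
                 ncr_len = as.integer(ncr_len),
                 sequence = sequence, seq_id = as.character(seq_id),
                 chimeric = any(arrangement$partial)),
            class = "minichromosome")
}

#' @export
print.minichromosome <- function(x, ...) {
  cat("<minichromosome> ", x$id, ": ", format_arrangement(x$genes),
      if (x$chimeric) " [chimeric]",
      if (!is.na(x$coding_len)) paste0(" (coding ", x$coding_len, " bp",
        if (!is.na(x$ncr_len)) paste0(", NCR ", x$ncr_len, " bp"), ")"),
      "\n", sep = "")
  invisible(x)
}

#' Construct a fragmented mitochondrial genome
#'
#' A taxon's mitochondrial genome as a set of minichromosomes, with genus and
#' clade metadata used by the comparative and ancestral-inference operations.
#' Enforces that minichromosome ids are unique and that every non-partial gene
#' identity occurs on at most one minichromosome unless its copies carry
#' paralog labels (e.g. Y1/Y2).
#'
#' @param taxon Taxon name.
#' @param minichromosomes List of [minichromosome()] objects.
#' @param genus,clade Optional metadata labels.
#' @return An object of class `fragmented_genome`.
#' @export
fragmented_genome <- function(taxon, minichromosomes, genus = NA_character_,
                              clade = NA_character_) {
  ids <- vapply(minichromosomes, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate minichromosome ids in '", taxon, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  occ <- if (length(minichromosomes)) {
    do.call(rbind, lapply(minichromosomes, function(m) {
      cbind(m$genes, mini = m$id, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(identity = character(), paralog = character(),
               partial = logical(), strand = character(), mini = character())
  }
  plain <- occ[!occ$partial & is.na(occ$paralog), , drop = FALSE]
  dup <- unique(plain$identity[duplicated(plain$identity)])
  if (length(dup)) {
    stop("gene(s) ", paste(dup, collapse = ", "), " occur on more than one ",
         "minichromosome of '", taxon, "' without paralog labels")
  }
  names(minichromosomes) <- ids
  structure(list(taxon = as.character(taxon), genus = as.character(genus),
                 clade = as.character(clade),
                 minichromosomes = minichromosomes),
            class = "fragmented_genome")
}

#' @export
print.fragmented_genome <- function(x, ...) {
  cat("<fragmented_genome> ", x$taxon,
      if (!is.na(x$genus)) paste0(" (genus ", x$genus,
        if (!is.na(x$clade)) paste0(", clade ", x$clade), ")"),
      ": ", length(x$minichromosomes), " minichromosomes\n", sep = "")
  for (m in x$minichromosomes) {
    cat("  ", m$id, ": ", format_arrangement(m$genes),
        if (m$chimeric) " [chimeric]", "\n", sep = "")
  }
  invisible(x)
}

# Minichromosomes used in censuses and comparisons: chimeras are excluded
# unless explicitly requested.
core_minis <- function(genome, include_chimeric = FALSE) {
  keep <- vapply(genome$minichromosomes, function(m) {
    include_chimeric || !m$chimeric
  }, NA)
  genome$minichromosomes[keep]
}

# All gene occurrences of a genome as one data frame.
genome_occurrences <- function(genome, include_chimeric = FALSE) {
  minis <- core_minis(genome, include_chimeric)
  if (length(minis) == 0L) {
    return(cbind(new_arrangement(character(), character(), logical(),
                                 character()), mini = character()))
  }
  do.call(rbind, lapply(minis, function(m) {
    cbind(m$genes, mini = m$id, stringsAsFactors = FALSE)
  }))
}

GENOME_TABLE_COLS <- c("taxon", "genus", "clade", "mini_id", "arrangement",
                       "coding_len", "ncr_len", "seq_id")

#' Read a genome table of minichromosome arrangements
#'
#' Reads a tab-separated table with columns `taxon`, `genus`, `clade`,
#' `mini_id`, `arrangement`, `coding_len`, `ncr_len`, `seq_id` (one row per
#' minichromosome) and groups rows into [fragmented_genome()] objects.
#' Parse and invariant failures are reported with the offending row number.
#'
#' @param path Path to the TSV file.
#' @return Named list of `fragmented_genome` objects, one per taxon, in order
#'   of first appearance.
#' @seealso [write_genome_table()]
#' @export
read_genome_table <- function(path) {
  if (!file.exists(path)) stop("genome table not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""))
  if (nrow(tab) == 0L) stop("genome table '", path, "' is empty")
  missing_cols <- setdiff(GENOME_TABLE_COLS, names(tab))
  if (length(missing_cols)) {
    stop("genome table '", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  key <- paste(tab$taxon, tab$mini_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (taxon, mini_id) at row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  rows_to_genome <- function(rows) {
    minis <- lapply(seq_len(nrow(rows)), function(i) {
      arr <- tryCatch(parse_arrangement(rows$arrangement[i]), error = function(e) {
        stop("row ", rownames(rows)[i], ": ", conditionMessage(e), call. = FALSE)
      })
      minichromosome(rows$mini_id[i], arr,
                     coding_len = rows$coding_len[i], ncr_len = rows$ncr_len[i],
                     seq_id = rows$seq_id[i])
    })
    fragmented_genome(rows$taxon[1], minis, genus = rows$genus[1],
                      clade = rows$clade[1])
  }
  taxa <- unique(tab$taxon)
  stats::setNames(lapply(taxa, function(t) {
    rows_to_genome(tab[tab$taxon == t, , drop = FALSE])
  }), taxa)
}

#' Write genomes to a genome table TSV
#'
#' Inverse of [read_genome_table()]; round-trips losslessly.
#'
#' @param genomes A `fragmented_genome` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_table <- function(genomes, path) {
  if (inherits(genomes, "fragmented_genome")) genomes <- list(genomes)
  rows <- do.call(rbind, lapply(genomes, function(g) {
    do.call(rbind, lapply(g$minichromosomes, function(m) {
      data.frame(taxon = g$taxon, genus = g$genus, clade = g$clade,
                 mini_id = m$id, arrangement = format_arrangement(m$genes),
                 coding_len = m$coding_len, ncr_len = m$ncr_len,
                 seq_id = m$seq_id, stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read nucleotide sequences from a FASTA file
#'
#' Sequences are validated against the IUPAC DNA alphabet and uppercased on
#' ingest; record ids are the first whitespace-delimited word of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    # the reader silently drops invalid letters with a warning; treat any
    # parser warning as malformed input
    warning = function(w) stop("malformed FASTA '", path, "': ",
                               conditionMessage(w), call. = FALSE))
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^ACGTRYSWKMBDHVN]", out)
  if (any(bad)) {
    stop("non-IUPAC characters in FASTA record(s): ",
         paste(names(out)[bad], collapse = ", "))
  }
  out
}

#' Write named sequences to a FASTA file
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Attach sequences from a FASTA file to a genome's minichromosomes
#'
#' Matches each minichromosome's `seq_id` against FASTA record names.
#'
#' @param genome A `fragmented_genome`.
#' @param seqs Named character vector (e.g. from [read_fasta()]).
#' @return The genome with `sequence` filled in where a record matched.
#' @export
attach_sequences <- function(genome, seqs) {
  genome$minichromosomes <- lapply(genome$minichromosomes, function(m) {
    if (!is.na(m$seq_id) && m$seq_id %in% names(seqs)) {
      m$sequence <- toupper(seqs[[m$seq_id]])
    }
    m
  })
  genome
}

#' Non-coding region of a minichromosome
#'
#' On the NCR-anchored linearization the coding region occupies positions
#' `[0, coding_len)` and the NCR the remainder, so the NCR runs from the base
#' after the coding 3' end around the circle to the base before the coding
#' 5' start.
#'
#' @param mini A `minichromosome` with `sequence` and `coding_len` set.
#' @return The NCR sequence.
#' @export
ncr_sequence <- function(mini) {
  if (is.null(mini$sequence) || is.na(mini$coding_len)) {
    stop("minichromosome '", mini$id, "' lacks a sequence or coding_len")
  }
  substring(mini$sequence, mini$coding_len + 1L, nchar(mini$sequence))
}
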