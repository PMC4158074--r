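#' @useDynLib minifrag, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# The 37 mitochondrial genes typical of bilaterian animals: 13 protein-coding,
# 2 rRNA, 22 tRNA. tRNAs use single-letter amino-acid abbreviations; the two
# serine and two leucine tRNAs are distinguished by anticodon class
# (S1: tct, S2: tga, L1: tag, L2: taa).
MT_PROTEIN_GENES <- c("atp6", "atp8", "cox1", "cox2", "cox3", "cob",
                      "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
MT_RRNA_GENES <- c("rrnS", "rrnL")
MT_TRNA_GENES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2",
                   "M", "N", "P", "Q", "R", "S1", "S2", "T", "V", "W", "Y")
ANTICODON_CLASS <- c(tct = "S1", tga = "S2", tag = "L1", taa = "L2")

#' The canonical bilaterian mitochondrial gene set
#'
#' Returns the closed vocabulary of 37 mitochondrial gene identities: 13
#' protein-coding genes, 2 rRNA genes and 22 tRNA genes (single-letter
#' amino-acid abbreviations, with the serine and leucine isoacceptors
#' disambiguated as S1/S2 and L1/L2).
#'
#' @param class Optional subset: one of `"protein"`, `"rRNA"`, `"tRNA"`.
#' @return Character vector of gene identities.
#' @export
#' @examples
#' length(mt_gene_set())  # 37
mt_gene_set <- function(class = NULL) {
  if (is.null(class)) {
    return(c(MT_PROTEIN_GENES, MT_RRNA_GENES, MT_TRNA_GENES))
  }
  switch(match.arg(class, c("protein", "rRNA", "tRNA")),
         protein = MT_PROTEIN_GENES,
         rRNA = MT_RRNA_GENES,
         tRNA = MT_TRNA_GENES)
}

#' Functional class of a gene identity
#'
#' @param identity Character vector of canonical gene identities.
#' @return Character vector: `"protein"`, `"rRNA"` or `"tRNA"`.
#' @export
gene_class <- function(identity) {
  out <- rep(NA_character_, length(identity))
  out[identity %in% MT_PROTEIN_GENES] <- "protein"
  out[identity %in% MT_RRNA_GENES] <- "rRNA"
  out[identity %in% MT_TRNA_GENES] <- "tRNA"
  if (anyNA(out)) {
    stop("unknown gene identity: ",
         paste(unique(identity[is.na(out)]), collapse = ", "))
  }
  out
}

# Case-insensitive lookup of a bare token against the canon. Returns the
# canonical spelling or NA.
match_canon <- function(x) {
  canon <- mt_gene_set()
  hit <- match(tolower(x), tolower(canon))
  if (is.na(hit)) NA_character_ else canon[hit]
}

# Resolve one raw token (no orientation mark, no partial prefix) to
# (identity, paralog). Handles the trn prefix, anticodon parentheses and
# numeric paralog suffixes. Returns NULL if unresolvable.
resolve_core_token <- function(x) {
  paralog <- NA_character_
  anticodon <- NA_character_

  m <- regmatches(x, regexec("^(.*)\\(([acgut]{3})\\)$", x, ignore.case = TRUE))[[1]]
  if (length(m) == 3) {
    x <- m[2]
    anticodon <- tolower(chartr("u", "t", m[3]))
  }
  x <- sub("^trn", "", x, ignore.case = TRUE)

  direct <- match_canon(x)
  if (is.na(direct) && grepl("^[A-Za-z][0-9]+$", x)) {
    # Single tRNA letter with a copy-number suffix, e.g. Y2. The S/L digits
    # are anticodon classes (part of the identity), never paralog labels,
    # and are caught by the direct match above.
    letter <- match_canon(substr(x, 1, 1))
    if (!is.na(letter) && letter %in% MT_TRNA_GENES) {
      direct <- letter
      paralog <- paste0(letter, substr(x, 2, nchar(x)))
    }
  }
  if (is.na(direct) && !is.na(anticodon)) {
    # A bare S or L (or nothing useful) disambiguated by its anticodon.
    cls <- unname(ANTICODON_CLASS[anticodon])
    if (!is.na(cls) && (tolower(x) %in% c("s", "l", tolower(cls)))) direct <- cls
  }
  if (is.na(direct)) return(NULL)
  if (!is.na(anticodon)) {
    cls <- unname(ANTICODON_CLASS[anticodon])
    if (is.na(cls) || !identical(cls, direct)) {
      stop("anticodon '", anticodon, "' does not match gene '", direct, "'")
    }
  }
  list(identity = direct, paralog = paralog)
}

#' Normalize a raw gene name to a canonical gene token
#'
#' Recognizes the 37-gene mitochondrial vocabulary case-insensitively,
#' including `trn` prefixes (`trnN` = `N`), anticodon parentheses
#' (`trnL2(taa)` or `trnL(taa)` = `L2`), copy-number paralog suffixes
#' (`Y2` keeps identity `Y` with paralog label `Y2`) and the `p` prefix for
#' partial genes (`prrnS` = partial `rrnS`).
#'
#' @param raw A single non-empty gene name string.
#' @return A list of class `gene_token` with elements `identity`, `paralog`
#'   (`NA` if none) and `partial` (logical).
#' @export
#' @examples
#' normalize_gene_token("trnL2(taa)")
#' normalize_gene_token("prrnS")
normalize_gene_token <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(trimws(raw))) {
    stop("gene token must be a single non-empty string")
  }
  x <- trimws(raw)
  tok <- resolve_core_token(x)
  partial <- FALSE
  if (is.null(tok) && grepl("^p", x) && nchar(x) > 1L) {
    tok <- resolve_core_token(substring(x, 2L))
    partial <- !is.null(tok)
  }
  if (is.null(tok)) {
    stop("unknown gene token: '", raw, "' (not in the 37-gene mitochondrial vocabulary)")
  }
  structure(list(identity = tok$identity, paralog = tok$paralog, partial = partial),
            class = "gene_token")
}

#' @export
print.gene_token <- function(x, ...) {
  cat("<gene_token> ", format_token(x$identity, x$paralog, x$partial),
      " [", gene_class(x$identity), "]\n", sep = "")
  invisible(x)
}

format_token <- function(identity, paralog, partial) {
  label <- ifelse(is.na(paralog), identity, paralog)
  ifelse(partial, paste0("p", label), label)
}

new_arrangement <- function(identity, paralog, partial, strand) {
  structure(
    data.frame(identity = identity, paralog = paralog, partial = partial,
               strand = strand, stringsAsFactors = FALSE),
    class = c("arrangement", "data.frame"))
}

#' Parse a hyphen-joined gene arrangement string
#'
#' Arrangements are written as hyphen-separated gene tokens in the order they
#' occur on the minichromosome, linearized at the non-coding region (NCR) and
#' read 5'-to-3' in the majority transcription orientation. A `~` prefix marks
#' a gene transcribed in the opposite orientation.
#'
#' @param text Arrangement string, e.g. `"atp8-atp6-N"` or `"~Q-~nad1-G-nad3"`.
#' @return An object of class `arrangement`: a data frame with columns
#'   `identity`, `paralog`, `partial` and `strand` (`"+"` or `"-"`), one row
#'   per gene occurrence.
#' @seealso [format_arrangement()]
#' @export
#' @examples
#' parse_arrangement("atp8-atp6-N")
parse_arrangement <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("arrangement string must be a single non-empty string")
  }
  text <- trimws(text)
  if (grepl("^-|-$|--", text)) {
    stop("malformed arrangement '", text, "': empty token (dangling separator?)")
  }
  pieces <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (length(pieces) == 0L || any(!nzchar(trimws(pieces)))) {
    stop("malformed arrangement '", text, "': empty token (dangling separator?)")
  }
  pieces <- trimws(pieces)
  minus <- startsWith(pieces, "~")
  pieces[minus] <- substring(pieces[minus], 2L)
  toks <- lapply(pieces, normalize_gene_token)
  new_arrangement(
    identity = vapply(toks, `[[`, "", "identity"),
    paralog = vapply(toks, `[[`, "", "paralog"),
    partial = vapply(toks, `[[`, NA, "partial"),
    strand = ifelse(minus, "-", "+"))
}

#' Format a gene arrangement back to its string form
#'
#' Inverse of [parse_arrangement()]: `parse_arrangement(format_arrangement(x))`
#' reproduces `x`.
#'
#' @param genes An `arrangement` object (or data frame with columns `identity`,
#'   `paralog`, `partial`, `strand`).
#' @param collapse_paralogs If `TRUE`, paralog labels are dropped so that e.g.
#'   `Y1` prints as `Y`; used when arrangements are compared as characters.
#' @return A single arrangement string.
#' @export
format_arrangement <- function(genes, collapse_paralogs = FALSE) {
  if (is.null(genes) || nrow(genes) == 0L) stop("empty arrangement")
  paralog <- if (collapse_paralogs) rep(NA_character_, nrow(genes)) else genes$paralog
  tok <- format_token(genes$identity, paralog, genes$partial)
  tok[genes$strand == "-"] <- paste0("~", tok[genes$strand == "-"])
  paste(tok, collapse = "-")
}

#' @export
print.arrangement <- function(x, ...) {
  cat("<arrangement> ", format_arrangement(x), "\n", sep = "")
  invisible(x)
}
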