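# Best match between the (masked) chimera and one parent. Exact mode uses the
# LCS kernel; approximate mode uses a Smith-Waterman local alignment and
# accepts it only at or above the identity floor. Returns NULL when nothing
# is found.
best_parent_match <- function(chimera, parent, min_identity) {
  if (min_identity >= 1) {
    r <- .lcs_dp(chimera, parent)
    if (r[1] == 0L) return(NULL)
    return(list(len = r[1], c_start = r[2], c_end = r[2] + r[1] - 1L,
                p_start = r[3], p_end = r[3] + r[1] - 1L, identity = 100))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  # masked chimera positions ('#') become N: never a positive score, so
  # alignments cannot reuse already-assigned regions
  chimera <- gsub("#", "N", chimera, fixed = TRUE)
  aln <- Biostrings::pairwiseAlignment(chimera, parent, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 0.5)
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  if (cols == 0L) return(NULL)
  identity <- 100 * Biostrings::nmatch(aln) / cols
  if (identity < 100 * min_identity) return(NULL)
  pr <- Biostrings::pattern(aln)
  sr <- Biostrings::subject(aln)
  c_start <- BiocGenerics::start(pr); c_end <- BiocGenerics::end(pr)
  list(len = c_end - c_start + 1L, c_start = c_start, c_end = c_end,
       p_start = BiocGenerics::start(sr), p_end = BiocGenerics::end(sr),
       identity = identity)
}

#' Map the partial-gene segments of a chimeric minichromosome to their parents
#'
#' Chimeric minichromosomes carry partial copies of genes from different
#' parental minichromosomes. Segments of the chimera's coding region are
#' assigned to parent genes greedily, longest match first: the best match
#' across all parents is recorded, the matched chimera region is masked, and
#' the search repeats until no match of at least `min_anchor` bp remains.
#' Matching is exact by default; set `min_identity` below 1 to accept
#' diverged copies via local alignment.
#'
#' @param chimera Coding-region sequence of the chimeric minichromosome.
#' @param parents Named character vector of full-length parent gene sequences.
#' @param min_anchor Minimum segment length, bp.
#' @param min_identity Identity floor for approximate matching (1 = exact).
#' @return Data frame, one row per segment ordered by chimera position:
#'   `parent`, `chimera_start`, `chimera_end`, `parent_start`, `parent_end`
#'   (1-based, inclusive), `length`, `fraction` (segment length over parent
#'   length) and `identity` (percent).
#' @export
map_partial_genes <- function(chimera, parents, min_anchor = 20L,
                              min_identity = 1) {
  chimera <- toupper(chimera)
  parents <- toupper(parents)
  if (is.null(names(parents)) || any(!nzchar(names(parents)))) {
    stop("parents must be a named sequence vector")
  }
  masked <- chimera
  segs <- list()
  repeat {
    best <- NULL; best_parent <- NA_character_
    for (p in names(parents)) {
      m <- best_parent_match(masked, parents[[p]], min_identity)
      if (!is.null(m) && m$len >= min_anchor &&
          (is.null(best) || m$len > best$len)) {
        best <- m; best_parent <- p
      }
    }
    if (is.null(best)) break
    segs[[length(segs) + 1L]] <- data.frame(
      parent = best_parent, chimera_start = best$c_start,
      chimera_end = best$c_end, parent_start = best$p_start,
      parent_end = best$p_end, length = best$len,
      fraction = (best$p_end - best$p_start + 1L) / nchar(parents[[best_parent]]),
      identity = best$identity, stringsAsFactors = FALSE)
    mask <- paste(rep("#", best$len), collapse = "")
    substring(masked, best$c_start, best$c_end) <- mask
  }
  if (length(segs) == 0L) {
    stop("no parent segment of at least ", min_anchor,
         " bp matches the chimera")
  }
  out <- do.call(rbind, segs)
  out <- out[order(out$chimera_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Microhomology at the junction of two mapped chimera segments
#'
#' At a recombination junction formed by microhomology-mediated joining, a
#' short sequence is shared by both parents adjacent to their breakpoints,
#' making the exact breakpoint position ambiguous. The ambiguity window is
#' measured in both directions: how far the chimera sequence immediately
#' before the junction also occurs in parent B just before its segment start,
#' and how far the sequence immediately after the junction also occurs in
#' parent A just after its segment end. The microhomology length is the sum;
#' lengths below `k_min` are reported as none (0).
#'
#' @param chimera Chimera coding-region sequence.
#' @param segment_a,segment_b Two adjacent rows of a [map_partial_genes()]
#'   table (`segment_b` must start right after `segment_a` ends).
#' @param parents Named parent sequences (as passed to [map_partial_genes()]).
#' @param k_min Minimum length to call microhomology.
#' @return List with `length` (0 when none), `segment` (`NA` when none) and
#'   `junction` (1-based position of the last base of `segment_a`).
#' @export
detect_junction_microhomology <- function(chimera, segment_a, segment_b,
                                          parents, k_min = 3L) {
  chimera <- toupper(chimera); parents <- toupper(parents)
  if (segment_b$chimera_start != segment_a$chimera_end + 1L) {
    stop("segments are not adjacent on the chimera")
  }
  j <- segment_a$chimera_end
  pa <- parents[[segment_a$parent]]
  pb <- parents[[segment_b$parent]]
  # left reach: chimera bases ending at the junction also present in parent B
  # immediately upstream of its breakpoint
  h1 <- 0L
  while (j - h1 >= segment_a$chimera_start &&
         segment_b$parent_start - h1 - 1L >= 1L &&
         substring(chimera, j - h1, j - h1) ==
         substring(pb, segment_b$parent_start - h1 - 1L,
                   segment_b$parent_start - h1 - 1L)) {
    h1 <- h1 + 1L
  }
  # right reach: chimera bases starting after the junction also present in
  # parent A immediately downstream of its breakpoint
  h2 <- 0L
  while (j + h2 + 1L <= segment_b$chimera_end &&
         segment_a$parent_end + h2 + 1L <= nchar(pa) &&
         substring(chimera, j + h2 + 1L, j + h2 + 1L) ==
         substring(pa, segment_a$parent_end + h2 + 1L,
                   segment_a$parent_end + h2 + 1L)) {
    h2 <- h2 + 1L
  }
  len <- h1 + h2
  if (len < k_min) {
    return(list(length = 0L, segment = NA_character_, junction = j))
  }
  list(length = len, segment = substring(chimera, j - h1 + 1L, j + h2),
       junction = j)
}

#' Full analysis of a chimeric minichromosome
#'
#' Maps partial-gene segments to parents with [map_partial_genes()] and scans
#' every junction between consecutive adjacent segments for microhomology.
#'
#' @inheritParams map_partial_genes
#' @inheritParams detect_junction_microhomology
#' @return List of class `chimera_report` with `segments` (data frame) and
#'   `junctions` (data frame with `position`, `microhomology_len`,
#'   `microhomology`).
#' @export
chimera_report <- function(chimera, parents, min_anchor = 20L,
                           min_identity = 1, k_min = 3L) {
  segs <- map_partial_genes(chimera, parents, min_anchor, min_identity)
  junctions <- data.frame(position = integer(), microhomology_len = integer(),
                          microhomology = character(), stringsAsFactors = FALSE)
  if (nrow(segs) > 1L) {
    for (i in seq_len(nrow(segs) - 1L)) {
      if (segs$chimera_start[i + 1L] != segs$chimera_end[i] + 1L) next
      mh <- detect_junction_microhomology(chimera, segs[i, ], segs[i + 1L, ],
                                          parents, k_min = k_min)
      junctions <- rbind(junctions, data.frame(
        position = mh$junction, microhomology_len = mh$length,
        microhomology = mh$segment, stringsAsFactors = FALSE))
    }
  }
  structure(list(segments = segs, junctions = junctions),
            class = "chimera_report")
}

#' @export
print.chimera_report <- function(x, ...) {
  cat("<chimera_report> ", nrow(x$segments), " parent segments, ",
      nrow(x$junctions), " junction(s) scanned\n", sep = "")
  print.data.frame(x$segments)
  if (nrow(x$junctions)) print.data.frame(x$junctions)
  invisible(x)
}
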