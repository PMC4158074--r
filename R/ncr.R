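# Locally-maximal segments of a 0/1 indicator with fraction >= threshold and
# length >= min_len: no single-base extension (within the window) keeps the
# fraction at or above the threshold, and no reported segment is contained in
# another reported segment. Brute force; windows are small (<= a few hundred
# bp).
maximal_dense_segments <- function(flag, min_len, threshold) {
  n <- length(flag)
  if (n < min_len) return(data.frame(start = integer(), end = integer(),
                                     fraction = numeric()))
  cs <- c(0L, cumsum(flag))
  qualifies <- function(i, j) {
    i >= 1L && j <= n && (cs[j + 1L] - cs[i]) / (j - i + 1L) >= threshold
  }
  hits <- list()
  for (i in seq_len(n - min_len + 1L)) {
    for (j in (i + min_len - 1L):n) {
      if (qualifies(i, j) && !qualifies(i - 1L, j) && !qualifies(i, j + 1L)) {
        hits[[length(hits) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(hits) == 0L) return(data.frame(start = integer(), end = integer(),
                                            fraction = numeric()))
  m <- do.call(rbind, hits)
  contained <- vapply(seq_len(nrow(m)), function(k) {
    any(m[, 1] <= m[k, 1] & m[, 2] >= m[k, 2] &
          (m[, 1] != m[k, 1] | m[, 2] != m[k, 2]))
  }, NA)
  m <- m[!contained, , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2],
             fraction = (cs[m[, 2] + 1L] - cs[m[, 1]]) / (m[, 2] - m[, 1] + 1L))
}

#' Scan a non-coding region for AT-rich and GC-rich boundary motifs
#'
#' Louse minichromosome NCRs carry an AT-rich motif just upstream of the
#' coding region's 5' end and a GC-rich motif just downstream of its 3' end.
#' On the NCR-anchored linearization the NCR starts at the coding 3' end, so
#' the downstream (GC-rich) boundary is the start of the NCR and the upstream
#' (AT-rich) boundary is its end. The scan reports maximal segments of length
#' at least `min_len` whose AT (respectively GC) fraction meets the threshold,
#' within a window adjacent to each boundary.
#'
#' @param ncr NCR sequence (linearized as above).
#' @param min_len Minimum motif length in bp.
#' @param at_threshold,gc_threshold Composition thresholds, in (0.5, 1].
#' @param window Search window adjacent to each boundary, bp.
#' @return Data frame with one row per hit: `kind` (`"AT-rich"`/`"GC-rich"`),
#'   `boundary` (`"upstream-of-coding"`/`"downstream-of-coding"`), `start`,
#'   `end` (0-based half-open, on the NCR), `length`, `fraction`.
#' @export
scan_composition_motifs <- function(ncr, min_len = 40L, at_threshold = 0.75,
                                    gc_threshold = 0.75, window = 200L) {
  for (t in c(at_threshold, gc_threshold)) {
    if (t <= 0.5 || t > 1) stop("composition thresholds must be in (0.5, 1]")
  }
  chars <- strsplit(toupper(ncr), "", fixed = TRUE)[[1]]
  n <- length(chars)
  down_end <- min(window, n)
  up_start <- max(1L, n - window + 1L)
  hit_rows <- function(offset, flag, threshold, kind, boundary) {
    seg <- maximal_dense_segments(flag, min_len, threshold)
    if (nrow(seg) == 0L) return(NULL)
    data.frame(kind = kind, boundary = boundary,
               start = offset + seg$start - 2L,  # 0-based half-open
               end = offset + seg$end - 1L,
               length = seg$end - seg$start + 1L,
               fraction = seg$fraction, stringsAsFactors = FALSE)
  }
  down <- chars[seq_len(down_end)]
  up <- chars[up_start:n]
  out <- rbind(
    hit_rows(up_start, up %in% c("A", "T"), at_threshold,
             "AT-rich", "upstream-of-coding"),
    hit_rows(1L, down %in% c("G", "C"), gc_threshold,
             "GC-rich", "downstream-of-coding"))
  if (is.null(out)) {
    out <- data.frame(kind = character(), boundary = character(),
                      start = integer(), end = integer(), length = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE)
  }
  out
}

seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1]]

# Positionwise identity of two equal-length character vectors.
block_identity <- function(u, v) mean(u == v)

majority_consensus <- function(units) {
  # units: list of equal-length character vectors
  u <- do.call(rbind, units)
  apply(u, 2, function(col) names(which.max(table(col))))
}

#' Find tandem repeats in a sequence
#'
#' Seed-free exhaustive search over candidate unit lengths: at every start
#' position the first unit is extended by consecutive units while each new
#' unit has identity at least `min_identity` to the running majority-rule
#' consensus. Overlapping candidates are resolved by score
#' (copies x unit length), ties by higher mean unit identity, then the
#' smaller start, then the smaller unit.
#'
#' @param seq Nucleotide sequence; must be at least `2 * unit_min` long.
#' @param unit_min,unit_max Candidate repeat-unit lengths, bp.
#' @param min_copies Minimum number of tandem copies (>= 2).
#' @param min_identity Minimum identity of each unit to the running consensus.
#' @return Data frame with one row per repeat: `start`, `end` (1-based,
#'   inclusive), `unit_len`, `copies`, `identity` (mean pairwise unit identity,
#'   percent) and `unit` (consensus).
#' @export
find_tandem_repeats <- function(seq, unit_min, unit_max, min_copies = 2L,
                                min_identity = 0.85) {
  if (unit_min < 1L || unit_min > unit_max) {
    stop("need 1 <= unit_min <= unit_max")
  }
  chars <- seq_chars(seq)
  n <- length(chars)
  if (n < 2L * unit_min) stop("sequence shorter than two minimal units")
  cands <- list()
  for (u in unit_min:min(unit_max, n %/% 2L)) {
    s <- 1L
    while (s <= n - 2L * u + 1L) {
      first <- chars[s:(s + u - 1L)]
      second <- chars[(s + u):(s + 2L * u - 1L)]
      if (block_identity(first, second) < min_identity) { s <- s + 1L; next }
      units <- list(first, second)
      consensus <- majority_consensus(units)
      repeat {
        nxt_start <- s + length(units) * u
        if (nxt_start + u - 1L > n) break
        nxt <- chars[nxt_start:(nxt_start + u - 1L)]
        if (block_identity(nxt, consensus) < min_identity) break
        units <- c(units, list(nxt))
        consensus <- majority_consensus(units)
      }
      if (length(units) >= min_copies) {
        pairs <- utils::combn(length(units), 2L)
        mean_id <- mean(vapply(seq_len(ncol(pairs)), function(k) {
          block_identity(units[[pairs[1, k]]], units[[pairs[2, k]]])
        }, 0))
        cands[[length(cands) + 1L]] <- data.frame(
          start = s, end = s + length(units) * u - 1L, unit_len = u,
          copies = length(units), identity = 100 * mean_id,
          unit = paste(consensus, collapse = ""), stringsAsFactors = FALSE)
      }
      s <- s + 1L
    }
  }
  empty <- data.frame(start = integer(), end = integer(), unit_len = integer(),
                      copies = integer(), identity = numeric(),
                      unit = character(), stringsAsFactors = FALSE)
  if (length(cands) == 0L) return(empty)
  cands <- do.call(rbind, cands)
  # overlap resolution: span score first, then unit identity (so the true
  # phase of an exact repeat beats shifted candidates of equal span), then
  # position and unit size
  cands <- cands[order(-(cands$copies * cands$unit_len), -cands$identity,
                       cands$start, cands$unit_len), , drop = FALSE]
  chosen <- empty
  for (i in seq_len(nrow(cands))) {
    c_i <- cands[i, ]
    if (nrow(chosen) == 0L ||
        all(c_i$end < chosen$start | c_i$start > chosen$end)) {
      chosen <- rbind(chosen, c_i)
    }
  }
  rownames(chosen) <- NULL
  chosen[order(chosen$start), , drop = FALSE]
}

#' Global percent identity of two sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, affine gaps) via
#' \pkg{Biostrings}; identity is the number of identical aligned columns
#' divided by the total number of alignment columns, gap columns included in
#' the denominator.
#'
#' @param a,b Non-empty nucleotide sequences.
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Gap penalties (positive costs).
#' @return Percent identity in `[0, 100]`.
#' @export
global_percent_identity <- function(a, b, match = 1, mismatch = -1,
                                    gap_open = 2, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("both sequences must be non-empty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(toupper(a), toupper(b), type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  p <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  s <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  100 * sum(p == s & p != "-") / length(p)
}

#' Extract conserved flanking motifs from a set of NCRs
#'
#' The NCR sections immediately flanking the coding region are highly
#' conserved across a genome's minichromosomes. Fixed-length windows adjacent
#' to each coding boundary (the first `flank_down` bp of each NCR, downstream
#' of the coding 3' end, and the last `flank_up` bp, upstream of the coding 5'
#' start) are stacked without gaps, a majority-rule consensus is computed, and
#' each sequence's identity to the consensus is reported.
#'
#' @param ncrs Named character vector of NCR sequences, all linearized from
#'   the coding 3' end to the coding 5' start.
#' @param flank_up,flank_down Flank lengths, bp; must not exceed the shortest
#'   NCR.
#' @return List with components `upstream` and `downstream`, each a list of
#'   `consensus` (string) and `identity` (named percent-identity vector).
#' @export
extract_conserved_flanks <- function(ncrs, flank_up = 74L, flank_down = 37L) {
  lens <- nchar(ncrs)
  if (length(ncrs) < 1L) stop("at least one NCR is required")
  if (max(flank_up, flank_down) > min(lens)) {
    stop("flank length exceeds the shortest NCR (", min(lens), " bp)")
  }
  one_side <- function(get_window) {
    stack <- lapply(ncrs, function(x) seq_chars(get_window(x)))
    consensus <- majority_consensus(stack)
    identity <- vapply(stack, function(u) 100 * block_identity(u, consensus), 0)
    list(consensus = paste(consensus, collapse = ""), identity = identity)
  }
  list(
    upstream = one_side(function(x) substring(x, nchar(x) - flank_up + 1L, nchar(x))),
    downstream = one_side(function(x) substring(x, 1L, flank_down)))
}
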