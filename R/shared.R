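# Run code with a private RNG state: seeds locally (if given) and restores
# the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Longest common substring of two sequences
#'
#' Exact longest common contiguous substring by dynamic programming.
#' Characters match only if identical, so IUPAC ambiguity codes match
#' themselves only. Ties are broken by the smallest start position in `a`,
#' then in `b`.
#'
#' @param a,b Non-empty nucleotide sequences (single strings).
#' @return List with `length`, `segment`, `pos_a`, `pos_b` (1-based starts).
#' @export
#' @examples
#' longest_common_substring("ACGTACGT", "TTACGTTT")$segment  # "TACGT"
longest_common_substring <- function(a, b) {
  if (!is.character(a) || !is.character(b) || length(a) != 1L || length(b) != 1L ||
      is.na(a) || is.na(b) || !nzchar(a) || !nzchar(b)) {
    stop("both sequences must be non-empty strings")
  }
  r <- .lcs_dp(a, b)
  list(length = r[1],
       segment = if (r[1] > 0) substring(a, r[2], r[2] + r[1] - 1L) else "",
       pos_a = if (r[1] > 0) r[2] else NA_integer_,
       pos_b = if (r[1] > 0) r[3] else NA_integer_)
}

shuffle_seq <- function(x) {
  paste(sample(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Permutation null for a longest-common-substring length
#'
#' Tests whether the longest identical segment shared by two sequences is
#' longer than expected by chance for sequences of their lengths and
#' nucleotide compositions. Each replicate independently shuffles both
#' sequences (preserving composition) and records the resulting LCS length;
#' the add-one Monte-Carlo p-value is
#' \eqn{p = (1 + \#\{null \ge observed\}) / (replicates + 1)}.
#'
#' @param a,b Non-empty nucleotide sequences.
#' @param replicates Number of shuffle replicates (>= 1; >= 99 recommended
#'   for a usable p-value resolution).
#' @param seed Optional integer seed; results are reproducible given a seed
#'   and the caller's RNG state is left untouched.
#' @return List of class `lcs_null`: `observed`, `p_value`, `null_mean`,
#'   `null_max`, `replicates`, `null_lengths`.
#' @export
simulate_lcs_null <- function(a, b, replicates = 999L, seed = NULL) {
  if (replicates < 1L) stop("replicates must be >= 1")
  obs <- longest_common_substring(a, b)$length
  null_lengths <- with_seed(seed, {
    vapply(seq_len(replicates), function(i) {
      .lcs_len(shuffle_seq(a), shuffle_seq(b))
    }, 0L)
  })
  p <- (1 + sum(null_lengths >= obs)) / (replicates + 1)
  structure(list(observed = obs, p_value = p,
                 null_mean = mean(null_lengths),
                 null_max = max(null_lengths),
                 replicates = as.integer(replicates),
                 null_lengths = null_lengths),
            class = "lcs_null")
}

#' @export
print.lcs_null <- function(x, ...) {
  cat("<lcs_null> observed LCS ", x$observed, " bp; null mean ",
      round(x$null_mean, 2), ", max ", x$null_max, " over ", x$replicates,
      " shuffles; p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}

#' Shared identical segments across all gene pairs
#'
#' For every unordered pair of gene sequences, finds the longest shared
#' identical segment and its permutation-null p-value, then flags pairs whose
#' Benjamini-Hochberg adjusted p-value is at most `alpha` (segments longer
#' than expected by chance, candidate traces of recombination between genes).
#' Per-pair null replicates are seeded deterministically from `seed` and the
#' pair's names, so the table is invariant to the input order of `seqs`.
#'
#' @param seqs Named character vector of gene sequences.
#' @param genes Optional subset of names to analyse.
#' @param alpha Significance level applied to adjusted p-values.
#' @param replicates Shuffle replicates per pair.
#' @param seed Integer seed for the permutation nulls.
#' @return Data frame of class `shared_segment_table`: one row per pair with
#'   `gene_a`, `gene_b`, `length`, `segment`, `pos_a`, `pos_b`, `null_mean`,
#'   `null_max`, `p_value`, `p_adjusted`, `flagged`.
#' @export
shared_segment_matrix <- function(seqs, genes = NULL, alpha = 0.05,
                                  replicates = 999L, seed = 1L) {
  if (!is.null(genes)) {
    missing <- setdiff(genes, names(seqs))
    if (length(missing)) {
      stop("no sequence for gene(s): ", paste(missing, collapse = ", "))
    }
    seqs <- seqs[genes]
  }
  nm <- sort(names(seqs))
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      length = integer(), segment = character(),
                      pos_a = integer(), pos_b = integer(),
                      null_mean = numeric(), null_max = integer(),
                      p_value = numeric(), p_adjusted = numeric(),
                      flagged = logical(), stringsAsFactors = FALSE)
  if (length(nm) < 2L) {
    return(structure(empty, class = c("shared_segment_table", "data.frame")))
  }
  pairs <- utils::combn(nm, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    ga <- pairs[1, k]; gb <- pairs[2, k]
    lcs <- longest_common_substring(seqs[[ga]], seqs[[gb]])
    null <- simulate_lcs_null(seqs[[ga]], seqs[[gb]], replicates = replicates,
                              seed = seed + k)
    data.frame(gene_a = ga, gene_b = gb, length = lcs$length,
               segment = lcs$segment, pos_a = lcs$pos_a, pos_b = lcs$pos_b,
               null_mean = null$null_mean, null_max = null$null_max,
               p_value = null$p_value, p_adjusted = NA_real_, flagged = NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$flagged <- out$p_adjusted <= alpha
  structure(out, class = c("shared_segment_table", "data.frame"),
            alpha = alpha, replicates = as.integer(replicates))
}

#' @export
print.shared_segment_table <- function(x, ...) {
  cat("<shared_segment_table> ", nrow(x), " gene pairs, ",
      sum(x$flagged), " flagged at alpha = ", attr(x, "alpha"),
      " (BH-adjusted, ", attr(x, "replicates"), " shuffles)\n", sep = "")
  print.data.frame(x)
  invisible(x)
}
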