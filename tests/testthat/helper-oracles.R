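# Shared helpers and independent brute-force oracles. The oracles deliberately
# use a different algorithmic route than the package implementation.

rdna <- function(n, at = 0.5) {
  p <- c(A = at / 2, T = at / 2, G = (1 - at) / 2, C = (1 - at) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Brute-force longest common substring: try every substring of `a` from the
# longest down and look for it verbatim in `b`.
lcs_brute <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  for (len in seq(min(na, nb), 1L)) {
    for (i in seq_len(na - len + 1L)) {
      if (grepl(substr(a, i, i + len - 1L), b, fixed = TRUE)) return(len)
    }
  }
  0L
}

# Brute-force two-clade ancestral rule: explicit double loop.
ancestral_brute <- function(mat, clade_map) {
  clade_map <- clade_map[!is.na(clade_map)]
  clade_map <- clade_map[intersect(rownames(mat), names(clade_map))]
  clades <- unique(clade_map)
  out <- character()
  for (ch in colnames(mat)) {
    ok <- TRUE
    for (cl in clades) {
      members <- names(clade_map)[clade_map == cl]
      if (!any(mat[members, ch])) { ok <- FALSE; break }
    }
    if (ok) out <- c(out, ch)
  }
  out
}

# Brute-force microhomology at a junction: longest chimera substring touching
# the junction that occurs in parent A aligned to segment A's breakpoint and
# in parent B aligned to segment B's breakpoint.
microhomology_brute <- function(chimera, seg_a, seg_b, parents) {
  j <- seg_a$chimera_end
  pa <- parents[[seg_a$parent]]; pb <- parents[[seg_b$parent]]
  best <- 0L
  for (s in seg_a$chimera_start:(j + 1L)) {
    for (e in j:seg_b$chimera_end) {
      if (e < s) next
      w <- substr(chimera, s, e)
      la <- j - s + 1L  # bases on the A side of the junction (may be 0)
      pa_start <- seg_a$parent_end - la + 1L
      pb_start <- seg_b$parent_start - la
      if (pa_start < 1L || pb_start < 1L) next
      if (pa_start + nchar(w) - 1L > nchar(pa)) next
      if (pb_start + nchar(w) - 1L > nchar(pb)) next
      in_a <- substr(pa, pa_start, pa_start + nchar(w) - 1L) == w
      in_b <- substr(pb, pb_start, pb_start + nchar(w) - 1L) == w
      if (in_a && in_b) best <- max(best, nchar(w))
    }
  }
  best
}

# Is `small` a contiguous ordered sub-run of `big`? (token-wise)
is_subrun <- function(small, big) {
  s <- strsplit(small, "-", fixed = TRUE)[[1]]
  b <- strsplit(big, "-", fixed = TRUE)[[1]]
  if (length(s) > length(b)) return(FALSE)
  any(vapply(seq_len(length(b) - length(s) + 1L), function(i) {
    all(b[i:(i + length(s) - 1L)] == s)
  }, NA))
}

# Build a one-taxon genome from arrangement strings (no sequences).
toy_genome <- function(taxon, arrangements, genus = NA, clade = NA) {
  minis <- lapply(seq_along(arrangements), function(i) {
    minichromosome(paste0("m", i), arrangements[[i]])
  })
  fragmented_genome(taxon, minis, genus = genus, clade = clade)
}

# Random presence/absence matrix for property tests.
random_matrix <- function(n_taxa, n_chars, p = 0.4) {
  m <- matrix(runif(n_taxa * n_chars) < p, n_taxa, n_chars,
              dimnames = list(paste0("t", seq_len(n_taxa)),
                              paste0("c", seq_len(n_chars))))
  m
}

akanezumi <- function() hoplopleura_genomes()[["Hoplopleura akanezumi"]]
kitti <- function() hoplopleura_genomes()[["Hoplopleura kitti"]]
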