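test_that("longest common substring matches examples and brute force", {
  x <- longest_common_substring("ACGTACGT", "TTACGTTT")
  expect_equal(x$length, 5L)
  expect_equal(x$segment, "TACGT")

  s <- "ATGCCGTAGGCTTAAG"
  expect_equal(longest_common_substring(s, s)$length, nchar(s))

  set.seed(501)
  for (rep in 1:40) {
    a <- rdna(sample(1:60, 1), at = 0.7)
    b <- rdna(sample(1:60, 1), at = 0.7)
    got <- longest_common_substring(a, b)
    expect_equal(got$length, lcs_brute(a, b))
    # reported segment really occurs at the reported positions
    if (got$length > 0) {
      expect_equal(substr(a, got$pos_a, got$pos_a + got$length - 1), got$segment)
      expect_equal(substr(b, got$pos_b, got$pos_b + got$length - 1), got$segment)
    }
    # symmetry of the length
    expect_equal(got$length, longest_common_substring(b, a)$length)
  }
  expect_error(longest_common_substring("", "ACGT"), "non-empty")
})

test_that("LCS ties break to the smallest start in a, then in b", {
  # "AA" occurs at a-positions 1 and 4; both match b
  got <- longest_common_substring("AACAA", "GGAAGG")
  expect_equal(got$pos_a, 1L)
  expect_equal(got$pos_b, 3L)
})

test_that("LCS is monotone under appending a common suffix", {
  set.seed(502)
  for (rep in 1:10) {
    a <- rdna(40); b <- rdna(40); sfx <- rdna(10)
    expect_gte(longest_common_substring(paste0(a, sfx), paste0(b, sfx))$length,
               longest_common_substring(a, b)$length)
  }
})

test_that("the permutation null is reproducible and exact for identical input", {
  a <- rdna(300)
  n1 <- simulate_lcs_null(a, a, replicates = 999, seed = 7)
  expect_equal(n1$p_value, 1 / 1000)
  n2 <- simulate_lcs_null(a, a, replicates = 999, seed = 7)
  expect_identical(n1$null_lengths, n2$null_lengths)
  expect_error(simulate_lcs_null(a, a, replicates = 0), "replicates")
})

test_that("planted shared segments are detected; independent pairs are not", {
  set.seed(503)
  flagged_planted <- logical(10)
  flagged_random <- logical(10)
  for (i in 1:10) {
    a <- rdna(500); b <- rdna(500)
    seg <- rdna(30)
    pa <- sample(470, 1); pb <- sample(470, 1)
    substring(a, pa, pa + 29) <- seg
    b2 <- b
    substring(b2, pb, pb + 29) <- seg
    p_planted <- simulate_lcs_null(a, b2, replicates = 999, seed = i)$p_value
    flagged_planted[i] <- p_planted <= 0.01
    p_rand <- simulate_lcs_null(rdna(500), rdna(500), replicates = 199,
                                seed = i)$p_value
    flagged_random[i] <- p_rand <= 0.05
  }
  expect_gte(mean(flagged_planted), 0.9)
  expect_gte(mean(!flagged_random), 0.9)
})

test_that("null p-values are valid (super-uniform) under the null", {
  set.seed(504)
  ps <- replicate(200, {
    simulate_lcs_null(rdna(60), rdna(60), replicates = 99)$p_value
  })
  # anti-conservative one-sided KS: empirical CDF must not exceed uniform
  d_minus <- max(seq_along(ps) / length(ps) - sort(ps))
  expect_lt(d_minus, 0.1)
})

test_that("the pair table flags exactly the planted pair and is order-invariant", {
  set.seed(505)
  seqs <- setNames(vapply(1:6, function(i) rdna(300), ""), paste0("g", 1:6))
  seg <- rdna(40)
  substring(seqs[["g2"]], 100, 139) <- seg
  substring(seqs[["g5"]], 200, 239) <- seg
  tab <- shared_segment_matrix(seqs, replicates = 999, seed = 42)
  expect_equal(nrow(tab), 15L)
  hit <- tab[tab$flagged, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$gene_a, hit$gene_b), c("g2", "g5"))
  expect_gte(hit$length, 40L)

  # permuting the input order leaves the table content unchanged
  tab2 <- shared_segment_matrix(seqs[sample(names(seqs))],
                                replicates = 999, seed = 42)
  expect_equal(as.data.frame(tab), as.data.frame(tab2))

  expect_equal(nrow(shared_segment_matrix(seqs[1])), 0L)
  expect_error(shared_segment_matrix(seqs, genes = c("g1", "nope")), "nope")
})
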