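test_that("planted boundary motifs are recovered as maximal dense segments", {
  set.seed(601)
  # uniform background; AT-rich motif at the upstream (NCR end) boundary,
  # GC-rich motif at the downstream (NCR start) boundary
  at_motif <- paste(sample(c(rep(c("A", "T"), 24), rep(c("G", "C"), 6))),
                    collapse = "")  # 60 bp, 80% AT
  gc_motif <- paste(sample(c(rep(c("G", "C"), 18), rep(c("A", "T"), 4))),
                    collapse = "")  # 44 bp, ~82% GC
  ncr <- paste0(gc_motif, rdna(300), at_motif)
  hits <- scan_composition_motifs(ncr)
  at_hits <- hits[hits$kind == "AT-rich", ]
  gc_hits <- hits[hits$kind == "GC-rich", ]
  planted_at <- c(nchar(ncr) - 60, nchar(ncr))  # 0-based half-open
  planted_gc <- c(0, 44)
  coverage <- function(h, span) {
    if (nrow(h) == 0) return(0)
    max(pmin(h$end, span[2]) - pmax(h$start, span[1])) / (span[2] - span[1])
  }
  expect_gte(coverage(at_hits, planted_at), 0.9)
  expect_gte(coverage(gc_hits, planted_gc), 0.9)
  expect_true(all(at_hits$boundary == "upstream-of-coding"))
  expect_true(all(gc_hits$boundary == "downstream-of-coding"))

  # reported fractions are recomputable from the reported spans
  for (i in seq_len(nrow(hits))) {
    span <- substr(ncr, hits$start[i] + 1, hits$end[i])
    base <- if (hits$kind[i] == "AT-rich") c("A", "T") else c("G", "C")
    frac <- mean(strsplit(span, "")[[1]] %in% base)
    expect_equal(frac, hits$fraction[i])
    expect_gte(frac, 0.75)
  }
})

test_that("degenerate and negative composition inputs behave as specified", {
  allA <- strrep("A", 300)
  hits <- scan_composition_motifs(allA, window = 150)
  at_hits <- hits[hits$kind == "AT-rich", ]
  expect_equal(nrow(at_hits), 1L)
  expect_equal(at_hits$length, 150L)  # spans the whole window
  expect_error(scan_composition_motifs("ACGT", at_threshold = 0.4), "threshold")
  expect_error(scan_composition_motifs("ACGT", gc_threshold = 1.2), "threshold")

  # uniform random sequence: hits are rare (measured no-hit rate 93%)
  set.seed(602)
  nohit <- replicate(60, nrow(scan_composition_motifs(rdna(400))) == 0)
  expect_gte(mean(nohit), 0.9)
})

test_that("tandem repeats are found exactly for exact copies", {
  unit <- "ACGTACGTAC"
  # flanking context chosen so it does not extend the periodic region
  seq <- paste0("TTGAG", strrep(unit, 3), "GGTTACGGC")
  hit <- find_tandem_repeats(seq, 8, 12)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$unit_len, 10L)
  expect_equal(hit$copies, 3L)
  expect_equal(hit$identity, 100)
  expect_equal(substr(seq, hit$start, hit$end), strrep(unit, 3))

  set.seed(603)
  for (rep in 1:5) {
    u <- sample(5:30, 1); k <- sample(2:5, 1)
    unit <- rdna(u)
    s <- paste0(rdna(40), strrep(unit, k), rdna(40))
    hit <- find_tandem_repeats(s, max(2, u - 3), u + 3)
    expect_gte(nrow(hit), 1L)
    best <- hit[which.max(hit$copies * hit$unit_len), ]
    expect_gte(best$copies * best$unit_len, k * u)
  }
  expect_error(find_tandem_repeats("ACGT", 0, 5), "unit_min")
  expect_error(find_tandem_repeats("ACGT", 6, 5), "unit_min")
  expect_error(find_tandem_repeats("ACGTAC", 5, 5), "shorter")
})

test_that("diverged planted repeats are recovered within one copy", {
  set.seed(604)
  unit <- rdna(72)
  mutate <- function(x, k) {
    ch <- strsplit(x, "")[[1]]
    at <- sample(length(ch), k)
    for (i in at) ch[i] <- sample(setdiff(c("A","C","G","T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  copies <- c(unit, vapply(1:3, function(i) mutate(unit, 4), ""))  # ~94% id
  ncr <- paste0(rdna(300, at = 0.7), paste(copies, collapse = ""),
                rdna(384, at = 0.7))
  hit <- find_tandem_repeats(ncr, 60, 80, min_copies = 2, min_identity = 0.85)
  expect_gte(nrow(hit), 1L)
  best <- hit[which.max(hit$copies * hit$unit_len), ]
  expect_equal(best$unit_len, 72L)
  expect_true(abs(best$copies - 4L) <= 1L)
  expect_gte(best$identity, 85)

  # random sequences essentially never contain long high-identity repeats
  set.seed(605)
  nohit <- replicate(20, {
    nrow(find_tandem_repeats(rdna(300), 20, 80, min_copies = 3,
                             min_identity = 0.9)) == 0
  })
  expect_gte(mean(nohit), 0.95)
})

test_that("global percent identity behaves like an alignment identity", {
  expect_equal(global_percent_identity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(global_percent_identity("AAAA", "TTTT"), 0)
  set.seed(606)
  a <- rdna(500)
  ch <- strsplit(a, "")[[1]]
  at <- sample(500, 50)  # 10% substitution load
  for (i in at) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  b <- paste(ch, collapse = "")
  id <- global_percent_identity(a, b)
  expect_gte(id, 85); expect_lte(id, 95)
  expect_equal(id, global_percent_identity(b, a))
  expect_lt(global_percent_identity(rdna(100), rdna(100)), 100)
  expect_error(global_percent_identity("", "ACGT"), "non-empty")
})

test_that("conserved flanks are recovered from stacked boundary windows", {
  set.seed(607)
  up <- rdna(74); down <- rdna(37)
  ncrs <- setNames(vapply(1:10, function(i) {
    paste0(down, rdna(sample(200:400, 1)), up)
  }, ""), paste0("n", 1:10))
  fl <- extract_conserved_flanks(ncrs, flank_up = 74, flank_down = 37)
  expect_equal(fl$upstream$consensus, up)
  expect_equal(fl$downstream$consensus, down)
  expect_true(all(fl$upstream$identity == 100))
  expect_true(all(fl$downstream$identity == 100))

  single <- extract_conserved_flanks(ncrs[1], flank_up = 74, flank_down = 37)
  expect_equal(single$upstream$consensus, up)

  # unrelated random NCRs: identity to the consensus is low
  rand <- setNames(vapply(1:8, function(i) rdna(300), ""), paste0("r", 1:8))
  fr <- extract_conserved_flanks(rand)
  expect_lt(mean(fr$upstream$identity), 60)

  expect_error(extract_conserved_flanks(c(x = "ACGT"), flank_up = 74), "exceeds")
})
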