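test_that("run extraction enumerates contiguous sub-runs within minichromosomes", {
  g <- toy_genome("x", "atp8-atp6-N")
  expect_setequal(extract_run_characters(g),
                  c("atp8-atp6", "atp6-N", "atp8-atp6-N"))
  expect_length(extract_run_characters(toy_genome("y", "nad2")), 0L)
  runs <- extract_run_characters(toy_genome("z", "E-cob-S1-S2"))
  expect_true(all(c("E-cob", "cob-S1") %in% runs))
  expect_error(extract_run_characters(g, min_len = 1), "min_len")
})

test_that("a minichromosome of L distinct genes yields L(L+1)/2 - L runs", {
  set.seed(401)
  for (rep in 1:5) {
    L <- sample(2:8, 1)
    genes <- sample(mt_gene_set(), L)
    g <- toy_genome("x", paste(genes, collapse = "-"))
    expect_length(extract_run_characters(g), L * (L + 1) / 2 - L)
  }
})

test_that("the character matrix matches the published presence pattern", {
  chars <- c("atp8-atp6-N", "E-cob", "cob-S1", "I-cox1", "D-Y-cox2",
             "R-nad4L-P-cox3", "cox3-A", "K-nad4", "M-L1-rrnL-V")
  m <- build_character_matrix(hoplopleura_genomes(), chars)
  expect_true(all(m["Hoplopleura kitti", ]))
  expect_equal(unname(m["Hoplopleura akanezumi", ]),
               c(rep(TRUE, 8), FALSE))  # lacks M-L1-rrnL-V
  m0 <- build_character_matrix(hoplopleura_genomes(), character())
  expect_equal(ncol(m0), 0L)
})

test_that("the two-clade rule recovers the nine published ancestral characters", {
  tab <- anoplura_character_table()
  anc <- infer_ancestral_characters(tab$matrix, tab$clade_map)
  expect_setequal(anc, c("atp8-atp6-N", "E-cob", "cob-S1", "I-cox1",
                         "D-Y-cox2", "R-nad4L-P-cox3", "cox3-A", "K-nad4",
                         "M-L1-rrnL-V"))
})

test_that("the two-clade rule equals a brute-force oracle and rejects bad clades", {
  set.seed(402)
  for (rep in 1:20) {
    n_taxa <- sample(2:8, 1)
    m <- random_matrix(n_taxa, sample(1:12, 1))
    clade_map <- setNames(sample(c("A", "B"), n_taxa, replace = TRUE),
                          rownames(m))
    if (length(unique(clade_map)) < 2) clade_map[1] <- setdiff(c("A", "B"), clade_map[-1])[1]
    expect_identical(infer_ancestral_characters(m, clade_map),
                     ancestral_brute(m, clade_map))
  }
  m <- random_matrix(3, 4)
  expect_error(infer_ancestral_characters(m, setNames(rep("A", 3), rownames(m))),
               "two clades")
  # a character private to one clade is never ancestral
  m2 <- matrix(c(TRUE, FALSE), 2, 1, dimnames = list(c("x", "y"), "atp8-atp6"))
  expect_length(infer_ancestral_characters(m2, c(x = "A", y = "B")), 0L)
})

test_that("maximal shared runs suppress contained runs with identical witnesses", {
  gA <- toy_genome("x", "atp8-atp6-N", clade = "A")
  gB <- toy_genome("y", "K-atp8-atp6-N", clade = "B")
  got <- find_maximal_shared_runs(list(gA, gB), c(x = "A", y = "B"))
  expect_identical(got, "atp8-atp6-N")

  # identical genomes in both clades: the full arrangement is the unique run
  g1 <- toy_genome("p", "E-cob-S1-S2"); g2 <- toy_genome("q", "E-cob-S1-S2")
  expect_identical(find_maximal_shared_runs(list(g1, g2), c(p = "A", q = "B")),
                   "E-cob-S1-S2")

  # every maximal run is ancestral, and a shorter run survives only when its
  # witness set differs from every longer ancestral run containing it
  set.seed(403)
  for (rep in 1:10) {
    mk <- function(nm, cl) {
      genes <- sample(mt_gene_set(c("tRNA")), sample(3:6, 1))
      toy_genome(nm, paste(genes, collapse = "-"), clade = cl)
    }
    gs <- list(mk("a", "A"), mk("b", "A"), mk("c", "B"), mk("d", "B"))
    cm <- c(a = "A", b = "A", c = "B", d = "B")
    maximal <- find_maximal_shared_runs(gs, cm)
    all_runs <- sort(unique(unlist(lapply(gs, extract_run_characters))))
    mat <- build_character_matrix(gs, all_runs)
    ancestral <- ancestral_brute(mat, cm)
    expect_true(all(maximal %in% ancestral))
    # oracle: independent containment + witness filter
    wit <- lapply(ancestral, function(ch) rownames(mat)[mat[, ch]])
    ntok <- lengths(strsplit(ancestral, "-", fixed = TRUE))
    keep <- ancestral[vapply(seq_along(ancestral), function(i) {
      !any(vapply(seq_along(ancestral), function(j) {
        i != j && ntok[j] > ntok[i] &&
          is_subrun(ancestral[i], ancestral[j]) &&
          setequal(wit[[i]], wit[[j]])
      }, NA))
    }, NA)]
    expect_setequal(maximal, keep)
  }
})

test_that("genus-specific minichromosomes match the published table", {
  t4 <- anoplura_genus_table()
  gsp <- find_genus_specific_minichromosomes(presence = t4$presence,
                                             genus_map = t4$genus_map)
  expect_setequal(gsp$Hoplopleura, c("E-cob-S1-S2", "C-nad6-W-L2", "rrnS"))
  expect_identical(gsp$Polyplax, "E-cob-I")
  expect_length(gsp$Haematopinus, 5L)
  expect_length(gsp$Pediculus, 9L)
  expect_length(gsp$Pthirus, 6L)
  # genus-specific sets are pairwise disjoint
  all_arr <- unlist(gsp, use.names = FALSE)
  expect_equal(anyDuplicated(all_arr), 0L)
})

test_that("single-genus input warns and reports arrangements shared by all members", {
  gs <- hoplopleura_genomes()
  expect_warning(res <- find_genus_specific_minichromosomes(gs), "one genus")
  expect_true("atp8-atp6-N" %in% res$Hoplopleura)
  expect_false("D-Y-cox2" %in% res$Hoplopleura)  # differs between the species
})
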