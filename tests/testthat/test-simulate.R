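test_that("simulation is deterministic and conserves the configured gene set", {
  cfg <- simulation_config(seed = 21)
  s1 <- simulate_fragmented_genome(cfg)
  s2 <- simulate_fragmented_genome(cfg)
  expect_identical(s1$gene_seqs, s2$gene_seqs)
  expect_identical(lapply(s1$genome$minichromosomes, `[[`, "sequence"),
                   lapply(s2$genome$minichromosomes, `[[`, "sequence"))
  expect_identical(s1$truth, s2$truth)

  occ <- do.call(rbind, lapply(s1$genome$minichromosomes, function(m) {
    if (m$chimeric) NULL else m$genes
  }))
  expect_equal(sort(occ$identity), sort(cfg$genes))  # each gene exactly once
  expect_equal(unique_gene_census(s1$genome)$n_unique, 37L)
})

test_that("a genome emulating the 34-gene / 11-minichromosome organisation", {
  genes34 <- setdiff(mt_gene_set(), c("F", "H", "nad5"))
  cfg <- simulation_config(seed = 22, genes = genes34, n_minichromosomes = 11)
  sim <- simulate_fragmented_genome(cfg)
  expect_length(sim$genome$minichromosomes, 11L)
  expect_equal(unique_gene_census(sim$genome)$n_unique, 34L)
  expect_setequal(missing_canonical_genes(sim$genome), c("F", "H", "nad5"))
  # every minichromosome is coding region + NCR with the planted flanks
  for (m in sim$genome$minichromosomes) {
    expect_equal(nchar(m$sequence), m$coding_len + m$ncr_len)
    ncr <- ncr_sequence(m)
    expect_equal(substr(ncr, nchar(ncr) - 73, nchar(ncr)),
                 sim$truth$planted$flank_up)
    expect_equal(substr(ncr, 1, 37), sim$truth$planted$flank_down)
  }
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simulation_config(genes = c("cox1", "cox2"),
                                 n_minichromosomes = 5), "too small")
  expect_error(simulation_config(genes = c("cox1", "cox1")), "duplicate")
  expect_error(simulation_config(at_motif = list(len = 900, frac = 0.8)),
               "exceed")
})

test_that("truth records round-trip through JSON", {
  cfg <- simulation_config(seed = 23)
  sim <- simulate_fragmented_genome(cfg)
  p <- withr::local_tempfile(fileext = ".json")
  write_truth(sim$truth, p)
  back <- read_truth(p)
  expect_equal(back$arrangements, sim$truth$arrangements)
  expect_length(back$arrangements, 11L)
  expect_equal(back$planted$flank_up, sim$truth$planted$flank_up)
  write_truth(list(), p)
  expect_length(read_truth(p), 0L)
})

test_that("taxon sets recover surviving ancestral runs under the two-clade rule", {
  cfg <- simulation_config(seed = 24, n_taxa_per_clade = 2, n_trna_moves = 2)
  ts <- simulate_taxon_set(cfg)
  expect_length(ts$genomes, 4L)
  expect_identical(simulate_taxon_set(cfg)$truth, ts$truth)  # deterministic

  mat <- build_character_matrix(ts$genomes, ts$truth$ancestral_runs)
  surviving <- infer_ancestral_characters(mat, ts$clade_map)
  all_runs <- sort(unique(unlist(lapply(ts$genomes, extract_run_characters))))
  inferred <- infer_ancestral_characters(
    build_character_matrix(ts$genomes, all_runs), ts$clade_map)
  # every surviving true ancestral run is recovered
  expect_gte(mean(surviving %in% inferred), 0.95)
  # construction check: every inferred run is genuinely present in at least
  # one taxon of each clade
  for (r in inferred) {
    for (cl in c("A", "B")) {
      members <- names(ts$clade_map)[ts$clade_map == cl]
      expect_true(any(vapply(members, function(t) {
        r %in% extract_run_characters(ts$genomes[[t]])
      }, NA)))
    }
  }
})

test_that("zero moves give identical taxa where every run is ancestral", {
  cfg <- simulation_config(seed = 25, n_taxa_per_clade = 1, n_trna_moves = 0)
  ts <- simulate_taxon_set(cfg)
  arrs <- lapply(ts$genomes, function(g) {
    vapply(g$minichromosomes, function(m) format_arrangement(m$genes), "")
  })
  expect_identical(arrs[[1]], arrs[[2]])
  inferred <- find_maximal_shared_runs(ts$genomes, ts$clade_map)
  expect_true(all(inferred %in% ts$truth$ancestral_runs))
  mat <- build_character_matrix(ts$genomes, ts$truth$ancestral_runs)
  expect_setequal(infer_ancestral_characters(mat, ts$clade_map),
                  ts$truth$ancestral_runs)
})

test_that("a genus-private move creates a detectable genus-specific arrangement", {
  cfg <- simulation_config(seed = 26, n_taxa_per_clade = 2, n_trna_moves = 1)
  ts <- simulate_taxon_set(cfg, genus_private_move = TRUE)
  gsp <- find_genus_specific_minichromosomes(ts$genomes)
  expect_true("GenusA" %in% names(gsp))
  expect_gte(length(gsp$GenusA), 1L)
  # the flagged arrangements are present in both GenusA members and absent
  # from all GenusB members
  a_members <- names(ts$genus_map)[ts$genus_map == "GenusA"]
  b_members <- names(ts$genus_map)[ts$genus_map == "GenusB"]
  full_arrs <- function(g) vapply(g$minichromosomes, function(m) {
    format_arrangement(m$genes, collapse_paralogs = TRUE)
  }, "")
  for (arr in gsp$GenusA) {
    expect_true(all(vapply(a_members, function(t) arr %in% full_arrs(ts$genomes[[t]]), NA)))
    expect_false(any(vapply(b_members, function(t) arr %in% full_arrs(ts$genomes[[t]]), NA)))
  }
})
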