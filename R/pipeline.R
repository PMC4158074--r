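#' Run the full minichromosome analysis pipeline
#'
#' Orchestrates the analysis stages in dependency order on a genome table:
#' per-taxon gene censuses, pairwise minichromosome comparison between taxa,
#' run-character extraction with two-clade ancestral inference and
#' genus-specific minichromosome detection, shared-segment testing on gene
#' sequences, and NCR characterisation on minichromosome sequences. Stage
#' results are written as TSVs plus one consolidated `summary.json`; all
#' stochastic stages derive from `seed`.
#'
#' @param genome_table Path to a genome table TSV (see [read_genome_table()]).
#' @param fasta Optional FASTA of minichromosome sequences (record names are
#'   matched against the table's `seq_id` column).
#' @param gene_fasta Optional FASTA of per-gene sequences for the
#'   shared-segment stage.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run, a subset of the default.
#' @param alpha,replicates,seed Parameters for the shared-segment stage and
#'   any other stochastic computation.
#' @return The summary list (invisibly), of class `minifrag_report`.
#' @export
run_pipeline <- function(genome_table, fasta = NULL, gene_fasta = NULL,
                         out_dir, stages = c("census", "compare", "characters",
                                             "shared", "ncr"),
                         alpha = 0.05, replicates = 999L, seed = 1L) {
  for (p in c(genome_table, fasta, gene_fasta)) {
    if (!is.null(p) && !file.exists(p)) stop("input not found: ", p)
  }
  stages <- match.arg(stages, several.ok = TRUE)
  genomes <- read_genome_table(genome_table)
  if (!is.null(fasta)) {
    seqs <- read_fasta(fasta)
    genomes <- lapply(genomes, attach_sequences, seqs = seqs)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(inputs = list(genome_table = genome_table, fasta = fasta,
                                gene_fasta = gene_fasta),
                  parameters = list(alpha = alpha, replicates = replicates,
                                    seed = seed),
                  taxa = names(genomes))
  write_tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  if ("census" %in% stages) {
    census_rows <- do.call(rbind, lapply(genomes, function(g) {
      cen <- unique_gene_census(g)
      tc <- trna_census(g)
      data.frame(taxon = g$taxon, n_unique = cen$n_unique,
                 n_occurrences = cen$n_occurrences,
                 n_minichromosomes = cen$n_minichromosomes,
                 n_missing = length(missing_canonical_genes(g)),
                 n_trna_unique = tc$n_unique,
                 n_trna_occurrences = tc$n_occurrences,
                 n_minis_with_trna = tc$n_minis_with_trna,
                 stringsAsFactors = FALSE)
    }))
    write_tsv(census_rows, "census.tsv")
    summary$census <- census_rows
  }

  if ("compare" %in% stages && length(genomes) >= 2L) {
    cmp <- list()
    combos <- utils::combn(names(genomes), 2L)
    for (k in seq_len(ncol(combos))) {
      a <- combos[1, k]; b <- combos[2, k]
      pairing <- pair_homologs(genomes[[a]], genomes[[b]])
      write_tsv(as.data.frame(pairing), paste0("pairing_", k, ".tsv"))
      cmp[[paste(a, b, sep = " vs ")]] <- list(
        n_identical = attr(pairing, "n_identical"),
        n_differing = attr(pairing, "n_differing"))
    }
    summary$compare <- cmp
  }

  if ("characters" %in% stages) {
    runs <- sort(unique(unlist(lapply(genomes, extract_run_characters))))
    mat <- build_character_matrix(genomes, runs)
    write_tsv(data.frame(taxon = rownames(mat),
                         ifelse(mat, "+", "-"), check.names = FALSE),
              "character_matrix.tsv")
    clade_map <- stats::setNames(vapply(genomes, `[[`, "", "clade"),
                                 names(genomes))
    summary$characters <- list(n_characters = length(runs))
    if (length(unique(stats::na.omit(clade_map))) == 2L) {
      anc <- find_maximal_shared_runs(genomes, clade_map)
      writeLines(anc, file.path(out_dir, "ancestral_characters.txt"))
      summary$characters$ancestral <- anc
    }
    genus_map <- stats::setNames(vapply(genomes, `[[`, "", "genus"),
                                 names(genomes))
    if (!anyNA(genus_map) && length(unique(genus_map)) >= 2L) {
      summary$characters$genus_specific <-
        find_genus_specific_minichromosomes(genomes, genus_map)
    }
  }

  if ("shared" %in% stages && !is.null(gene_fasta)) {
    gene_seqs <- read_fasta(gene_fasta)
    shared <- shared_segment_matrix(gene_seqs, alpha = alpha,
                                    replicates = replicates, seed = seed)
    write_tsv(as.data.frame(shared), "shared_segments.tsv")
    summary$shared <- list(n_pairs = nrow(shared),
                           flagged = shared[shared$flagged,
                                            c("gene_a", "gene_b", "length")])
  }

  if ("ncr" %in% stages) {
    ncr_rows <- list(); ncrs <- character()
    for (g in genomes) {
      for (m in g$minichromosomes) {
        if (is.null(m$sequence) || is.na(m$coding_len)) next
        ncr <- ncr_sequence(m)
        ncrs[[paste(g$taxon, m$id, sep = ":")]] <- ncr
        motifs <- scan_composition_motifs(ncr)
        if (nrow(motifs)) {
          ncr_rows[[length(ncr_rows) + 1L]] <-
            cbind(taxon = g$taxon, mini_id = m$id, motifs)
        }
        reps <- find_tandem_repeats(ncr, unit_min = 20L,
                                    unit_max = min(120L, nchar(ncr) %/% 2L),
                                    min_copies = 2L)
        if (nrow(reps)) {
          ncr_rows[[length(ncr_rows) + 1L]] <- cbind(
            taxon = g$taxon, mini_id = m$id, kind = "tandem-repeat",
            boundary = NA, start = reps$start - 1L, end = reps$end,
            length = reps$end - reps$start + 1L,
            fraction = reps$identity / 100)
        }
      }
    }
    if (length(ncr_rows)) {
      write_tsv(do.call(rbind, ncr_rows), "ncr_features.tsv")
      summary$ncr <- list(n_features = sum(vapply(ncr_rows, nrow, 0L)),
                          n_ncrs = length(ncrs))
    } else {
      summary$ncr <- list(n_features = 0L, n_ncrs = length(ncrs))
    }
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null")
  invisible(structure(summary, class = "minifrag_report"))
}

#' @export
print.minifrag_report <- function(x, ...) {
  cat("<minifrag_report> taxa: ", paste(x$taxa, collapse = ", "), "\n", sep = "")
  cat("  stages run: ",
      paste(intersect(c("census", "compare", "characters", "shared", "ncr"),
                      names(x)), collapse = ", "), "\n", sep = "")
  invisible(x)
}
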