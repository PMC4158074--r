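# Typical lengths (bp) used when simulating gene sequences. Protein and rRNA
# lengths are in the range seen in insect mt genomes; tRNAs are drawn from
# 60-72 bp at simulation time.
SIM_GENE_LEN <- c(atp6 = 670, atp8 = 160, cox1 = 1540, cox2 = 680, cox3 = 780,
                  cob = 1100, nad1 = 900, nad2 = 980, nad3 = 350, nad4 = 1270,
                  nad4L = 280, nad5 = 1700, nad6 = 480, rrnS = 700, rrnL = 1100)

random_dna <- function(n, at = 0.7) {
  if (n <= 0L) return("")
  p <- c(A = at / 2, T = at / 2, G = (1 - at) / 2, C = (1 - at) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Sequence of length n with an exact number of A/T bases (round(n * frac)),
# bases and positions randomized.
composition_motif <- function(n, frac, kind = c("AT", "GC")) {
  kind <- match.arg(kind)
  rich <- if (kind == "AT") c("A", "T") else c("G", "C")
  poor <- setdiff(c("A", "C", "G", "T"), rich)
  k <- round(n * frac)
  paste(sample(c(sample(rich, k, replace = TRUE),
                 sample(poor, n - k, replace = TRUE))), collapse = "")
}

mutate_seq <- function(x, rate) {
  chars <- seq_chars(x)
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Configuration for the fragmented-genome simulator
#'
#' Defaults emulate the minichromosomal organisation observed in louse
#' mitochondrial genomes: 11 minichromosomes carrying the 37-gene canon, one
#' coding region of roughly 0.7-1.65 kb and one NCR of 0.8-1.25 kb each, an
#' AT-rich base composition (70 percent), shared conserved flanks around the
#' coding region (74 bp upstream, 37 bp downstream), an AT-rich motif (60 bp,
#' 80 percent A+T) at the upstream boundary and a GC-rich motif (44 bp, 82
#' percent G+C) at the downstream boundary of every NCR.
#'
#' @param seed Integer root seed; all randomness derives from it.
#' @param genes Gene identities to place (default: the 37-gene canon).
#' @param n_minichromosomes Number of (non-chimeric) minichromosomes.
#' @param ncr_len_range NCR length range, bp.
#' @param base_at Background A+T fraction.
#' @param flank_up_len,flank_down_len Conserved flank lengths, bp.
#' @param at_motif,gc_motif Lists `list(len=, frac=)` for the boundary
#'   composition motifs; `NULL` to omit.
#' @param tandem_repeat Optional plant: `list(unit_len=, copies=, identity=,
#'   mini=)` (`mini` = index or id; defaults to the first minichromosome).
#' @param shared_segment Optional plant: `list(genes = c(a, b), len =)`, a
#'   segment copied verbatim into both genes.
#' @param chimera Optional plant: `list(parents = c(a, b), lens = c(la, lb),
#'   microhomology =)` building one chimeric minichromosome from slices of two
#'   parent genes, joined bluntly (`microhomology = 0`) or over a planted
#'   microhomology.
#' @param n_taxa_per_clade,n_trna_moves Taxon-set options for
#'   [simulate_taxon_set()]: taxa per clade, and tRNA translocations applied
#'   per taxon.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genes = mt_gene_set(),
                              n_minichromosomes = 11L,
                              ncr_len_range = c(800L, 1250L),
                              base_at = 0.7,
                              flank_up_len = 74L, flank_down_len = 37L,
                              at_motif = list(len = 60L, frac = 0.8),
                              gc_motif = list(len = 44L, frac = 0.82),
                              tandem_repeat = NULL,
                              shared_segment = NULL,
                              chimera = NULL,
                              n_taxa_per_clade = 2L,
                              n_trna_moves = 2L) {
  stopifnot(n_minichromosomes >= 1L, all(ncr_len_range > 0),
            base_at > 0, base_at < 1)
  genes <- vapply(genes, function(g) normalize_gene_token(g)$identity, "")
  if (anyDuplicated(genes)) stop("duplicate genes in the configured set")
  if (length(genes) < n_minichromosomes) {
    stop("gene set too small: ", length(genes), " genes cannot fill ",
         n_minichromosomes, " minichromosomes")
  }
  fixed <- flank_up_len + flank_down_len +
    (if (is.null(at_motif)) 0L else at_motif$len) +
    (if (is.null(gc_motif)) 0L else gc_motif$len)
  if (fixed > ncr_len_range[1]) {
    stop("planted NCR features (", fixed, " bp) exceed the minimum NCR length")
  }
  structure(list(seed = as.integer(seed), genes = unname(genes),
                 n_minichromosomes = as.integer(n_minichromosomes),
                 ncr_len_range = as.integer(ncr_len_range), base_at = base_at,
                 flank_up_len = as.integer(flank_up_len),
                 flank_down_len = as.integer(flank_down_len),
                 at_motif = at_motif, gc_motif = gc_motif,
                 tandem_repeat = tandem_repeat,
                 shared_segment = shared_segment, chimera = chimera,
                 n_taxa_per_clade = as.integer(n_taxa_per_clade),
                 n_trna_moves = as.integer(n_trna_moves)),
            class = "sim_config")
}

# Partition the configured genes over minichromosomes the way louse genomes
# are organised: protein/rRNA genes anchor the minichromosomes (one or two
# each), tRNAs are sprinkled across them at random positions.
partition_genes <- function(genes, n_minis) {
  anchors <- genes[gene_class(genes) %in% c("protein", "rRNA")]
  trnas <- setdiff(genes, anchors)
  groups <- rep(list(character()), n_minis)
  if (length(anchors) >= n_minis) {
    slot <- c(seq_len(n_minis),
              sample(n_minis, length(anchors) - n_minis, replace = TRUE))
  } else {
    slot <- seq_along(anchors)
  }
  slot <- sample(slot)
  for (i in seq_along(anchors)) {
    groups[[slot[i]]] <- c(groups[[slot[i]]], anchors[i])
  }
  empty <- which(lengths(groups) == 0L)
  if (length(empty) > length(trnas)) stop("not enough genes to fill every minichromosome")
  take <- seq_along(empty)
  for (k in take) groups[[empty[k]]] <- trnas[k]
  trnas <- trnas[setdiff(seq_along(trnas), take)]
  for (g in sample(trnas)) {
    i <- sample(n_minis, 1L)
    pos <- sample(length(groups[[i]]) + 1L, 1L)
    groups[[i]] <- append(groups[[i]], g, after = pos - 1L)
  }
  groups
}

sim_gene_sequence <- function(identity, at) {
  len <- if (identity %in% names(SIM_GENE_LEN)) {
    SIM_GENE_LEN[[identity]]
  } else {
    sample(60:72, 1L)
  }
  random_dna(len, at)
}

build_ncr <- function(cfg, target_len, repeat_plant = NULL) {
  flank_down <- cfg$.flank_down
  flank_up <- cfg$.flank_up
  gc <- if (is.null(cfg$gc_motif)) "" else
    composition_motif(cfg$gc_motif$len, cfg$gc_motif$frac, "GC")
  at <- if (is.null(cfg$at_motif)) "" else
    composition_motif(cfg$at_motif$len, cfg$at_motif$frac, "AT")
  rep_seq <- ""
  rep_truth <- NULL
  if (!is.null(repeat_plant)) {
    unit <- random_dna(repeat_plant$unit_len, 0.5)
    rate <- (1 - repeat_plant$identity) / 2
    copies <- vapply(seq_len(repeat_plant$copies), function(i) {
      if (i == 1L) unit else mutate_seq(unit, rate)
    }, "")
    rep_seq <- paste(copies, collapse = "")
    rep_truth <- list(unit_len = repeat_plant$unit_len,
                      copies = repeat_plant$copies)
  }
  fixed <- nchar(flank_down) + nchar(gc) + nchar(rep_seq) + nchar(at) +
    nchar(flank_up)
  mid_len <- max(0L, target_len - fixed)
  half <- mid_len %/% 2L
  ncr <- paste0(flank_down, gc, random_dna(half, cfg$base_at), rep_seq,
                random_dna(mid_len - half, cfg$base_at), at, flank_up)
  truth <- list(
    gc_motif = if (nchar(gc)) c(start = nchar(flank_down),
                                end = nchar(flank_down) + nchar(gc)),
    at_motif = if (nchar(at)) c(start = nchar(ncr) - nchar(flank_up) - nchar(at),
                                end = nchar(ncr) - nchar(flank_up)),
    tandem_repeat = if (!is.null(rep_truth)) c(rep_truth, list(
      start = nchar(flank_down) + nchar(gc) + half + 1L)))
  list(seq = ncr, truth = truth)
}

#' Simulate a fragmented mitochondrial genome with known planted truth
#'
#' Generates one taxon's genome under the supplied [simulation_config()]:
#' genes are partitioned across minichromosomes (each configured gene exactly
#' once), per-gene sequences are simulated, and each minichromosome gets an
#' NCR carrying the conserved flanks, the boundary composition motifs and any
#' configured tandem-repeat plant. Optional plants add a verbatim shared
#' segment between two genes and a chimeric minichromosome built from slices
#' of two parent genes. Deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List with `genome` (a [fragmented_genome()] with sequences),
#'   `gene_seqs` (named vector of simulated gene sequences) and `truth` (a
#'   list recording arrangements and all planted feature coordinates).
#' @export
simulate_fragmented_genome <- function(config) {
  with_seed(config$seed, simulate_fragmented_genome_impl(config, "sim_taxon"))
}

simulate_fragmented_genome_impl <- function(config, taxon,
                                            genus = "SimGenus",
                                            clade = "A",
                                            with_sequences = TRUE) {
  cfg <- config
  groups <- partition_genes(cfg$genes, cfg$n_minichromosomes)
  gene_seqs <- character()
  truth <- list(arrangements = list(), planted = list())

  if (with_sequences) {
    # conserved flanks are shared by all NCRs of the genome
    cfg$.flank_up <- random_dna(cfg$flank_up_len, cfg$base_at)
    cfg$.flank_down <- random_dna(cfg$flank_down_len, cfg$base_at)
    truth$planted$flank_up <- cfg$.flank_up
    truth$planted$flank_down <- cfg$.flank_down
    gene_seqs <- vapply(cfg$genes, sim_gene_sequence, "", at = cfg$base_at)
    if (!is.null(cfg$shared_segment)) {
      ss <- cfg$shared_segment
      seg <- random_dna(ss$len, 0.5)
      for (g in ss$genes) {
        at <- sample(nchar(gene_seqs[[g]]) - ss$len + 1L, 1L)
        substring(gene_seqs[[g]], at, at + ss$len - 1L) <- seg
        truth$planted$shared_segment[[g]] <- c(start = at, len = ss$len)
      }
      truth$planted$shared_segment$genes <- ss$genes
    }
  }

  # The chimera plant edits the parent gene sequences (microhomology bases and
  # forced boundary mismatches), so it must run before coding regions are
  # concatenated from gene_seqs.
  chim <- NULL
  if (with_sequences && !is.null(cfg$chimera)) {
    ch <- cfg$chimera
    pa <- gene_seqs[[ch$parents[1]]]; pb <- gene_seqs[[ch$parents[2]]]
    la <- as.integer(ch$lens[1]); lb <- as.integer(ch$lens[2])
    h <- if (is.null(ch$microhomology)) 0L else as.integer(ch$microhomology)
    a_start <- sample(nchar(pa) - la, 1L)
    b_start <- sample((h + 2L):(nchar(pb) - lb), 1L)
    if (h > 0L) {
      # plant the microhomology: parent B carries, right before its
      # breakpoint, the h bases that end parent A's slice
      m <- substring(pa, a_start + la - h, a_start + la - 1L)
      substring(pb, b_start - h, b_start - 1L) <- m
      pb <- enforce_mismatch(pb, b_start - h - 1L,
                             substring(pa, a_start + la - h - 1L,
                                       a_start + la - h - 1L))
    } else {
      pb <- enforce_mismatch(pb, b_start - 1L,
                             substring(pa, a_start + la - 1L, a_start + la - 1L))
    }
    # forbid extension of the A segment past the junction
    pa <- enforce_mismatch(pa, a_start + la, substring(pb, b_start, b_start))
    gene_seqs[[ch$parents[1]]] <- pa
    gene_seqs[[ch$parents[2]]] <- pb
    chim <- list(coding = paste0(substring(pa, a_start, a_start + la - 1L),
                                 substring(pb, b_start, b_start + lb - 1L)),
                 arr_str = paste0("p", ch$parents[1], "-p", ch$parents[2]),
                 truth = list(parents = ch$parents, junction = la,
                              parent_spans = list(
                                c(a_start, a_start + la - 1L),
                                c(b_start, b_start + lb - 1L)),
                              fractions = c(la / nchar(pa), lb / nchar(pb)),
                              microhomology = h))
  }

  rep_mini <- if (!is.null(cfg$tandem_repeat)) {
    if (is.null(cfg$tandem_repeat$mini)) 1L else cfg$tandem_repeat$mini
  }
  minis <- lapply(seq_along(groups), function(i) {
    ids <- groups[[i]]
    arr_str <- paste(ids, collapse = "-")
    mini_id <- paste0("m", sprintf("%02d", i))
    truth$arrangements[[mini_id]] <<- arr_str
    if (!with_sequences) {
      return(minichromosome(mini_id, arr_str))
    }
    coding <- paste(gene_seqs[ids], collapse = "")
    plant <- if (!is.null(rep_mini) && (identical(rep_mini, i) ||
                                        identical(rep_mini, mini_id))) {
      cfg$tandem_repeat
    }
    ncr <- build_ncr(cfg, sample(cfg$ncr_len_range[1]:cfg$ncr_len_range[2], 1L),
                     repeat_plant = plant)
    truth$planted$ncr[[mini_id]] <<- ncr$truth
    minichromosome(mini_id, arr_str, coding_len = nchar(coding),
                   ncr_len = nchar(ncr$seq),
                   sequence = paste0(coding, ncr$seq), seq_id = mini_id)
  })

  if (!is.null(chim)) {
    ncr <- build_ncr(cfg, sample(cfg$ncr_len_range[1]:cfg$ncr_len_range[2], 1L))
    minis[[length(minis) + 1L]] <- minichromosome(
      "chimera", chim$arr_str, coding_len = nchar(chim$coding),
      ncr_len = nchar(ncr$seq), sequence = paste0(chim$coding, ncr$seq),
      seq_id = "chimera")
    truth$arrangements[["chimera"]] <- chim$arr_str
    truth$planted$chimera <- chim$truth
  }

  genome <- fragmented_genome(taxon, minis, genus = genus, clade = clade)
  list(genome = genome, gene_seqs = gene_seqs, truth = truth)
}

# Force the base at position i of x to differ from `avoid` (no-op when i is
# outside x).
enforce_mismatch <- function(x, i, avoid) {
  if (i < 1L || i > nchar(x) || !nzchar(avoid)) return(x)
  if (substring(x, i, i) == avoid) {
    substring(x, i, i) <- sample(setdiff(c("A", "C", "G", "T"), avoid), 1L)
  }
  x
}

#' Simulate a two-clade taxon set from a common ancestral genome
#'
#' Generates an ancestral fragmented genome, then derives each taxon by
#' applying `n_trna_moves` tRNA translocations (a tRNA occurrence is removed
#' from one minichromosome and inserted at a uniformly chosen position in
#' another), the simplest move type consistent with the tRNA-limited
#' intra-genus variation observed in louse minichromosomes. Optionally, a
#' genus-private move shared by all members of one genus plants a detectable
#' synapomorphy.
#'
#' @param config A [simulation_config()]; `n_taxa_per_clade` and
#'   `n_trna_moves` control the taxon set.
#' @param genus_private_move If `TRUE`, all taxa of the first genus in clade A
#'   share one extra, identical tRNA translocation.
#' @return List with `genomes` (named list of [fragmented_genome()], two
#'   genera `GenusA`/`GenusB` in clades `A`/`B`), `clade_map`, `genus_map` and
#'   `truth` (ancestral arrangements, surviving ancestral run characters, and
#'   per-taxon applied moves).
#' @export
simulate_taxon_set <- function(config, genus_private_move = FALSE) {
  with_seed(config$seed, {
    if (config$n_taxa_per_clade < 1L) stop("need at least one taxon per clade")
    anc <- simulate_fragmented_genome_impl(config, "ancestor",
                                           with_sequences = FALSE)
    move_trna <- function(genome) {
      occ <- genome_occurrences(genome)
      trnas <- occ[occ$identity %in% MT_TRNA_GENES, , drop = FALSE]
      if (nrow(trnas) == 0L) stop("no tRNA available for a translocation move")
      pick <- trnas[sample(nrow(trnas), 1L), ]
      src <- genome$minichromosomes[[pick$mini]]
      if (nrow(src$genes) < 2L) return(list(genome = genome, move = NULL))
      row <- which(src$genes$identity == pick$identity)[1]
      gene_row <- src$genes[row, , drop = FALSE]
      src$genes <- src$genes[-row, , drop = FALSE]
      dest_id <- sample(setdiff(names(genome$minichromosomes), src$id), 1L)
      dest <- genome$minichromosomes[[dest_id]]
      at <- sample(nrow(dest$genes) + 1L, 1L)
      idx <- seq_len(nrow(dest$genes))
      dest$genes <- rbind(dest$genes[idx < at, , drop = FALSE], gene_row,
                          dest$genes[idx >= at, , drop = FALSE])
      genome$minichromosomes[[src$id]] <- src
      genome$minichromosomes[[dest_id]] <- dest
      list(genome = genome,
           move = list(gene = pick$identity, from = src$id, to = dest_id,
                       position = at))
    }
    clades <- c("A", "B")
    genomes <- list(); moves <- list()
    private_mover <- NULL
    for (cl in clades) {
      for (t in seq_len(config$n_taxa_per_clade)) {
        name <- paste0("taxon_", cl, t)
        g <- anc$genome
        g$taxon <- name
        g$clade <- cl
        g$genus <- paste0("Genus", cl)
        applied <- list()
        if (config$n_trna_moves > 0L) {
          for (k in seq_len(config$n_trna_moves)) {
            res <- move_trna(g)
            g <- res$genome
            if (!is.null(res$move)) applied[[length(applied) + 1L]] <- res$move
          }
        }
        genomes[[name]] <- g
        moves[[name]] <- applied
      }
    }
    if (genus_private_move) {
      # one identical extra move applied to every member of GenusA
      members <- names(genomes)[startsWith(names(genomes), "taxon_A")]
      res <- move_trna(genomes[[members[1]]])
      if (!is.null(res$move)) {
        for (m in members) {
          g <- genomes[[m]]
          occ <- genome_occurrences(g)
          hit <- occ[occ$identity == res$move$gene, , drop = FALSE]
          src <- g$minichromosomes[[hit$mini[1]]]
          row <- which(src$genes$identity == res$move$gene)[1]
          gene_row <- src$genes[row, , drop = FALSE]
          if (nrow(src$genes) < 2L) next
          src$genes <- src$genes[-row, , drop = FALSE]
          dest <- g$minichromosomes[[res$move$to]]
          if (identical(dest$id, src$id)) next
          at <- min(res$move$position, nrow(dest$genes) + 1L)
          idx <- seq_len(nrow(dest$genes))
          dest$genes <- rbind(dest$genes[idx < at, , drop = FALSE], gene_row,
                              dest$genes[idx >= at, , drop = FALSE])
          g$minichromosomes[[src$id]] <- src
          g$minichromosomes[[dest$id]] <- dest
          genomes[[m]] <- g
          moves[[m]] <- c(moves[[m]], list(c(res$move, private = TRUE)))
        }
      }
    }
    clade_map <- stats::setNames(vapply(genomes, `[[`, "", "clade"),
                                 names(genomes))
    genus_map <- stats::setNames(vapply(genomes, `[[`, "", "genus"),
                                 names(genomes))
    ancestral_runs <- extract_run_characters(anc$genome)
    truth <- list(ancestral_arrangements = anc$truth$arrangements,
                  ancestral_runs = ancestral_runs,
                  moves = moves)
    list(genomes = genomes, clade_map = clade_map, genus_map = genus_map,
         truth = truth)
  })
}

#' Write a simulation truth record to JSON
#'
#' @param truth Truth list from the simulators.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a truth record written by [write_truth()]
#'
#' @param path Path to the JSON file.
#' @return The truth list.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                      simplifyMatrix = FALSE)
}
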