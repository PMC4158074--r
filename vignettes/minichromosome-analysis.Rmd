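---
title: "Comparative analysis of fragmented mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of fragmented mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minifrag)
```

## The biological setting

Most bilaterian animals carry their 37 mitochondrial genes (13 protein-coding,
2 rRNA, 22 tRNA) on a single circular chromosome. Blood-sucking lice
(Anoplura) are a striking exception: their mitochondrial genome is fragmented
into many **minichromosomes**, each a small circle of roughly 1.5-4 kb
carrying between one and a handful of genes plus a non-coding region (NCR).
The NCRs of one genome are highly similar to each other, while each coding
region is distinct; gene content and gene order on the minichromosomes vary
between species, even within a genus.

`minifrag` implements the comparative analyses this organisation invites:

* gene accounting (which of the 37 canonical genes are present, where);
* minichromosome-level comparison between taxa;
* gene-order characters and a two-clade rule for inferring ancestral
  arrangements;
* genus-specific minichromosomes as candidate synapomorphies;
* a permutation test for identical sequence segments shared between genes
  (a trace of recombination);
* NCR characterisation: AT-rich/GC-rich boundary motifs, tandem repeats,
  conserved flanks, alignment identity;
* dissection of chimeric minichromosomes (partial genes from two parents,
  junction microhomology);
* a synthetic-data generator that plants every one of these features at known
  coordinates, so each stage can be validated against ground truth.

## Representation and conventions

A minichromosome is circular; the package linearizes it at the NCR/coding
boundary. Position 0 is the first base of the coding region, the NCR follows
the coding region, and coordinates are 0-based, half-open. Gene order is read
5'-to-3' in the majority transcription orientation, anchored at the NCR.
Arrangements are written as hyphen-joined tokens (`atp8-atp6-N`); a `~`
prefix marks the rare genes transcribed in the opposite orientation
(`~Q-~nad1-G-nad3`). The published material prints gene orders with hyphens
but has no orientation mark; `~` was chosen because it cannot be confused
with the separator.

Tokens are matched case-insensitively against the closed 37-gene vocabulary.
tRNAs use single-letter abbreviations, with serine and leucine isoacceptors
split by anticodon class (S1: tct, S2: tga, L1: tag, L2: taa). Copy-number
suffixes on tRNAs (`Y1`, `Y2`) are paralog labels: they are kept on the
occurrence but collapse to one identity for censuses and character
comparison, which is what makes a genome carrying `trnY1` and `trnY2` count
28 unique genes rather than 29. A `p` prefix marks a partial gene (`prrnS`),
and any minichromosome containing partial genes is treated as chimeric:
chimeras are excluded from censuses, pairing and character extraction, since
their gene fragments are copies of genes counted elsewhere.

## Minichromosome comparison

`pair_homologs()` pairs minichromosomes across two taxa by their *anchor*,
the set of protein-coding and rRNA genes they carry. Anchors ignore tRNA
content and order, so a `D-Y-cox2` minichromosome pairs with `D-Y-cox2-T`;
the pair is then compared position-by-position (identity and orientation,
paralogs collapsed) to decide whether the two arrangements are identical.
"Differing" minichromosomes are counted on the second (reference) genome's
side: non-identical pairs plus reference minichromosomes with no anchor
match. On the bundled *Hoplopleura* fixtures this reproduces the published
seven identical and four differing minichromosomes, the latter including the
`~Q-~nad1-G-nad3` minichromosome absent from *Ho. akanezumi*.

## Gene-run characters and the two-clade rule

A **run character** is a contiguous, ordered, orientation-sensitive run of at
least two genes on one minichromosome. Runs never span the NCR, because the
NCR breaks gene adjacency on the circle, and reverse readings are not
matched: the published comparisons are between like-oriented, NCR-anchored
arrangements. `extract_run_characters()` enumerates all such runs; a
minichromosome of `L` distinct genes yields `L(L+1)/2 - L` of them.

For a group known to have diversified into two major clades, a character
present in at least one species of each clade is most parsimoniously
inherited from the most recent common ancestor.
`infer_ancestral_characters()` applies exactly this rule to a
presence/absence matrix; taxa without a clade assignment (outgroups) are
ignored. External taxa whose arrangements are only available as published
presence/absence rows can be supplied as precomputed matrix rows, which keeps
the inference testable without third-party sequence data.
`find_maximal_shared_runs()` additionally removes a run contained in a longer
ancestral run *witnessed by exactly the same taxa*, since such a sub-run
carries no additional signal; a sub-run seen in more taxa than its container
is kept.

`find_genus_specific_minichromosomes()` flags full arrangements present in
every sampled member of exactly one genus and absent from all other taxa —
the strict reading of a candidate synapomorphy. Requiring all members (not
any) follows the published presence pattern, where every genus column is
marked for every member of the genus.

## Shared segments and the permutation null

The longest identical segment shared by two genes (`longest_common_substring`,
exact dynamic programming, ambiguity codes match only themselves) is compared
against a Monte-Carlo null: both sequences are independently shuffled,
preserving length and nucleotide composition, and the LCS is recomputed
(`simulate_lcs_null`). The add-one p-value `(1 + #{null >= obs}) /
(replicates + 1)` is used. The null is deliberately assumption-light: the
source material asserts "longer than expected by chance" without a formula,
and a composition-preserving shuffle is the weakest exchangeability
assumption under which that phrase is well-defined. Across many gene pairs
(`shared_segment_matrix`) p-values are Benjamini-Hochberg adjusted at
`alpha = 0.05` by default; raw p-values are also reported.

One numerical caveat is worth stating: the LCS of shuffled sequences is a
small integer concentrated on a few values, so these p-values are *valid*
(conservative; `P(p <= t) <= t`) but necessarily far from uniformly
distributed. The test suite asserts validity (the anti-conservative one-sided
Kolmogorov-Smirnov statistic stays below 0.1) rather than two-sided
uniformity, which no discrete statistic can achieve.

## NCR characterisation

`scan_composition_motifs()` looks for the AT-rich motif upstream of the
coding 5' end and the GC-rich motif downstream of the coding 3' end, within a
200 bp window adjacent to each boundary (the published motifs sit against the
coding boundaries; the exact search window is not stated, and 200 bp
comfortably covers all reported motif/flank sizes). A hit is a maximal
segment of at least `min_len` bp (default 40) whose AT or GC fraction meets
the threshold (default 0.75): no extension of the segment keeps the fraction
at the threshold, and no reported hit is contained in another. Reported
fractions are recomputable from the reported spans. On an AT-rich background
(louse mitochondrial DNA is roughly 70% A+T) an AT threshold close to the
background produces merged hits; scanning for a planted 80%-AT motif is done
at `at_threshold = 0.8`.

`find_tandem_repeats()` is a seed-free exhaustive scanner: for every unit
length and start, consecutive units are accepted while each has at least
`min_identity` (default 0.85) identity to the running majority-rule
consensus. NCRs are short (about a kilobase), so the quadratic scan is
affordable and avoids re-implementing heuristic external repeat finders.
Overlapping candidates are resolved by span score (copies x unit), then by
higher mean unit identity — so the true phase of an exact repeat beats
shifted candidates of equal span — then by smaller start.

`global_percent_identity()` delegates Needleman-Wunsch alignment to
Biostrings (match +1, mismatch -1, gap open 2, gap extend 0.5) and defines
identity as identical columns over *all* alignment columns, gaps included —
stated explicitly because "percent identity" is ambiguous.
`extract_conserved_flanks()` stacks fixed-length boundary windows without
gaps and reports a majority-rule consensus (ties broken alphabetically) plus
per-sequence identity to it; the published flanks are highly conserved, so a
gap-free stack is adequate and keeps the consensus well-defined.

## Chimeric minichromosomes

`map_partial_genes()` assigns chimera segments to parent genes greedily,
longest exact match first (a >= 98%-identity local-alignment mode exists for
diverged copies); fractions are segment length over parent length.
`detect_junction_microhomology()` measures the breakpoint-ambiguity window at
a junction: how far the chimera sequence immediately left of the junction
also occurs in parent B just before its breakpoint, plus how far the sequence
right of the junction continues parent A past its breakpoint. The
microhomology length is that sum — the length over which the true breakpoint
position is ambiguous, the operational signature of microhomology-mediated
joining. Lengths below `k_min = 3` are reported as none; the source material
calls microhomology "short" without a bound, and 3 bp is the smallest length
that is unlikely to span a junction by chance (probability about `2/4^3` per
junction). A blunt junction between unrelated parents therefore reports 0,
matching the published negative result.

## The synthetic-data generator

`simulation_config()` defaults encode the observed organisation: 11
minichromosomes, the 37-gene canon, NCRs of 0.8-1.25 kb, 70% A+T background
(typical of louse mitochondrial sequence), shared 74 bp upstream and 37 bp
downstream flanks, a 60 bp/80% AT-rich and a 44 bp/82% GC-rich boundary
motif in every NCR. Gene lengths use typical insect mitochondrial values
(e.g. rRNA genes of 700 and 1100 bp), so planted chimera slices of 172 and
51 bp reproduce the published partial-gene fractions of about 24% and 5%.
Optional plants add a tandem repeat (unit, copies, target unit identity), a
verbatim shared segment between two genes, and a chimeric minichromosome
with a configurable junction microhomology (planted so the ambiguity window
is exactly the requested length, with forced mismatches at both ends).

`simulate_taxon_set()` generates an ancestral genome and derives taxa in two
clades by tRNA translocations — remove a tRNA occurrence, insert it at a
uniform position on another minichromosome — the simplest move consistent
with the observed tRNA-limited intra-genus variation. This move model is a
testing device, not a biological claim: no rearrangement mechanism or rate is
published. All randomness flows from a single root seed through R's RNG, so
identical configurations give byte-identical genomes and truth records.

What the simulator does *not* emulate: realistic substitution processes (no
rate heterogeneity, no transition/transversion bias), gene-boundary features
(start/stop codons, tRNA structure), copy-number differences between
minichromosomes, or sequencing error. Passing the planted-truth suite
therefore shows the detectors are correct on clean signal at realistic sizes
and compositions, not that they are robust to annotation error or assembly
artefacts in real data.

## Numerical choices and degenerate inputs

* Empty arrangements, empty sequences, unknown gene tokens, duplicate
  minichromosome ids, clades with no taxa, flanks longer than the shortest
  NCR, and chimera analyses where no segment meets `min_anchor` all raise
  errors naming the offending input.
* LCS ties are broken toward the smallest start in the first sequence, then
  the second, making results deterministic.
* `shared_segment_matrix` seeds each pair's null from the root seed and the
  pair's position in the *sorted* pair list, so the table is invariant to
  input order.
* Composition thresholds must lie in (0.5, 1]; a threshold at or below 0.5
  would make "rich" meaningless.
* The single-genus case of genus-specific detection warns and reports
  arrangements shared by all members, rather than failing.

## Problem sizes used by the test suite

The packaged tests and the acceptance script run on the bundled published
arrangement fixtures (22 minichromosome records, 17-taxon character matrix,
10-taxon genus table) and on simulated genomes of the default size (11
minichromosomes, 37 genes, NCRs up to 1.25 kb). Permutation tests use
999 replicates on 500 bp sequences for planted-segment detection and 99-199
replicates for calibration sweeps; LCS brute-force cross-checks use random
pairs up to 60 bp. These sizes were chosen so every statistical property is
exercised at the scale of real minichromosomes while the whole suite stays
fast enough to run routinely.

## A worked example

```{r example, eval = FALSE}
library(minifrag)
gs <- hoplopleura_genomes()
unique_gene_census(gs[["Hoplopleura akanezumi"]])
#> <gene_census> Hoplopleura akanezumi: 28 unique genes (29 occurrences) on
#>   10 minichromosomes
#>   by class: protein=10, rRNA=2, tRNA=16

pair_homologs(gs[[1]], gs[[2]])
#> <homolog_pairing> Hoplopleura akanezumi vs Hoplopleura kitti:
#>   7 identical, 4 differing (Hoplopleura kitti side)

tab <- anoplura_character_table()
infer_ancestral_characters(tab$matrix, tab$clade_map)
#> [1] "atp8-atp6-N" "E-cob" "cob-S1" "I-cox1" "D-Y-cox2"
#> [6] "R-nad4L-P-cox3" "cox3-A" "K-nad4" "M-L1-rrnL-V"
```

## Known limitations

* Gene identification itself (annotation of raw sequence) is out of scope;
  the package starts from arrangement tables and annotated sequences.
* The two-clade rule is the published presence criterion, not a parsimony or
  likelihood reconstruction on a tree.
* Published sequence-dependent values (alignment identities, exact motif
  lengths of the deposited sequences) can only be recomputed when the user
  supplies those sequences; the synthetic suite validates the machinery on
  planted analogues instead.
* Breakpoint/rearrangement distances between arrangements are not
  implemented.
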