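---
title: "pirnaterm: generative model and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pirnaterm: generative model and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the generative model behind `syn_config()` /
`make_genome()` and the exact procedure implemented by each analysis stage,
including the numerical conventions and the reasoning behind the parameter
defaults. It is a methods reference, not a tutorial; see the README for a
worked example.

## Coordinate and labelling conventions

* All internal coordinates are **0-based, half-open** `[start, end)`.
  Writers emit each format's own convention (GFF3 1-based closed, BED
  0-based half-open) and readers convert back, so every reader/writer pair
  round-trips.
* The strand-aware 5′ end of an interval is defined once, in
  `five_prime_end()`: `start` on `+`, `end - 1` on `-`. Every module uses
  this rule.
* A multi-mapping read is represented as one row per placement, each row
  carrying the total `multiplicity`, so fractional counting can weight each
  placement by `1/multiplicity`.
* Randomness is controlled by a single master seed. Each generator derives
  a stage seed from the master seed and a stage tag (kept below 2^31), so
  stages are independently reproducible and the whole pipeline is
  byte-deterministic under one configuration.

## The generative model

`make_genome()` draws a uniform-random genome (default two 400-kb
chromosomes) and places, without overlap:

* **Gene models** — 200 genes of 1–3 exons (150–500 bp, introns 80–200 bp),
  random strand, with free-form labels (`germline`/`soma`,
  `piRNA_target`, `HRDE1_target`, `CSR1_target`).
* **piRNA loci** — `n_pirna_loci` motif-dependent loci per cluster inside
  `n_clusters` contiguous cluster regions on the last chromosome (the
  two-cluster organisation of the 21U system), plus scattered
  motif-independent loci so that motif-dependent loci make up
  `frac_motif_dependent` (default 80%) of the total. Each locus stores its
  5′U position; the genome base there is forced to `T` on the locus strand
  so mature reads genuinely start with uracil.
* **TE copies** — 40 copies in 5 families, a quarter of them inside exons
  ≥300 bp (so TE upregulation calls can be confounded by host genes). Half
  of all copies (`te_target_frac`) receive one planted antisense piRNA
  target site carrying 0–3 random substitutions, oriented on the TE's own
  strand, so the mismatch-tolerant scan has true sites at every mismatch
  level.
* **Ground truth** — per-gene expression means (log-normal), 22G rates
  (log-normal, correlated with expression), a silenced piRNA-target set
  (5% of genes: top length-normalized 22G density, bottom-decile wild-type
  expression, 6× desilencing in the mutant), a Pol II class
  (I/II/III with probabilities 0.25/0.5/0.25) and a wild-type Pol II level.

Read generators consume this ground truth:

* `make_small_rnas()` emits mature 21U reads (Poisson per locus, depleted
  to `pirna_depletion_mut` = 0.15 in the mutant), antisense 22G reads
  placed only at exonic positions whose antisense first base is G
  (abundance at silenced targets ×`depletion_factor_mut` = 0.2 in the
  mutant), background reads of other lengths, and multimapper decoys
  (multiplicity 2 or 4, placed off-exon, inheriting the source read's
  sequence). A ground-truth sidecar maps read id → origin and class.
* `make_capped_reads()` places 5′ ends `tss_offset_upstream` = 2 nt
  upstream of each 5′U (10% jittered by ±1–3 nt with geometrically decaying
  mass) and draws lengths from a two-component discretized normal mixture —
  modes 26/45 nt (wild type) or 28/47 nt (mutant), sd 1.5 nt, truncated at
  16 nt.
* `make_cleavage_fragments()` draws 5′-monophosphate fragment 5′ ends from
  `N(TSS + 38, 2)` in the transcription direction of each motif-dependent
  locus (TSS ≡ 5′U − 2) with lengths `N(20, 1)`, scaled to 20% abundance in
  the mutant (termination-defective animals make fewer cleavage products).
* `make_expression_tables()` draws negative-binomial counts
  (size 25, 4 replicates) and produces a DE table (Welch t on
  log2(count+1), BH adjustment).
* `make_chip_tracks()` tiles gene bodies with 25-bp windows around the
  gene's wild-type level (noise sd 0.05); the mutant multiplies the level
  by 1.8 / 1.0 / 0.5 for true classes I / II / III.
* `make_images()` builds disk-mask nuclei with Gaussian mCherry foci
  (σ = 2 px, ≥6σ apart) and a flat GFP baseline multiplied by
  `foci_enrichment` = 2 over a 3σ disk at each focus when colocalized,
  with optional Poisson shot noise.

### Why the mixture weights are 0.6/0.4

With exactly equal component masses the median of a bimodal mixture sits in
the inter-mode trough, where it is not identifiable from finite samples:
the genotype median shift would flip sign run to run. Weighting the lower
component 0.6 places the distribution median stably on its shoulder, so the
simulation reproduces both printed observations at once — the two length
peaks *and* a positive ~2-nt median shift in the mutant. This is a
structural choice, made before any tuning against outcomes.

## Analysis stages

**Small-RNA classification** (`classify_reads`) is a pure function of read
length and 5′ base on the read's own strand: 21 nt + 5′U → `piRNA_21U`;
22 nt + 5′G → `siRNA_22G`; anything else → `other`. Sequence-less reads
take the base from the genome at the strand-aware 5′ end (complemented on
`-`).

**Fractional antisense counting** (`count_antisense`) mirrors fractional
multimapper counting with reverse-stranded exon-level assignment: each
placement overlapping ≥1 bp of exon on the strand opposite the gene adds
`1/multiplicity` to that gene, once per (placement, gene) pair; sense
placements add nothing. A brute-force triple loop over reads × genes ×
exons serves as the test oracle.

**Normalization** (`normalize_counts`): TPM divides by exonic length in kb
and closes each sample to 1e6; RPM closes raw counts to 1e6. The
pseudo-count option adds 1 to the *normalized* value (the convention used
before log transformation), never to raw counts — so TPM columns sum to
1e6 exactly and log2(TPM+1) is well defined at zero.

**Equal-occupancy binning** (`assign_bins`) sorts by density with
lexicographic id tie-breaks and cuts into blocks of `floor(N/B)` or
`ceil(N/B)`, the larger blocks going to the lowest bins, so occupancies
never differ by more than one (e.g. 17,140 features → 20 bins of 857).
Per-bin expression summaries use a pooled-variance two-sample t-test by
default — the plain "two-sample t-test" — with Welch available via
`var_equal = FALSE`; bin medians are computed on `log2(TPM + 1)`.

**Target scan** (`scan_targets`) slides the reverse complement of each
21-nt piRNA along target sequences and reports every window with Hamming
distance ≤ `k_max`; non-ACGT bases always count as mismatches. The naive
O(n·m) scan *is* the reference implementation — inputs are desk-scale —
and `cumulative_match_table` counts distinct piRNAs per family at their
minimal mismatch level, cumulatively for k = 0..3.

**Precursor lengths** (`extract_precursors`, `estimate_peaks`): capped
reads are assigned to the nearest strand-matched 5′U within 25 nt (ties to
the lower coordinate). The bootstrap peak estimator subsamples without
replacement (2,000 × 5,000 at production scale), builds a 1-nt histogram,
smooths with a centred 3-bin moving average (partial windows at the edges),
takes local maxima, and keeps the two highest maxima separated by ≥8 nt
(ties toward the smaller length; unimodal subsamples report `NA` for the
upper peak). Medians over subsamples give the reported peak positions. The
8-nt separation floor prevents shoulder bins of one mode from masquerading
as the second mode; 3-bin smoothing suppresses single-bin noise without
displacing a 1-nt-resolution mode.

**Profiles**: `offset_profile` sums strand-matched 5′-end counts at signed
offsets around each motif-dependent 5′U (negative = upstream in the
transcription direction regardless of genomic strand).
`cleavage_profile` uses uniquely mapped monoP reads, removes >15-nt reads
initiating exactly at a 5′U (mature piRNA contaminants, not cleavage
products), histograms the rest relative to each TSS (5′U − 2), and
normalizes to reads per million *mapped* (not retained) reads.

**Pol II classes** (`gene_body_enrichment`, `assign_classes`): per-base
arithmetic mean of the log2 fold-enrichment track over the full gene span
(introns included; any uncovered base → `NA`, reported). Class I if
mutant mean ≥ 1.5× wild-type mean, class III if ≤ wild-type/1.5, class II
otherwise; the ratio is applied directly to the log2-scale means, and
genes with non-positive or missing wild-type means are flagged
unclassifiable rather than silently classified. Within-class genotype
comparisons use the two-sided Mann–Whitney U test.

**DE and overlap** (`call_deg`, `overlap_stats`): up/down calls use strict
|log2FC| > 1 and adjusted P < 0.01 thresholds. Percentage shares in
`deg_summary` are truncated (not rounded) to two decimals, so the two
shares never jointly exceed 100 (e.g. 292 of 1,556 → 18.76%, 1,264 of
1,556 → 81.23%). Overlap significance is the exact hypergeometric upper
tail P(X ≥ k); the representation factor is k/(n1·n2/N). Upregulated TEs
overlapping ≥1 bp of exon of an upregulated gene are filtered as
host-gene-driven calls (intron-only overlap does not filter).

**Imaging** (`otsu_threshold`, `segment_foci`, `coloc_ratio`): Otsu's
threshold is found by exhaustive search over 256 histogram-bin boundaries
of the in-mask intensities, maximizing between-class variance with ties
toward the lower boundary. Note that when the inter-mode trough is empty
the objective is flat across it — any plateau threshold binarizes
identically; this implementation returns the plateau's lower edge. Foci
are 8-connected components above threshold with area ≥ 4 px (a diagonal
pixel belongs to its blob; 4 px rejects single-pixel noise at σ = 2
spots). The colocalization ratio divides the mean measured-channel
intensity over all foci pixels by the mean over ≥10 random disk ROIs of
matching mean area placed inside the mask but outside the foci (no
additional guard zone around foci). Genotypes are compared with Welch's
t-test on per-nucleus ratios.

## Problem sizes and defaults

The default configuration (2 × 400 kb, 200 genes, 125 piRNA loci, 40 TEs)
is sized so that every stage, including the 2,000 × 5,000 bootstrap, runs
in seconds on one CPU while leaving enough features for the statistics to
behave (e.g. BH correction across 200 genes, 20-bin occupancy, ≥95% Pol II
class recovery at noise sd 0.05). `run_pipeline()` uses routine-scale
bootstrap parameters (200 × 2,000) by default; production-scale estimates
should raise them to 2,000 × 5,000 as in `scripts/acceptance.R`.

## Scope and limitations

* The generator models read *placements*, not sequencing errors, adapters
  or quality scores; SAM/BAM is out of scope (BED6+ carries everything the
  analyses need).
* Genome sequence is i.i.d. uniform apart from forced 5′U bases and
  planted TE target sites; there is no codon structure, repeat landscape
  or GC bias, so target-scan background hit rates are lower than in a real
  genome.
* Expression DE power at the default 4 replicates and strict thresholds is
  deliberately marginal — only strongly desilenced targets reach
  significance; raise `n_reps` for high-power contrasts.
* The imaging model is a single z-slice with disk nuclei and flat-top GFP
  enrichment; background ROIs may graze the enrichment annulus just
  outside a segmented focus, biasing noise-free ratios a few percent below
  the configured enrichment factor.
* Association measures reported for binned expression comparisons include
  both the Pearson correlation coefficient and the regression slope where
  a linear fit is used; they are labelled explicitly since "linear
  regression correlation coefficient" is ambiguous.
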