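test_that("syn_config validates its fields", {
  expect_s3_class(syn_config(), "syn_config")
  expect_error(syn_config(n_genes = 0L), "positive count")
  expect_error(syn_config(frac_motif_dependent = 1.2), "lie in \\[0, 1\\]")
  expect_error(syn_config(wt_length_modes = c(45L, 26L)), "increasing pair")
  expect_error(syn_config(mode_weights = c(-1, 2)), "non-negative")
  # weights are normalized
  expect_equal(sum(syn_config(mode_weights = c(3, 1))$mode_weights), 1)
})

test_that("make_genome is deterministic under a fixed config", {
  cfg <- tiny_cfg()
  g1 <- make_genome(cfg)
  g2 <- make_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$ann$genes, g2$ann$genes)
  expect_identical(g1$truth, g2$truth)
  # different seed, different genome
  g3 <- make_genome(tiny_cfg(seed = 12L))
  expect_false(identical(as.character(g1$genome), as.character(g3$genome)))
})

test_that("motif-dependent loci lie in exactly n_clusters disjoint regions", {
  fx <- tiny_fixture()
  cl <- fx$gen$clusters
  pl <- fx$gen$ann$pirna_loci
  md <- pl[pl$kind == "motif_dependent", ]
  expect_equal(nrow(cl), fx$cfg$n_clusters)
  expect_equal(nrow(md), fx$cfg$n_clusters * fx$cfg$n_pirna_loci)
  # disjoint cluster intervals
  o <- cl[order(cl$start), ]
  if (nrow(o) > 1L)
    expect_true(all(o$start[-1L] >= o$end[-nrow(o)]))
  # every motif-dependent 5'U inside some cluster on the cluster chromosome
  inside <- vapply(seq_len(nrow(md)), function(i)
    any(cl$chrom == md$chrom[i] & md$u5_pos[i] >= cl$start &
          md$u5_pos[i] < cl$end), logical(1))
  expect_true(all(inside))
  # motif-independent loci outside every cluster
  mi <- pl[pl$kind == "motif_independent", ]
  outside <- vapply(seq_len(nrow(mi)), function(i)
    !any(cl$chrom == mi$chrom[i] & mi$u5_pos[i] >= cl$start &
           mi$u5_pos[i] < cl$end), logical(1))
  expect_true(all(outside))
})

test_that("the genome base at every 5'U site is U (T) on the locus strand", {
  fx <- tiny_fixture()
  pl <- fx$gen$ann$pirna_loci
  base <- vapply(seq_len(nrow(pl)), function(i)
    as.character(Biostrings::subseq(fx$gen$genome[[pl$chrom[i]]],
                                    pl$u5_pos[i] + 1L, pl$u5_pos[i] + 1L)),
    "")
  expected <- ifelse(pl$strand == "+", "T", "A")
  expect_identical(base, expected)
})

test_that("gene models are internally consistent and non-overlapping", {
  fx <- tiny_fixture()
  g <- fx$gen$ann$genes; ex <- fx$gen$ann$exons
  expect_equal(nrow(g), fx$cfg$n_genes)
  m <- match(ex$gene_id, g$gene_id)
  expect_true(all(ex$start >= g$start[m] & ex$end <= g$end[m]))
  expect_true(all(ex$strand == g$strand[m]))
  # genes do not overlap one another
  for (ch in unique(g$chrom)) {
    gi <- g[g$chrom == ch, ]
    gi <- gi[order(gi$start), ]
    if (nrow(gi) > 1L)
      expect_true(all(gi$start[-1L] >= gi$end[-nrow(gi)]))
  }
})

test_that("ground truth marks the configured silenced fraction", {
  fx <- tiny_fixture()
  n_sil <- round(fx$cfg$silenced_frac * fx$cfg$n_genes)
  expect_equal(sum(fx$gen$truth$silenced), n_sil)
  expect_identical(genes_with_label(fx$gen$ann, "piRNA_target"),
                   fx$gen$truth$gene_id[fx$gen$truth$silenced])
  expect_true(all(fx$gen$truth$mut_expr_mult[fx$gen$truth$silenced] > 1))
})

test_that("simulated small-RNA sidecar labels agree with read classes", {
  fx <- tiny_fixture()
  sm <- suppressWarnings(make_small_rnas(fx$cfg, fx$gen))
  sc <- sm$sidecar
  expect_equal(nrow(sc), nrow(sm$reads))
  expect_true(all(sc$class[sc$origin == "piRNA"] == "piRNA_21U"))
  expect_true(all(sc$class[sc$origin == "siRNA22G"] == "siRNA_22G"))
  # mature piRNAs: 21 nt, 5' U, initiating exactly at a 5'U site
  pi <- sm$reads[sc$origin == "piRNA", ]
  expect_true(all(pi$end - pi$start == 21L))
  expect_true(all(substr(pi$sequence, 1L, 1L) == "T"))
  p5 <- five_prime_end(pi$start, pi$end, pi$strand)
  key <- paste(pi$chrom, pi$strand, p5)
  pl <- fx$gen$ann$pirna_loci
  expect_true(all(key %in% paste(pl$chrom, pl$strand, pl$u5_pos)))
})

test_that("multimapper placements share a read id and a multiplicity", {
  fx <- tiny_fixture()
  sm <- suppressWarnings(make_small_rnas(fx$cfg, fx$gen))
  r <- sm$reads
  multi <- r[r$multiplicity > 1L, ]
  expect_gt(nrow(multi), 0L)
  tab <- table(multi$read_id)
  k <- multi$multiplicity[match(names(tab), multi$read_id)]
  expect_equal(as.integer(tab), as.integer(k))
  # one sequence per multimapper, shared across its placements
  nseq <- tapply(multi$sequence, multi$read_id,
                 function(s) length(unique(s)))
  expect_true(all(nseq == 1L))
})

test_that("mature piRNAs and silenced-target 22Gs are depleted in mutant", {
  fx <- tiny_fixture()
  sm_wt <- suppressWarnings(make_small_rnas(fx$cfg, fx$gen, "wildtype"))
  sm_mut <- suppressWarnings(make_small_rnas(fx$cfg, fx$gen, "mutant"))
  n21 <- function(sm) sum(sm$sidecar$origin == "piRNA")
  expect_lt(n21(sm_mut), 0.5 * n21(sm_wt))
  sil <- fx$gen$truth$gene_id[fx$gen$truth$silenced]
  c_wt <- count_antisense(sm_wt$reads, fx$gen$ann, class_filter = "siRNA_22G")
  c_mut <- count_antisense(sm_mut$reads, fx$gen$ann,
                           class_filter = "siRNA_22G")
  expect_lt(sum(c_mut[sil]), 0.5 * sum(c_wt[sil]))
})

test_that("capped reads initiate 2 nt upstream of a 5'U when unjittered", {
  fx <- tiny_fixture()
  cfg0 <- tiny_cfg(jitter_frac = 0)
  cap <- make_capped_reads(cfg0, fx$gen, n_reads = 500L)
  p5 <- five_prime_end(cap$start, cap$end, cap$strand)
  pl <- fx$gen$ann$pirna_loci
  # the canonical initiation site, in the transcription direction
  canon <- ifelse(pl$strand == "+", pl$u5_pos - 2L, pl$u5_pos + 2L)
  expect_true(all(paste(cap$chrom, cap$strand, p5) %in%
                    paste(pl$chrom, pl$strand, canon)))
  expect_true(all(cap$assay == "capped"))
})

test_that("precursor lengths follow the genotype's preset modes", {
  fx <- tiny_fixture()
  cap_wt <- make_capped_reads(fx$cfg, fx$gen, "wildtype", n_reads = 8000L)
  cap_mut <- make_capped_reads(fx$cfg, fx$gen, "mutant", n_reads = 8000L)
  modal <- function(x) as.integer(names(which.max(table(x))))
  expect_equal(modal(cap_wt$end - cap_wt$start), fx$cfg$wt_length_modes[1])
  expect_equal(modal(cap_mut$end - cap_mut$start), fx$cfg$mut_length_modes[1])
})

test_that("cleavage fragments sit on motif-dependent loci, scaled in mutant", {
  fx <- tiny_fixture()
  mp_wt <- make_cleavage_fragments(fx$cfg, fx$gen, "wildtype",
                                   n_frags = 2000L)
  mp_mut <- make_cleavage_fragments(fx$cfg, fx$gen, "mutant",
                                    n_frags = 2000L)
  expect_true(all(mp_wt$assay == "monoP"))
  md <- fx$gen$ann$pirna_loci[
    fx$gen$ann$pirna_loci$kind == "motif_dependent", ]
  expect_true(all(mp_wt$chrom %in% md$chrom))
  expect_true(all(mp_wt$strand %in% md$strand))
  # abundance scaled by cleavage_scale_mut in the mutant
  expect_lt(nrow(mp_mut), 0.5 * nrow(mp_wt))
})

test_that("noise-free images are two-level in GFP and masked to a disk", {
  cfg <- tiny_cfg(image_noise = "none")
  img <- make_images(cfg, colocalized = TRUE, n_nuclei = 1L)[[1]]
  expect_equal(dim(img$gfp), c(cfg$image_size, cfg$image_size))
  in_vals <- sort(unique(img$gfp[img$mask]))
  expect_equal(in_vals, c(200, 200 * cfg$foci_enrichment))
  expect_true(all(img$gfp[!img$mask] == 0))
  # non-colocalized GFP is flat inside the nucleus
  img0 <- make_images(cfg, colocalized = FALSE, n_nuclei = 1L)[[1]]
  expect_equal(unique(img0$gfp[img0$mask]), 200)
  # mCherry carries the foci either way
  expect_gt(max(img0$mcherry), 500)
})

test_that("expression tables require two genotypes and two replicates", {
  fx <- tiny_fixture()
  expect_error(make_expression_tables(fx$cfg, fx$gen, genotypes = "wildtype"),
               "at least two genotypes")
  expect_error(make_expression_tables(fx$cfg, fx$gen, n_reps = 1L),
               "fewer than 2 replicates")
  expect_error(make_small_rnas(fx$cfg, fx$gen, genotype = "mystery"),
               "unknown genotype")
})
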