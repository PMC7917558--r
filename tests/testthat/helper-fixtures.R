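# Shared small fixture, generated once per test run.
.fixture_env <- new.env(parent = emptyenv())

tiny_cfg <- function(seed = 11L, ...) {
  syn_config(seed = seed, n_genes = 40L, n_pirna_loci = 10L,
             n_te_copies = 10L, chrom_len = 120000L, image_size = 96L, ...)
}

tiny_fixture <- function() {
  if (is.null(.fixture_env$gen)) {
    .fixture_env$cfg <- tiny_cfg()
    .fixture_env$gen <- make_genome(.fixture_env$cfg)
  }
  list(cfg = .fixture_env$cfg, gen = .fixture_env$gen)
}

# A tiny hand-built annotation: one gene per strand, known exons, two piRNA
# loci (one per kind) and one TE copy, on a 1000-bp chromosome.
toy_annotation <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chrT",
    start = c(100L, 500L), end = c(300L, 800L),
    strand = c("+", "-"),
    labels = c("germline,piRNA_target", "soma"),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("gA", "gA", "gB"), chrom = "chrT",
    start = c(100L, 220L, 500L), end = c(180L, 300L, 800L),
    strand = c("+", "+", "-"), stringsAsFactors = FALSE)
  pirna_loci <- data.frame(
    locus_id = c("p1", "p2"), chrom = "chrT",
    u5_pos = c(400L, 900L), strand = c("+", "-"),
    kind = c("motif_dependent", "motif_independent"),
    stringsAsFactors = FALSE)
  te_copies <- data.frame(
    te_id = "t1", family = "TEfam1", chrom = "chrT",
    start = 150L, end = 250L, strand = "+", stringsAsFactors = FALSE)
  annotation_set(genes, exons, pirna_loci, te_copies,
                 chrom_lengths = c(chrT = 1000L))
}
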