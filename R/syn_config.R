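#' Configuration for the synthetic-data generator
#'
#' Builds and validates the single configuration object that every generator
#' consumes. The defaults are the study conditions the analyses assume:
#' wild-type nascent precursor lengths bimodal with modes 26 and 45 nt,
#' shifted to 28 and 47 nt in the termination-defective mutant; capped reads
#' initiating 2 nt upstream of the annotated piRNA 5'U site; ~20-nt
#' 3'-cleavage fragments centred at +38 from the TSS; motif-dependent piRNA
#' loci confined to two contiguous clusters.
#'
#' @param seed integer master seed; identical configurations produce
#'   byte-identical outputs.
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length (bp).
#' @param n_genes number of protein-coding gene models.
#' @param n_pirna_loci motif-dependent piRNA loci per cluster.
#' @param n_clusters number of contiguous piRNA clusters.
#' @param frac_motif_dependent proportion of all piRNA loci that are
#'   motif-dependent (the remainder are scattered motif-independent loci).
#' @param tss_offset_upstream canonical initiation offset of capped precursors
#'   upstream of the 5'U site (nt).
#' @param wt_length_modes,mut_length_modes the two precursor length modes (nt)
#'   for wild type and mutant.
#' @param length_mode_sd standard deviation (nt) of each length-mixture
#'   component.
#' @param mode_weights mixing proportions of the two length components.
#' @param cleavage_center centre of the cleavage-fragment 5'-end distribution,
#'   nt downstream of the TSS.
#' @param cleavage_sd standard deviation (nt) of cleavage 5'-end positions.
#' @param fragment_len_mode,fragment_len_sd cleavage-fragment length mode and
#'   sd (nt).
#' @param cleavage_scale_mut mutant/wild-type ratio of expected cleavage
#'   fragment abundance.
#' @param n_te_copies number of transposable-element copies.
#' @param te_target_frac fraction of TE copies that receive one planted
#'   antisense piRNA target site carrying 0-3 substitutions, so the
#'   mismatch-tolerant target scan has true sites to find.
#' @param silenced_frac proportion of genes given the piRNA-target structure
#'   (top 22G density, low wild-type expression, desilenced in mutant).
#' @param depletion_factor_mut mutant/wild-type ratio of 22G abundance at the
#'   silenced target set (restored in rescue).
#' @param pirna_depletion_mut mutant/wild-type ratio of mature piRNA abundance.
#' @param multimap_frac fraction of simulated small-RNA reads duplicated into
#'   decoy placements with multiplicity 2 or 4.
#' @param jitter_frac fraction of capped reads whose initiation offset is
#'   jittered off the canonical position.
#' @param chip_noise_sd per-window noise sd of the Pol II log2
#'   fold-enrichment tracks.
#' @param image_size image side length in pixels.
#' @param n_foci foci per nucleus.
#' @param foci_enrichment GFP in-foci/background enrichment ratio when
#'   channels colocalize.
#' @param image_noise `"poisson"` for shot noise, `"none"` for noise-free
#'   images.
#' @return an object of class `syn_config` (a validated list).
#' @export
syn_config <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_len = 400000L,
                       n_genes = 200L,
                       n_pirna_loci = 50L,
                       n_clusters = 2L,
                       frac_motif_dependent = 0.8,
                       tss_offset_upstream = 2L,
                       wt_length_modes = c(26L, 45L),
                       mut_length_modes = c(28L, 47L),
                       length_mode_sd = 1.5,
                       mode_weights = c(0.6, 0.4),
                       cleavage_center = 38L,
                       cleavage_sd = 2,
                       fragment_len_mode = 20L,
                       fragment_len_sd = 1,
                       cleavage_scale_mut = 0.2,
                       n_te_copies = 40L,
                       te_target_frac = 0.5,
                       silenced_frac = 0.05,
                       depletion_factor_mut = 0.2,
                       pirna_depletion_mut = 0.15,
                       multimap_frac = 0.1,
                       jitter_frac = 0.1,
                       chip_noise_sd = 0.05,
                       image_size = 128L,
                       n_foci = 3L,
                       foci_enrichment = 2,
                       image_noise = c("poisson", "none")) {
  image_noise <- match.arg(image_noise)
  cfg <- list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_len = as.integer(chrom_len), n_genes = as.integer(n_genes),
    n_pirna_loci = as.integer(n_pirna_loci),
    n_clusters = as.integer(n_clusters),
    frac_motif_dependent = frac_motif_dependent,
    tss_offset_upstream = as.integer(tss_offset_upstream),
    wt_length_modes = as.integer(wt_length_modes),
    mut_length_modes = as.integer(mut_length_modes),
    length_mode_sd = length_mode_sd,
    mode_weights = mode_weights / sum(mode_weights),
    cleavage_center = as.integer(cleavage_center),
    cleavage_sd = cleavage_sd,
    fragment_len_mode = as.integer(fragment_len_mode),
    fragment_len_sd = fragment_len_sd,
    cleavage_scale_mut = cleavage_scale_mut,
    n_te_copies = as.integer(n_te_copies),
    te_target_frac = te_target_frac,
    silenced_frac = silenced_frac,
    depletion_factor_mut = depletion_factor_mut,
    pirna_depletion_mut = pirna_depletion_mut,
    multimap_frac = multimap_frac,
    jitter_frac = jitter_frac,
    chip_noise_sd = chip_noise_sd,
    image_size = as.integer(image_size),
    n_foci = as.integer(n_foci),
    foci_enrichment = foci_enrichment,
    image_noise = image_noise
  )
  validate_syn_config(cfg)
  structure(cfg, class = "syn_config")
}

validate_syn_config <- function(cfg) {
  counts <- c("n_chrom", "chrom_len", "n_genes", "n_clusters", "image_size")
  for (f in counts) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] <= 0L)
      stop("syn_config: '", f, "' must be a positive count", call. = FALSE)
  }
  for (f in c("n_pirna_loci", "n_te_copies", "n_foci", "tss_offset_upstream")) {
    if (cfg[[f]] < 0L)
      stop("syn_config: '", f, "' must be non-negative", call. = FALSE)
  }
  props <- c("frac_motif_dependent", "silenced_frac", "multimap_frac",
             "jitter_frac", "te_target_frac")
  for (f in props) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("syn_config: '", f, "' must lie in [0, 1]", call. = FALSE)
  }
  for (f in c("wt_length_modes", "mut_length_modes")) {
    if (length(cfg[[f]]) != 2L || cfg[[f]][1L] >= cfg[[f]][2L])
      stop("syn_config: '", f, "' must be an increasing pair", call. = FALSE)
  }
  if (any(cfg$mode_weights < 0))
    stop("syn_config: 'mode_weights' must be non-negative", call. = FALSE)
  for (f in c("depletion_factor_mut", "pirna_depletion_mut",
              "cleavage_scale_mut", "foci_enrichment")) {
    if (cfg[[f]] < 0)
      stop("syn_config: '", f, "' must be non-negative", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.syn_config <- function(x, ...) {
  cat("Synthetic-data configuration (seed ", x$seed, ")\n", sep = "")
  cat("  genome: ", x$n_chrom, " chromosome(s) x ", x$chrom_len, " bp, ",
      x$n_genes, " genes, ", x$n_te_copies, " TE copies\n", sep = "")
  cat("  piRNA loci: ", x$n_pirna_loci, " motif-dependent per cluster x ",
      x$n_clusters, " clusters (", round(100 * x$frac_motif_dependent),
      "% motif-dependent overall)\n", sep = "")
  cat("  precursor length modes: wt ", paste(x$wt_length_modes, collapse = "/"),
      " nt, mutant ", paste(x$mut_length_modes, collapse = "/"),
      " nt (sd ", x$length_mode_sd, ")\n", sep = "")
  cat("  initiation offset: -", x$tss_offset_upstream,
      " nt; cleavage centre: +", x$cleavage_center, " from TSS\n", sep = "")
  invisible(x)
}

genotypes_known <- c("wildtype", "mutant", "rescue")
fractions_known <- c("chromatin", "nucleoplasm", "none")
assays_known <- c("smallRNA", "capped", "monoP")

check_genotype <- function(genotype) {
  if (!genotype %in% genotypes_known)
    stop("unknown genotype '", genotype, "'; expected one of ",
         paste(genotypes_known, collapse = ", "), call. = FALSE)
  genotype
}
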