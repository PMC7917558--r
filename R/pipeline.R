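#' Write every simulated input to an output directory
#'
#' Generates the full input bundle under one seeded configuration: genome
#' FASTA, GFF3 + BED annotations, small-RNA / capped / monoP read tables
#' (BED6+), the ground-truth sidecar, expression counts and DE tables (TSV),
#' Pol II bedGraph tracks per genotype, two-channel nuclear TIFFs with
#' masks, and an echo of the effective configuration (JSON).
#'
#' @param cfg a [syn_config()] object.
#' @param out_dir output directory (created if missing).
#' @param genotypes genotypes to simulate.
#' @param n_capped,n_frags,n_nuclei per-genotype read/image counts.
#' @return invisibly, the list of generated in-memory objects.
#' @export
simulate_all <- function(cfg, out_dir,
                         genotypes = c("wildtype", "mutant"),
                         n_capped = 20000L, n_frags = 10000L,
                         n_nuclei = 4L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- make_genome(cfg)
  write_genome_fasta(gen$genome, file.path(out_dir, "genome.fa"))
  write_annotations(gen$ann, file.path(out_dir, "genes.gff3"),
                    file.path(out_dir, "pirna_loci.bed"),
                    file.path(out_dir, "te_copies.bed"))
  write_tsv(gen$truth, file.path(out_dir, "truth.tsv"))

  objs <- list(gen = gen)
  for (g in genotypes) {
    sm <- make_small_rnas(cfg, gen, g)
    write_reads_bed(sm$reads, file.path(out_dir, paste0("smallrna_", g, ".bed")))
    write_tsv(sm$sidecar, file.path(out_dir, paste0("sidecar_", g, ".tsv")))
    cap <- make_capped_reads(cfg, gen, g, "chromatin", n_reads = n_capped)
    write_reads_bed(cap, file.path(out_dir, paste0("capped_", g, ".bed")))
    mp <- make_cleavage_fragments(cfg, gen, g, n_frags = n_frags)
    write_reads_bed(mp, file.path(out_dir, paste0("monop_", g, ".bed")))
    tr <- make_chip_tracks(cfg, gen, g)
    write_bedgraph(tr, file.path(out_dir, paste0("chip_", g, ".bedgraph")))
    objs[[g]] <- list(smallrna = sm, capped = cap, monop = mp, chip = tr)
  }
  expr <- make_expression_tables(cfg, gen, genotypes[1:2])
  write_counts_tsv(expr$counts, file.path(out_dir, "mrna_counts.tsv"))
  write_tsv(expr$de, file.path(out_dir, "de_table.tsv"))
  objs$expr <- expr

  for (coloc in c(TRUE, FALSE)) {
    imgs <- make_images(cfg, colocalized = coloc, n_nuclei = n_nuclei)
    tag <- if (coloc) "coloc" else "nocoloc"
    for (i in seq_along(imgs)) {
      write_image_tiff(imgs[[i]]$mcherry,
                       file.path(out_dir, sprintf("img_%s_%02d_mcherry.tif", tag, i)),
                       max_value = 4096)
      write_image_tiff(imgs[[i]]$gfp,
                       file.path(out_dir, sprintf("img_%s_%02d_gfp.tif", tag, i)),
                       max_value = 4096)
      write_image_tiff(imgs[[i]]$mask * 1,
                       file.path(out_dir, sprintf("img_%s_%02d_mask.tif", tag, i)),
                       max_value = 1)
    }
    objs[[paste0("images_", tag)]] <- imgs
  }
  cfg_out <- unclass(cfg)
  jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(objs)
}

#' Run the full analysis pipeline on simulated data
#'
#' simulate -> classify/count -> bins -> target scan -> termination profiles
#' -> Pol II classes -> DE/overlap -> colocalization, writing a
#' machine-readable JSON summary of every headline statistic. Deterministic
#' under a fixed configuration seed.
#'
#' @param cfg a [syn_config()] object.
#' @param out_dir output directory for the summary (created if missing).
#' @param n_bins transcriptome bins.
#' @param n_capped capped reads per genotype.
#' @param n_subsamples,subsample_size bootstrap parameters for the peak
#'   estimator (sized for routine runs; raise for production estimates).
#' @param n_nuclei nuclei per genotype in the colocalization stage.
#' @return the summary list (also written to `out_dir/summary.json`).
#' @export
run_pipeline <- function(cfg, out_dir, n_bins = 20L, n_capped = 20000L,
                         n_subsamples = 200L, subsample_size = 2000L,
                         n_nuclei = 8L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = cfg$seed)
  gen <- make_genome(cfg)

  # small-RNA classification + antisense 22G counting
  sm_wt <- make_small_rnas(cfg, gen, "wildtype")
  sm_mut <- make_small_rnas(cfg, gen, "mutant")
  cls <- table(classify_reads(sm_wt$reads))
  c22_wt <- count_antisense(sm_wt$reads, gen$ann, class_filter = "siRNA_22G")
  c22_mut <- count_antisense(sm_mut$reads, gen$ann, class_filter = "siRNA_22G")
  ex_len <- vapply(split(gen$ann$exons$end - gen$ann$exons$start,
                         gen$ann$exons$gene_id), sum, numeric(1))
  cm22 <- count_matrix(cbind(wildtype = c22_wt, mutant = c22_mut),
                       lengths = ex_len[names(c22_wt)])
  tpm22 <- normalize_counts(cm22, "TPM")
  summary$smallrna <- list(
    class_counts = as.list(cls),
    total_22g_wt = unname(sum(c22_wt)), total_22g_mut = unname(sum(c22_mut)))

  # density bins + expression overlay + set composition
  expr <- make_expression_tables(cfg, gen)
  bins <- assign_bins(tpm22[, "wildtype"], n_bins)
  mtpm <- normalize_counts(count_matrix(expr$counts$counts,
                                        expr$counts$lengths), "TPM",
                           pseudo = TRUE)
  wt_cols <- grep("^wildtype_", colnames(mtpm))
  mut_cols <- grep("^mutant_", colnames(mtpm))
  expr_log <- list(wildtype = log2(rowMeans(mtpm[, wt_cols, drop = FALSE])),
                   mutant = log2(rowMeans(mtpm[, mut_cols, drop = FALSE])))
  bsum <- bin_expression_summary(bins, expr_log)
  sets <- list(piRNA_target = genes_with_label(gen$ann, "piRNA_target"),
               HRDE1_target = genes_with_label(gen$ann, "HRDE1_target"),
               CSR1_target = genes_with_label(gen$ann, "CSR1_target"))
  comp <- bin_set_composition(bins, sets)
  top <- levels(bins$assignment)[n_bins]
  summary$bins <- list(
    n_bins = n_bins, occupancy = as.list(bins$occupancy),
    top_bin_mean_wt = bsum$mean_wildtype[bsum$bin == top],
    top_bin_mean_mut = bsum$mean_mutant[bsum$bin == top],
    pirna_target_top_bin_prop = unname(comp["piRNA_target", top]))
  write_tsv(bsum, file.path(out_dir, "bin_summary.tsv"))

  # piRNA target scan against TE consensus sequences
  pl <- gen$ann$pirna_loci
  pirnas <- setNames(genome_read_seq(
    gen$genome, pl$chrom,
    ifelse(pl$strand == "+", pl$u5_pos, pl$u5_pos - 20L),
    ifelse(pl$strand == "+", pl$u5_pos + 21L, pl$u5_pos + 1L),
    pl$strand), pl$locus_id)
  te <- gen$ann$te_copies
  te_seq <- setNames(genome_read_seq(gen$genome, te$chrom, te$start, te$end,
                                     te$strand), te$te_id)
  hits <- scan_targets(pirnas, te_seq, k_max = 3L)
  fam <- setNames(te$family, te$te_id)
  mt <- cumulative_match_table(hits, fam)
  summary$target_scan <- list(n_hits = nrow(hits),
                              n_families = nrow(mt),
                              total_k3 = sum(mt$k3))
  write_tsv(mt, file.path(out_dir, "match_table.tsv"))

  # termination profiles
  cap_wt <- make_capped_reads(cfg, gen, "wildtype", "chromatin", n_capped)
  cap_mut <- make_capped_reads(cfg, gen, "mutant", "chromatin", n_capped)
  len_wt <- extract_precursors(cap_wt, gen$ann)
  len_mut <- extract_precursors(cap_mut, gen$ann)
  lw <- unlist(len_wt[grep("^motif_dependent", names(len_wt))])
  lm <- unlist(len_mut[grep("^motif_dependent", names(len_mut))])
  pk_wt <- estimate_peaks(lw, n_subsamples, min(subsample_size, length(lw)),
                          seed = cfg$seed)
  pk_mut <- estimate_peaks(lm, n_subsamples, min(subsample_size, length(lm)),
                           seed = cfg$seed)
  off <- offset_profile(cap_wt, gen$ann, window = 50L)
  monop <- make_cleavage_fragments(cfg, gen, "wildtype")
  cp <- cleavage_profile(monop, gen$ann)
  shift <- median_shift(lw, lm, seed = cfg$seed)
  summary$termination <- list(
    wt_peaks = c(pk_wt$median_lower, pk_wt$median_upper),
    mut_peaks = c(pk_mut$median_lower, pk_mut$median_upper),
    median_shift = shift$shift,
    modal_offset = off$offset[which.max(off$count)],
    modal_cleavage_position = cp$position[which.max(cp$rpm)])
  write_tsv(off, file.path(out_dir, "offset_profile.tsv"))
  write_tsv(cp, file.path(out_dir, "cleavage_profile.tsv"))

  # Pol II classes
  tr_wt <- make_chip_tracks(cfg, gen, "wildtype")
  tr_mut <- make_chip_tracks(cfg, gen, "mutant")
  m_wt <- gene_body_enrichment(tr_wt, gen$ann)
  m_mut <- gene_body_enrichment(tr_mut, gen$ann)
  pc <- assign_classes(m_mut, m_wt)
  summary$chip <- list(class_counts = as.list(table(pc$class)),
                       accuracy = mean(as.character(pc$class) ==
                                         gen$truth$chip_class
                                       [match(names(pc$class),
                                              gen$truth$gene_id)]))

  # DE calling + overlap statistics
  de <- call_deg(expr$de)
  ds <- deg_summary(de)
  ov <- overlap_stats(de$feature_id[de$direction == "up"],
                      genes_with_label(gen$ann, "piRNA_target"),
                      de$feature_id)
  summary$overlap <- list(deg = ds,
                          rf = ov$representation_factor, p = ov$p_value)

  # colocalization
  img_a <- make_images(cfg, colocalized = TRUE, n_nuclei = n_nuclei)
  img_b <- make_images(cfg, colocalized = FALSE, n_nuclei = n_nuclei)
  ra <- coloc_pipeline(img_a, seed = cfg$seed)
  rb <- coloc_pipeline(img_b, seed = cfg$seed)
  gt <- genotype_test(ra, rb)
  summary$coloc <- list(mean_ratio_coloc = mean(ra),
                        mean_ratio_nocoloc = mean(rb), p = gt$p_value)

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10)
  summary
}
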