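#' Simulate per-gene mRNA counts and a differential-expression table
#'
#' Counts are negative binomial around each gene's ground-truth mean; the
#' silenced target set pairs top 22G density with bottom-quartile wild-type
#' expression and is desilenced (mean raised) in the mutant. The DE table
#' compares the second genotype against the first with a Welch two-sample
#' t-test on log2(count + 1) across replicates, Benjamini-Hochberg adjusted.
#'
#' @inheritParams make_small_rnas
#' @param genotypes character vector of at least two genotypes; the DE table
#'   contrasts `genotypes[2]` vs `genotypes[1]`.
#' @param n_reps replicates per genotype (must be >= 2; the test is undefined
#'   otherwise).
#' @param nb_size negative-binomial dispersion parameter.
#' @return list with `counts` (a [count_matrix()] of genes x samples) and
#'   `de` (data frame: feature_id, log2FC, true_log2FC, pvalue, padj).
#' @export
make_expression_tables <- function(cfg, gen, genotypes = c("wildtype", "mutant"),
                                   n_reps = 4L, nb_size = 25) {
  if (length(genotypes) < 2L)
    stop("at least two genotypes are required", call. = FALSE)
  for (g in genotypes) check_genotype(g)
  if (n_reps < 2L)
    stop("fewer than 2 replicates per genotype: differential expression ",
         "is undefined", call. = FALSE)
  set.seed(stage_seed(cfg$seed, "expression", paste(genotypes, collapse = "+")))
  truth <- gen$truth; ann <- gen$ann
  mult_of <- function(g) if (g == "mutant") truth$mut_expr_mult else
    rep(1, nrow(truth))

  samples <- unlist(lapply(genotypes, function(g)
    paste0(g, "_rep", seq_len(n_reps))))
  counts <- matrix(0, nrow(truth), length(samples),
                   dimnames = list(truth$gene_id, samples))
  col <- 0L
  for (g in genotypes) {
    mu <- truth$expr_mean * mult_of(g)
    for (r in seq_len(n_reps)) {
      col <- col + 1L
      counts[, col] <- rnbinom(nrow(truth), mu = mu, size = nb_size)
    }
  }
  ex_len <- vapply(split(ann$exons$end - ann$exons$start, ann$exons$gene_id),
                   sum, numeric(1))[truth$gene_id]
  cm <- count_matrix(counts, lengths = ex_len)

  i1 <- grep(paste0("^", genotypes[1], "_rep"), samples)
  i2 <- grep(paste0("^", genotypes[2], "_rep"), samples)
  lc <- log2(counts + 1)
  m1 <- rowMeans(counts[, i1, drop = FALSE])
  m2 <- rowMeans(counts[, i2, drop = FALSE])
  pv <- vapply(seq_len(nrow(counts)), function(i) {
    a <- lc[i, i1]; b <- lc[i, i2]
    if (sd(a) == 0 && sd(b) == 0)
      return(if (mean(a) == mean(b)) 1 else 0)
    t.test(a, b)$p.value
  }, numeric(1))
  de <- data.frame(
    feature_id = truth$gene_id,
    log2FC = log2((m2 + 1) / (m1 + 1)),
    true_log2FC = log2(vapply(seq_len(nrow(truth)), function(i)
      (truth$expr_mean[i] * mult_of(genotypes[2])[i]) /
        (truth$expr_mean[i] * mult_of(genotypes[1])[i]), numeric(1))),
    pvalue = pv,
    padj = p.adjust(pv, method = "BH"),
    stringsAsFactors = FALSE)
  list(counts = cm, de = de)
}

#' Simulate an RNA Pol II log2 fold-enrichment track
#'
#' Gene bodies are tiled with fixed-width windows whose values fluctuate
#' around the gene's wild-type level; in the mutant the level is multiplied
#' by 1.8, 1.0 or 0.5 according to the gene's true class (I, II, III).
#'
#' @inheritParams make_small_rnas
#' @param window_bp tile width in bp.
#' @param noise_sd per-window Gaussian noise sd; defaults to
#'   `cfg$chip_noise_sd`.
#' @return a [GenomicRanges::GRanges] with a `score` column (log2 fold
#'   enrichment), directly exportable as bedGraph; covers every gene body
#'   with no gaps.
#' @export
make_chip_tracks <- function(cfg, gen, genotype = "wildtype",
                             window_bp = 25L, noise_sd = NULL) {
  check_genotype(genotype)
  if (is.null(noise_sd)) noise_sd <- cfg$chip_noise_sd
  set.seed(stage_seed(cfg$seed, "chip", genotype))
  truth <- gen$truth; g <- gen$ann$genes
  mult <- c(I = 1.8, II = 1.0, III = 0.5)
  level <- truth$chip_wt_level
  if (genotype == "mutant") level <- level * mult[truth$chip_class]
  segs <- vector("list", nrow(g))
  for (i in seq_len(nrow(g))) {
    br <- unique(c(seq(g$start[i], g$end[i], by = window_bp), g$end[i]))
    s <- utils::head(br, -1L); e <- utils::tail(br, -1L)
    segs[[i]] <- data.frame(chrom = g$chrom[i], start = s, end = e,
                            score = level[i] + rnorm(length(s), 0, noise_sd),
                            stringsAsFactors = FALSE)
  }
  segs <- do.call(rbind, segs)
  gr <- GenomicRanges::GRanges(
    seqnames = segs$chrom,
    ranges = IRanges::IRanges(segs$start + 1L, segs$end),
    score = segs$score)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}
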