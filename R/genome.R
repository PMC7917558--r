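#' Generate a toy genome with gene, piRNA-locus and transposon annotations
#'
#' Builds a random genome and a non-overlapping gene complement, places
#' motif-dependent piRNA loci inside `cfg$n_clusters` contiguous cluster
#' regions (with the remainder of loci scattered as motif-independent
#' singletons), and drops transposable-element copies of which a subset
#' overlaps gene exons. Every piRNA locus carries an annotated 5'U position;
#' the genome base at that position on the locus strand is forced to T, so
#' mature 21U reads read off the genome start with uracil.
#'
#' @param cfg a [syn_config()] object.
#' @return a list with elements `genome` (a [Biostrings::DNAStringSet]),
#'   `ann` (an `annotation_set`, see [annotation_set()]) and `truth`
#'   (a per-gene data frame of generator ground truth: silenced status,
#'   22G rate, mean expression, mutant expression multiplier, Pol II class
#'   and wild-type Pol II level) and `clusters` (one row per piRNA cluster
#'   region: cluster, chrom, start, end in 0-based half-open coordinates).
#' @export
make_genome <- function(cfg) {
  validate_syn_config(cfg)
  set.seed(stage_seed(cfg$seed, "genome"))

  chrom_names <- paste0("chr", utils::as.roman(seq_len(cfg$n_chrom)))
  chrom_lengths <- setNames(rep(cfg$chrom_len, cfg$n_chrom), chrom_names)
  seqs <- lapply(chrom_lengths, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  names(seqs) <- chrom_names

  occupied <- lapply(chrom_names, function(x) IRanges::IRanges())
  names(occupied) <- chrom_names
  margin <- 300L

  place <- function(chrom, width, what) {
    L <- chrom_lengths[[chrom]]
    if (width + 2L * margin > L)
      stop("placement-failure: ", what, " of width ", width,
           " does not fit on ", chrom, call. = FALSE)
    for (try in seq_len(500L)) {
      s <- sample.int(L - width - 2L * margin, 1L) + margin  # 0-based start
      cand <- IRanges::IRanges(s + 1L, s + width)            # 1-based for IRanges
      if (IRanges::countOverlaps(cand, occupied[[chrom]]) == 0L) {
        occupied[[chrom]] <<- c(occupied[[chrom]], cand)
        return(s)
      }
    }
    stop("placement-failure: could not place ", what, " on ", chrom,
         " without overlap after 500 attempts", call. = FALSE)
  }

  # -- piRNA cluster regions (reserved first, on the last chromosome) -------
  n_md <- cfg$n_clusters * cfg$n_pirna_loci
  n_mi <- if (cfg$frac_motif_dependent > 0 && n_md > 0)
    as.integer(round(n_md * (1 - cfg$frac_motif_dependent) /
                       cfg$frac_motif_dependent)) else 0L
  spacing <- 120L
  cluster_chrom <- chrom_names[cfg$n_chrom]
  clusters <- data.frame()
  if (n_md > 0L) {
    cluster_width <- cfg$n_pirna_loci * spacing + 100L
    clusters <- do.call(rbind, lapply(seq_len(cfg$n_clusters), function(i) {
      s <- place(cluster_chrom, cluster_width, paste0("piRNA cluster ", i))
      data.frame(cluster = i, chrom = cluster_chrom,
                 start = s, end = s + cluster_width)
    }))
  }

  # -- gene models ----------------------------------------------------------
  genes <- vector("list", cfg$n_genes)
  exons <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    ne <- sample(1:3, 1L)
    exon_w <- sample(150:500, ne, replace = TRUE)
    intr_w <- if (ne > 1L) sample(80:200, ne - 1L, replace = TRUE) else integer(0)
    span <- sum(exon_w) + sum(intr_w)
    chrom <- sample(chrom_names, 1L)
    s <- place(chrom, span, paste0("gene ", g))
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("gene%04d", g)
    offs <- cumsum(c(0L, as.integer(utils::head(
      as.vector(rbind(exon_w, c(intr_w, 0L))), -1L))))
    ex_start <- s + offs[seq(1L, 2L * ne - 1L, by = 2L)]
    genes[[g]] <- data.frame(gene_id = gid, chrom = chrom, start = s,
                             end = s + span, strand = strand,
                             stringsAsFactors = FALSE)
    exons[[g]] <- data.frame(gene_id = gid, chrom = chrom, start = ex_start,
                             end = ex_start + exon_w, strand = strand,
                             stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)

  # -- piRNA loci -----------------------------------------------------------
  loci <- list()
  if (n_md > 0L) {
    k <- 0L
    for (i in seq_len(cfg$n_clusters)) {
      cl <- clusters[i, ]
      for (j in seq_len(cfg$n_pirna_loci)) {
        k <- k + 1L
        u5 <- cl$start + 50L + (j - 1L) * spacing +
          sample.int(40L, 1L)  # stagger within the slot
        loci[[k]] <- data.frame(
          locus_id = sprintf("21ur-%04d", k), chrom = cl$chrom,
          u5_pos = u5, strand = sample(c("+", "-"), 1L),
          kind = "motif_dependent", stringsAsFactors = FALSE)
      }
    }
  }
  if (n_mi > 0L) {
    for (j in seq_len(n_mi)) {
      chrom <- sample(chrom_names, 1L)
      s <- place(chrom, 60L, "motif-independent piRNA locus")
      loci[[length(loci) + 1L]] <- data.frame(
        locus_id = sprintf("21ur-mi-%04d", j), chrom = chrom,
        u5_pos = s + 30L, strand = sample(c("+", "-"), 1L),
        kind = "motif_independent", stringsAsFactors = FALSE)
    }
  }
  pirna_loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(locus_id = character(), chrom = character(),
               u5_pos = integer(), strand = character(), kind = character(),
               stringsAsFactors = FALSE)

  # force T (on the locus strand) at every 5'U position
  if (nrow(pirna_loci)) {
    for (i in seq_len(nrow(pirna_loci))) {
      p <- pirna_loci$u5_pos[i] + 1L  # 1-based into the char vector
      seqs[[pirna_loci$chrom[i]]][p] <-
        if (pirna_loci$strand[i] == "+") "T" else "A"
    }
  }

  # -- transposon copies ----------------------------------------------------
  te <- list()
  families <- paste0("TEfam", 1:5)
  n_in_exon <- as.integer(round(0.25 * cfg$n_te_copies))
  big_exons <- exons[exons$end - exons$start >= 300L, ]
  for (j in seq_len(cfg$n_te_copies)) {
    w <- sample(120:280, 1L)
    if (j <= n_in_exon && nrow(big_exons)) {
      ex <- big_exons[sample.int(nrow(big_exons), 1L), ]
      w <- min(w, ex$end - ex$start)
      s <- ex$start + sample.int(max(1L, ex$end - ex$start - w + 1L), 1L) - 1L
      chrom <- ex$chrom
    } else {
      chrom <- sample(chrom_names, 1L)
      s <- place(chrom, w, paste0("TE copy ", j))
    }
    te[[j]] <- data.frame(te_id = sprintf("te%03d", j),
                          family = sample(families, 1L), chrom = chrom,
                          start = s, end = s + w,
                          strand = sample(c("+", "-"), 1L),
                          stringsAsFactors = FALSE)
  }
  te_copies <- if (length(te)) do.call(rbind, te) else
    data.frame(te_id = character(), family = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)

  # -- per-gene ground truth ------------------------------------------------
  z <- rnorm(cfg$n_genes)
  expr_mean <- exp(4 + 1.2 * z)
  g22_rate <- 3 * exp(0.8 * z)
  ex_len <- vapply(split(exons$end - exons$start, exons$gene_id),
                   sum, numeric(1))[genes$gene_id]
  silenced <- rep(FALSE, cfg$n_genes)
  n_sil <- as.integer(round(cfg$silenced_frac * cfg$n_genes))
  if (n_sil > 0L) {
    idx <- sample.int(cfg$n_genes, n_sil)
    silenced[idx] <- TRUE
    # silenced targets sit at the top of the length-normalized 22G density
    top_density <- max((g22_rate / ex_len)[-idx])
    g22_rate[idx] <- ex_len[idx] * top_density * runif(n_sil, 1.2, 2.0)
    expr_mean[idx] <- quantile(expr_mean[!silenced], 0.10) * runif(n_sil, 0.5, 1)
  }
  truth <- data.frame(
    gene_id = genes$gene_id, silenced = silenced,
    g22_rate = g22_rate, expr_mean = expr_mean,
    mut_expr_mult = ifelse(silenced, 6, 1),
    chip_class = sample(c("I", "II", "III"), cfg$n_genes, replace = TRUE,
                        prob = c(0.25, 0.5, 0.25)),
    chip_wt_level = rnorm(cfg$n_genes, 1.0, 0.1),
    stringsAsFactors = FALSE)

  labels <- character(cfg$n_genes)
  tissue <- sample(c("germline", "soma"), cfg$n_genes, replace = TRUE)
  ago <- sample(c("", "HRDE1_target", "CSR1_target"), cfg$n_genes,
                replace = TRUE, prob = c(0.7, 0.15, 0.15))
  for (g in seq_len(cfg$n_genes)) {
    lab <- c(tissue[g], if (silenced[g]) "piRNA_target",
             if (nzchar(ago[g])) ago[g])
    labels[g] <- paste(lab, collapse = ",")
  }
  genes$labels <- labels

  # plant one degenerate antisense piRNA target site (0-3 substitutions)
  # into a fraction of TE copies, oriented so the site reads as the reverse
  # complement of the piRNA on the TE's own strand
  n_plant <- as.integer(round(cfg$te_target_frac * nrow(te_copies)))
  if (n_plant > 0L && nrow(pirna_loci)) {
    bases4 <- c("A", "C", "G", "T")
    for (j in sample.int(nrow(te_copies), n_plant)) {
      lp <- pirna_loci[sample.int(nrow(pirna_loci), 1L), ]
      s0 <- if (lp$strand == "+") lp$u5_pos else lp$u5_pos - 20L
      seq21 <- paste(seqs[[lp$chrom]][(s0 + 1L):(s0 + 21L)], collapse = "")
      if (lp$strand == "-") seq21 <- revcomp(seq21)
      site <- strsplit(revcomp(seq21), "")[[1]]
      k <- sample(0:3, 1L)
      for (p in if (k > 0L) sample.int(21L, k) else integer(0))
        site[p] <- sample(setdiff(bases4, site[p]), 1L)
      tj <- te_copies[j, ]
      if (tj$strand == "-")
        site <- rev(chartr("ACGT", "TGCA", site))
      off <- sample.int(tj$end - tj$start - 20L, 1L) - 1L
      seqs[[tj$chrom]][(tj$start + off + 1L):(tj$start + off + 21L)] <- site
    }
  }

  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  names(genome) <- chrom_names

  ann <- annotation_set(genes = genes, exons = exons,
                        pirna_loci = pirna_loci, te_copies = te_copies,
                        chrom_lengths = chrom_lengths)
  list(genome = genome, ann = ann, truth = truth, clusters = clusters)
}
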