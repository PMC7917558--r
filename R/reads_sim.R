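#' Construct an aligned-read table
#'
#' Reads are plain data frames with one row per placement, internal
#' 0-based half-open coordinates and an explicit alignment multiplicity: a
#' read reported at k placements appears as k rows that each carry
#' `multiplicity = k`, so fractional counting can weight every placement by
#' `1/multiplicity`.
#'
#' @param read_id,chrom,start,end,strand,multiplicity,assay,fraction,genotype,sequence
#'   column vectors; `sequence` may be `NA` (it is then read off the genome
#'   where needed).
#' @return a validated data frame of class `aligned_reads`.
#' @export
aligned_reads <- function(read_id, chrom, start, end, strand,
                          multiplicity = 1L, assay = "smallRNA",
                          fraction = "none", genotype = "wildtype",
                          sequence = NA_character_) {
  df <- data.frame(read_id = read_id, chrom = chrom,
                   start = as.integer(start), end = as.integer(end),
                   strand = strand,
                   multiplicity = as.integer(multiplicity),
                   assay = assay, fraction = fraction, genotype = genotype,
                   sequence = sequence, stringsAsFactors = FALSE)
  validate_reads(df)
}

validate_reads <- function(df, where = "aligned_reads") {
  bad <- function(i, msg) stop(where, ": ", msg, " (record ",
                               paste(utils::head(i, 3), collapse = ", "),
                               ")", call. = FALSE)
  if (any(df$start < 0L)) bad(which(df$start < 0L), "negative start")
  if (any(df$end <= df$start)) bad(which(df$end <= df$start),
                                   "end must exceed start")
  if (!all(df$strand %in% c("+", "-")))
    bad(which(!df$strand %in% c("+", "-")), "strand must be + or -")
  if (any(df$multiplicity < 1L))
    bad(which(df$multiplicity < 1L), "multiplicity must be >= 1")
  if (!all(df$assay %in% assays_known))
    bad(which(!df$assay %in% assays_known), "unknown assay label")
  if (!all(df$fraction %in% fractions_known))
    bad(which(!df$fraction %in% fractions_known), "unknown fraction label")
  has_seq <- !is.na(df$sequence)
  if (any(has_seq & nchar(df$sequence) != df$end - df$start))
    bad(which(has_seq & nchar(df$sequence) != df$end - df$start),
        "sequence length must equal end - start")
  class(df) <- c("aligned_reads", "data.frame")
  df
}

# read-strand-oriented sequences extracted from the genome, vectorized by chrom
genome_read_seq <- function(genome, chrom, start, end, strand) {
  out <- character(length(chrom))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    v <- Biostrings::Views(genome[[ch]], start = start[i] + 1L, end = end[i])
    s <- as.character(v)
    neg <- strand[i] == "-"
    if (any(neg)) s[neg] <- revcomp(s[neg])
    out[i] <- s
  }
  out
}

#' Simulate a small-RNA sequencing library
#'
#' Emits three read populations: mature 21U piRNAs (21 nt, 5' U, initiating
#' exactly at each locus 5'U site, depleted in the mutant), secondary 22G
#' siRNAs (22 nt, 5' G, antisense to gene exons, with abundance at the
#' silenced target set multiplied by `depletion_factor_mut` in the mutant and
#' restored in the rescue), and background reads of other lengths and 5'
#' bases. A configurable fraction of 22G/background reads is duplicated into
#' intergenic decoy placements with multiplicity 2 or 4 to exercise
#' fractional counting. Ground-truth origin and class labels are returned as
#' a sidecar table.
#'
#' @param cfg a [syn_config()] object.
#' @param gen output of [make_genome()] (genome + annotation + truth).
#' @param genotype one of `"wildtype"`, `"mutant"`, `"rescue"`.
#' @param pirna_mean expected mature piRNA reads per locus in wild type.
#' @param g22_scale multiplier applied to every gene's 22G rate.
#' @param n_background number of background reads.
#' @return list with `reads` (an `aligned_reads` table) and `sidecar`
#'   (data frame: read_id, origin, class).
#' @export
make_small_rnas <- function(cfg, gen, genotype = "wildtype",
                            pirna_mean = 20, g22_scale = 3,
                            n_background = 2000L) {
  check_genotype(genotype)
  set.seed(stage_seed(cfg$seed, "smallrna", genotype))
  ann <- gen$ann; genome <- gen$genome; truth <- gen$truth
  rows <- list(); origin <- list()

  # mature 21U piRNAs
  pl <- ann$pirna_loci
  if (nrow(pl)) {
    scale21 <- if (genotype == "mutant") cfg$pirna_depletion_mut else 1
    n_per <- rpois(nrow(pl), pirna_mean * scale21)
    idx <- rep(seq_len(nrow(pl)), n_per)
    if (length(idx)) {
      st <- ifelse(pl$strand[idx] == "+", pl$u5_pos[idx], pl$u5_pos[idx] - 20L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = pl$chrom[idx], start = as.integer(st),
        end = as.integer(st + 21L), strand = pl$strand[idx],
        multiplicity = 1L, stringsAsFactors = FALSE)
      origin[[length(origin) + 1L]] <- rep("piRNA", length(idx))
    }
  }

  # antisense 22G siRNAs: candidate 5' positions where the antisense base is G
  g <- ann$genes; ex <- ann$exons
  skipped <- 0L
  g22 <- list()
  for (gi in seq_len(nrow(g))) {
    gene <- g[gi, ]
    rate <- truth$g22_rate[gi] * g22_scale
    if (genotype == "mutant" && truth$silenced[gi])
      rate <- rate * cfg$depletion_factor_mut
    n <- rpois(1L, rate)
    if (n == 0L) next
    gex <- ex[ex$gene_id == gene$gene_id & ex$end - ex$start >= 22L, ]
    if (!nrow(gex)) { skipped <- skipped + 1L; next }
    # enumerate read starts with a G first base on the antisense strand
    cand <- integer(0)
    for (e in seq_len(nrow(gex))) {
      s0 <- gex$start[e]; e0 <- gex$end[e]
      bases <- strsplit(as.character(
        Biostrings::Views(genome[[gene$chrom]], s0 + 1L, e0)), "")[[1]]
      if (gene$strand == "+") {
        # read on -, 5' end at pos p (= start+21) needs ref base C
        p <- which(bases == "C") - 1L + s0      # 0-based genomic
        p <- p[p - 21L >= s0 & p + 1L <= e0]
        cand <- c(cand, p - 21L)                # read start
      } else {
        # read on +, 5' end at read start needs ref base G
        p <- which(bases == "G") - 1L + s0
        p <- p[p + 22L <= e0]
        cand <- c(cand, p)
      }
    }
    if (!length(cand)) { skipped <- skipped + 1L; next }
    st <- sample(cand, n, replace = TRUE)
    g22[[length(g22) + 1L]] <- data.frame(
      chrom = gene$chrom, start = st, end = st + 22L,
      strand = if (gene$strand == "+") "-" else "+",
      multiplicity = 1L, stringsAsFactors = FALSE)
  }
  if (length(g22)) {
    g22 <- do.call(rbind, g22)
    rows[[length(rows) + 1L]] <- g22
    origin[[length(origin) + 1L]] <- rep("siRNA22G", nrow(g22))
  }

  # background reads of other lengths / 5' bases
  if (n_background > 0L) {
    chrom <- sample(names(ann$chrom_lengths), n_background, replace = TRUE)
    len <- sample(18:30, n_background, replace = TRUE)
    st <- vapply(seq_len(n_background), function(i)
      sample.int(ann$chrom_lengths[[chrom[i]]] - len[i] - 1L, 1L), integer(1))
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, start = st, end = st + len,
      strand = sample(c("+", "-"), n_background, replace = TRUE),
      multiplicity = 1L, stringsAsFactors = FALSE)
    origin[[length(origin) + 1L]] <- rep("background", n_background)
  }

  reads <- do.call(rbind, rows)
  origin <- unlist(origin)
  reads$read_id <- sprintf("%s_sr%06d", genotype, seq_len(nrow(reads)))

  # multimapper decoys for a fraction of non-piRNA reads
  pickable <- which(origin != "piRNA")
  n_multi <- as.integer(round(cfg$multimap_frac * length(pickable)))
  extra <- NULL
  if (n_multi > 0L) {
    sel <- sample(pickable, n_multi)
    k <- sample(c(2L, 4L), n_multi, replace = TRUE)
    reads$multiplicity[sel] <- k
    ex_gr <- exons_granges(ann)
    dup <- rep(sel, k - 1L)
    len <- reads$end[dup] - reads$start[dup]
    chrom <- sample(names(ann$chrom_lengths), length(dup) * 3L, replace = TRUE)
    st <- vapply(seq_along(chrom), function(i)
      sample.int(ann$chrom_lengths[[chrom[i]]] - 40L, 1L), integer(1))
    cand_gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st + 1L, st + 30L))
    free <- which(GenomicRanges::countOverlaps(cand_gr, ex_gr,
                                               ignore.strand = TRUE) == 0L)
    if (length(free) < length(dup))  # rare: fall back to arbitrary positions
      free <- c(free, setdiff(seq_along(chrom), free))
    free <- free[seq_along(dup)]
    extra <- data.frame(
      chrom = chrom[free], start = st[free], end = st[free] + len,
      strand = reads$strand[dup], multiplicity = reads$multiplicity[dup],
      read_id = reads$read_id[dup], stringsAsFactors = FALSE)
    origin <- c(origin, origin[dup])
  }
  if (!is.null(extra)) reads <- rbind(reads, extra[, names(reads)])

  reads$assay <- "smallRNA"; reads$fraction <- "none"
  reads$genotype <- genotype
  # a multimapper carries one sequence: decoy placements inherit the
  # source placement's sequence rather than the decoy-locus genome bases
  n_primary <- nrow(reads) - NROW(extra)
  reads$sequence <- NA_character_
  reads$sequence[seq_len(n_primary)] <- genome_read_seq(
    genome, reads$chrom[seq_len(n_primary)], reads$start[seq_len(n_primary)],
    reads$end[seq_len(n_primary)], reads$strand[seq_len(n_primary)])
  if (!is.null(extra)) {
    m <- match(reads$read_id[-seq_len(n_primary)],
               reads$read_id[seq_len(n_primary)])
    reads$sequence[-seq_len(n_primary)] <- reads$sequence[m]
  }
  reads <- validate_reads(reads[, c("read_id", "chrom", "start", "end",
                                    "strand", "multiplicity", "assay",
                                    "fraction", "genotype", "sequence")])
  sidecar <- data.frame(read_id = reads$read_id, origin = origin,
                        class = classify_reads(reads),
                        stringsAsFactors = FALSE)
  attr(reads, "n_skipped_genes") <- skipped
  if (skipped > 0L)
    warning(skipped, " gene(s) had no exon able to host a 22-nt read; skipped")
  list(reads = reads, sidecar = sidecar)
}

#' Simulate a short-capped-RNA (nascent precursor) library
#'
#' Reads initiate `cfg$tss_offset_upstream` nt upstream of each locus 5'U
#' (90% of reads by default; the remainder jittered by up to 3 nt with
#' geometrically decaying mass) on the locus strand, with lengths drawn from
#' the genotype's two-component discretized-normal mixture truncated at
#' 16 nt.
#'
#' @inheritParams make_small_rnas
#' @param fraction `"chromatin"` (nascent) or `"nucleoplasm"`.
#' @param n_reads number of reads to emit.
#' @param loci_kind restrict emission to loci of this kind (default: all).
#' @return an `aligned_reads` table.
#' @export
make_capped_reads <- function(cfg, gen, genotype = "wildtype",
                              fraction = c("chromatin", "nucleoplasm"),
                              n_reads = 20000L, loci_kind = NULL) {
  check_genotype(genotype)
  fraction <- match.arg(fraction)
  set.seed(stage_seed(cfg$seed, "capped", genotype, fraction))
  pl <- gen$ann$pirna_loci
  if (!is.null(loci_kind)) pl <- pl[pl$kind %in% loci_kind, ]
  if (!nrow(pl) || n_reads == 0L)
    return(aligned_reads(character(0), character(0), integer(0), integer(0),
                         character(0), assay = "capped"))
  idx <- sample.int(nrow(pl), n_reads, replace = TRUE)

  off <- rep(-cfg$tss_offset_upstream, n_reads)
  jit <- runif(n_reads) < cfg$jitter_frac
  if (any(jit)) {
    jv <- c(-3L, -2L, -1L, 1L, 2L, 3L)
    jp <- 0.5^abs(jv); jp <- jp / sum(jp)
    off[jit] <- off[jit] + sample(jv, sum(jit), replace = TRUE, prob = jp)
  }
  modes <- if (genotype == "mutant") cfg$mut_length_modes else cfg$wt_length_modes
  comp <- sample(1:2, n_reads, replace = TRUE, prob = cfg$mode_weights)
  len <- pmax(16L, as.integer(round(rnorm(n_reads, modes[comp],
                                          cfg$length_mode_sd))))
  pos_strand <- pl$strand[idx] == "+"
  p5 <- ifelse(pos_strand, pl$u5_pos[idx] + off, pl$u5_pos[idx] - off)
  st <- ifelse(pos_strand, p5, p5 - len + 1L)
  en <- st + len
  cl <- gen$ann$chrom_lengths[pl$chrom[idx]]
  st <- pmax(0L, as.integer(st)); en <- pmin(as.integer(cl), as.integer(en))
  aligned_reads(sprintf("%s_%s_cap%06d", genotype, fraction,
                        seq_len(n_reads)),
                pl$chrom[idx], st, en, pl$strand[idx],
                multiplicity = 1L, assay = "capped", fraction = fraction,
                genotype = genotype)
}

#' Simulate 5'-monophosphate cleavage fragments
#'
#' Fragment 5' ends are drawn around `TSS + cleavage_center` in the
#' transcription direction of each motif-dependent locus (TSS is taken 2 nt
#' upstream of the 5'U), with lengths around `fragment_len_mode`. Total
#' abundance is scaled by `cleavage_scale_mut` in the mutant.
#'
#' @inheritParams make_small_rnas
#' @param n_frags expected number of fragments in wild type (Poisson mean).
#' @return an `aligned_reads` table with `assay = "monoP"`.
#' @export
make_cleavage_fragments <- function(cfg, gen, genotype = "wildtype",
                                    n_frags = 10000L) {
  check_genotype(genotype)
  set.seed(stage_seed(cfg$seed, "cleavage", genotype))
  pl <- gen$ann$pirna_loci
  pl <- pl[pl$kind == "motif_dependent", ]
  if (!nrow(pl))
    return(aligned_reads(character(0), character(0), integer(0), integer(0),
                         character(0), assay = "monoP"))
  scale <- if (genotype == "mutant") cfg$cleavage_scale_mut else 1
  n <- rpois(1L, n_frags * scale)
  if (n == 0L)
    return(aligned_reads(character(0), character(0), integer(0), integer(0),
                         character(0), assay = "monoP"))
  idx <- sample.int(nrow(pl), n, replace = TRUE)
  d <- as.integer(round(rnorm(n, cfg$cleavage_center, cfg$cleavage_sd)))
  len <- pmax(1L, as.integer(round(rnorm(n, cfg$fragment_len_mode,
                                         cfg$fragment_len_sd))))
  pos_strand <- pl$strand[idx] == "+"
  tss <- ifelse(pos_strand, pl$u5_pos[idx] - 2L, pl$u5_pos[idx] + 2L)
  p5 <- ifelse(pos_strand, tss + d, tss - d)
  st <- ifelse(pos_strand, p5, p5 - len + 1L)
  en <- st + len
  cl <- gen$ann$chrom_lengths[pl$chrom[idx]]
  st <- pmax(0L, as.integer(st)); en <- pmin(as.integer(cl), as.integer(en))
  aligned_reads(sprintf("%s_monoP%06d", genotype, seq_len(n)),
                pl$chrom[idx], st, en, pl$strand[idx],
                multiplicity = 1L, assay = "monoP", fraction = "none",
                genotype = genotype)
}
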