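#' File formats
#'
#' All readers convert to the internal convention (0-based half-open
#' coordinates, strand-aware 5' ends per [five_prime_end()]); all writers
#' emit the standard convention of each format (GFF3 1-based closed, BED
#' 0-based half-open). TSVs are tab-delimited with headers, UTF-8, Unix
#' newlines. Reader/writer pairs round-trip.
#'
#' @name formats
NULL

#' @rdname formats
#' @param genome a [Biostrings::DNAStringSet].
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname formats
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write an annotation set to GFF3 + BED
#'
#' Genes and exons go to GFF3 (gene labels as a `labels` attribute); piRNA
#' loci and TE copies go to BED6+ files, the locus written as a 21-nt span
#' whose strand-aware 5' terminus is the 5'U position, with the motif class
#' (resp. TE family) in column 7.
#'
#' @param ann an `annotation_set`.
#' @param gff_path,pirna_bed_path,te_bed_path output files.
#' @export
write_annotations <- function(ann, gff_path, pirna_bed_path, te_bed_path) {
  g <- ann$genes; ex <- ann$exons
  gr_g <- GenomicRanges::GRanges(g$chrom,
                                 IRanges::IRanges(g$start + 1L, g$end),
                                 strand = g$strand)
  S4Vectors::mcols(gr_g)$type <- "gene"
  S4Vectors::mcols(gr_g)$ID <- g$gene_id
  S4Vectors::mcols(gr_g)$labels <- g$labels
  gr_e <- GenomicRanges::GRanges(ex$chrom,
                                 IRanges::IRanges(ex$start + 1L, ex$end),
                                 strand = ex$strand)
  S4Vectors::mcols(gr_e)$type <- "exon"
  S4Vectors::mcols(gr_e)$Parent <- ex$gene_id
  gr_e_m <- S4Vectors::DataFrame(type = "exon",
                                 ID = NA_character_,
                                 labels = NA_character_,
                                 Parent = ex$gene_id)
  S4Vectors::mcols(gr_e) <- gr_e_m
  S4Vectors::mcols(gr_g)$Parent <- NA_character_
  gff <- c(gr_g, gr_e)
  sl <- ann$chrom_lengths
  GenomeInfoDb::seqlevels(gff) <- names(sl)
  GenomeInfoDb::seqlengths(gff) <- sl
  rtracklayer::export(gff, gff_path, format = "gff3")
  # make chromosome lengths explicit so readers can validate coordinates
  lines <- readLines(gff_path)
  pragma <- sprintf("##sequence-region %s 1 %d", names(sl), sl)
  writeLines(c(lines[1L], pragma, lines[-1L]), gff_path)

  pl <- ann$pirna_loci
  bed <- data.frame(
    chrom = pl$chrom,
    start = ifelse(pl$strand == "+", pl$u5_pos, pl$u5_pos - 20L),
    end = ifelse(pl$strand == "+", pl$u5_pos + 21L, pl$u5_pos + 1L),
    name = pl$locus_id, score = rep(0L, nrow(pl)), strand = pl$strand,
    kind = pl$kind)
  write.table(bed, pirna_bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  te <- ann$te_copies
  bed_te <- data.frame(chrom = te$chrom, start = te$start, end = te$end,
                       name = te$te_id, score = rep(0L, nrow(te)),
                       strand = te$strand, family = te$family)
  write.table(bed_te, te_bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' Read an annotation set from GFF3 + BED
#'
#' @param gff_path GFF3 with gene/exon records.
#' @param pirna_bed_path,te_bed_path BED6+ files as written by
#'   [write_annotations()].
#' @param chrom_lengths optional named lengths; defaults to the GFF3
#'   `##sequence-region` pragmas.
#' @return an `annotation_set`.
#' @export
read_annotations <- function(gff_path, pirna_bed_path, te_bed_path,
                             chrom_lengths = NULL) {
  gff <- tryCatch(rtracklayer::import(gff_path, format = "gff3"),
                  error = function(e) stop("parse error in ", gff_path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(chrom_lengths)) {
    hdr <- grep("^##sequence-region", readLines(gff_path, n = 200L),
                value = TRUE)
    if (!length(hdr))
      stop("chromosome lengths missing from ", gff_path,
           "; pass chrom_lengths=", call. = FALSE)
    parts <- strsplit(hdr, "[ \t]+")
    chrom_lengths <- setNames(
      vapply(parts, function(p) as.integer(p[4]), integer(1)),
      vapply(parts, function(p) p[2], ""))
  }
  m <- S4Vectors::mcols(gff)
  is_gene <- m$type == "gene"
  genes <- data.frame(
    gene_id = as.character(m$ID[is_gene]),
    chrom = as.character(GenomeInfoDb::seqnames(gff)[is_gene]),
    start = GenomicRanges::start(gff)[is_gene] - 1L,
    end = GenomicRanges::end(gff)[is_gene],
    strand = as.character(GenomicRanges::strand(gff)[is_gene]),
    labels = as.character(m$labels[is_gene]),
    stringsAsFactors = FALSE)
  genes$labels[is.na(genes$labels)] <- ""
  is_ex <- m$type == "exon"
  parent <- m$Parent[is_ex]
  parent <- vapply(as.list(parent), function(p) as.character(p)[1], "")
  exons <- data.frame(
    gene_id = parent,
    chrom = as.character(GenomeInfoDb::seqnames(gff)[is_ex]),
    start = GenomicRanges::start(gff)[is_ex] - 1L,
    end = GenomicRanges::end(gff)[is_ex],
    strand = as.character(GenomicRanges::strand(gff)[is_ex]),
    stringsAsFactors = FALSE)

  read_bed6p <- function(path, extra) {
    if (file.size(path) == 0L) {
      df <- data.frame(chrom = character(), start = integer(),
                       end = integer(), name = character(), score = integer(),
                       strand = character(), x = character(),
                       stringsAsFactors = FALSE)
      names(df)[7] <- extra
      return(df)
    }
    df <- tryCatch(
      read.table(path, sep = "\t", stringsAsFactors = FALSE,
                 col.names = c("chrom", "start", "end", "name", "score",
                               "strand", extra)),
      error = function(e) stop("parse error in ", path, ": ",
                               conditionMessage(e), call. = FALSE))
    df
  }
  plb <- read_bed6p(pirna_bed_path, "kind")
  pirna_loci <- data.frame(
    locus_id = plb$name, chrom = plb$chrom,
    u5_pos = five_prime_end(plb$start, plb$end, plb$strand),
    strand = plb$strand, kind = plb$kind, stringsAsFactors = FALSE)
  teb <- read_bed6p(te_bed_path, "family")
  te_copies <- data.frame(te_id = teb$name, family = teb$family,
                          chrom = teb$chrom, start = teb$start, end = teb$end,
                          strand = teb$strand, stringsAsFactors = FALSE)
  annotation_set(genes = genes[order(genes$gene_id), , drop = FALSE],
                 exons = exons, pirna_loci = pirna_loci,
                 te_copies = te_copies, chrom_lengths = chrom_lengths)
}

#' Write aligned reads as BED6+ (extra columns: multiplicity, assay,
#' fraction, genotype, sequence)
#'
#' @param reads an `aligned_reads` table.
#' @param path output BED file.
#' @export
write_reads_bed <- function(reads, path) {
  df <- data.frame(chrom = reads$chrom, start = reads$start, end = reads$end,
                   name = reads$read_id, score = 0L, strand = reads$strand,
                   multiplicity = reads$multiplicity, assay = reads$assay,
                   fraction = reads$fraction, genotype = reads$genotype,
                   sequence = ifelse(is.na(reads$sequence), ".",
                                     reads$sequence))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read aligned reads from BED6 or BED6+
#'
#' A minimal 6-column BED defaults to multiplicity 1, assay `smallRNA`,
#' fraction `none`, genotype `wildtype` and no sequence. Validation failures
#' report the file and record.
#'
#' @param path BED file as written by [write_reads_bed()] (or plain BED6).
#' @return an `aligned_reads` table.
#' @export
read_reads <- function(path) {
  df <- tryCatch(read.table(path, sep = "\t", stringsAsFactors = FALSE),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  nc <- ncol(df)
  if (nc < 6L)
    stop("parse error in ", path, ": expected >= 6 BED columns, found ", nc,
         call. = FALSE)
  full <- c("chrom", "start", "end", "read_id", "score", "strand",
            "multiplicity", "assay", "fraction", "genotype", "sequence")
  names(df) <- full[seq_len(nc)]
  if (nc < 7L) df$multiplicity <- 1L
  if (nc < 8L) df$assay <- "smallRNA"
  if (nc < 9L) df$fraction <- "none"
  if (nc < 10L) df$genotype <- "wildtype"
  if (nc < 11L) df$sequence <- NA_character_
  df$sequence[df$sequence == "."] <- NA_character_
  out <- df[, c("read_id", "chrom", "start", "end", "strand", "multiplicity",
                "assay", "fraction", "genotype", "sequence")]
  tryCatch(validate_reads(out, where = path),
           error = function(e) stop(conditionMessage(e), call. = FALSE))
}

#' @rdname formats
#' @param cm a [count_matrix()].
#' @export
write_counts_tsv <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm$counts), length = cm$lengths,
                   cm$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname formats
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(m) <- df$feature_id
  count_matrix(m, lengths = setNames(df$length, df$feature_id))
}

#' @rdname formats
#' @param df any data frame.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname formats
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname formats
#' @param gr a GRanges with a `score` column.
#' @export
write_bedgraph <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname formats
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' @rdname formats
#' @param img numeric matrix of intensities.
#' @param max_value full-scale intensity mapped to 16-bit white.
#' @export
write_image_tiff <- function(img, path, max_value = 65535) {
  scaled <- img / max_value
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname formats
#' @export
read_image_tiff <- function(path, max_value = 65535) {
  round(tiff::readTIFF(path) * max_value)
}

#' Length-window filter on read length
#'
#' Keeps reads whose length lies in `[min_len, max_len]`; the semantics of
#' the standard adapter-trimming size selection applied to already-trimmed
#' alignments.
#'
#' @param reads an `aligned_reads` table.
#' @param min_len,max_len inclusive bounds in nt.
#' @export
filter_length_window <- function(reads, min_len = 14L, max_len = 32L) {
  len <- reads$end - reads$start
  reads[len >= min_len & len <= max_len, , drop = FALSE]
}
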