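#' Classify small-RNA reads by length and 5' base
#'
#' The classification is a pure function of read length and the 5' base on
#' the read's own strand: 21 nt with a 5' U (T in DNA space) is a mature
#' piRNA (`piRNA_21U`); 22 nt with a 5' G is a secondary siRNA
#' (`siRNA_22G`); everything else is `other`. When a read carries no
#' sequence, the 5' base is read off the genome at the strand-aware 5' end
#' (complemented for minus-strand reads).
#'
#' @param reads an `aligned_reads` table.
#' @param genome optional [Biostrings::DNAStringSet]; required for reads
#'   without a sequence.
#' @return character vector: `"piRNA_21U"`, `"siRNA_22G"` or `"other"`.
#' @export
classify_reads <- function(reads, genome = NULL) {
  len <- reads$end - reads$start
  base5 <- rep(NA_character_, nrow(reads))
  has_seq <- !is.na(reads$sequence)
  base5[has_seq] <- substr(reads$sequence[has_seq], 1L, 1L)
  if (any(!has_seq)) {
    if (is.null(genome))
      stop("reads without sequence require a genome to determine the 5' base",
           call. = FALSE)
    i <- which(!has_seq)
    p5 <- five_prime_end(reads$start[i], reads$end[i], reads$strand[i])
    ref <- vapply(seq_along(i), function(k)
      as.character(Biostrings::subseq(genome[[reads$chrom[i[k]]]],
                                      p5[k] + 1L, p5[k] + 1L)), "")
    neg <- reads$strand[i] == "-"
    ref[neg] <- comp_base(ref[neg])
    base5[i] <- ref
  }
  out <- rep("other", nrow(reads))
  out[len == 21L & base5 %in% c("T", "U")] <- "piRNA_21U"
  out[len == 22L & base5 == "G"] <- "siRNA_22G"
  out
}

#' Fractional antisense counting over gene exons
#'
#' A read placement overlapping at least 1 bp of an exon on the strand
#' opposite the gene contributes `1/multiplicity` to that gene; a placement
#' hitting exons of several genes contributes the fraction to each of them;
#' sense placements contribute nothing. This mirrors fractional multimapper
#' counting with reverse-stranded exon-level assignment.
#'
#' @param reads an `aligned_reads` table.
#' @param ann an `annotation_set`.
#' @param class_filter optional class name (see [classify_reads()]); when
#'   given, only reads of that class are counted.
#' @param genome genome for classification of sequence-less reads.
#' @return named numeric vector of fractional counts, one entry per gene
#'   (zeros included).
#' @export
count_antisense <- function(reads, ann, class_filter = NULL, genome = NULL) {
  if (!is.null(class_filter)) {
    cls <- classify_reads(reads, genome)
    reads <- reads[cls == class_filter, , drop = FALSE]
  }
  out <- setNames(numeric(nrow(ann$genes)), ann$genes$gene_id)
  if (!nrow(reads)) return(out)
  gr_reads <- reads_granges(reads)
  gr_ex <- exons_granges(ann)
  # antisense: flip the read strand, then require same-strand overlap
  flipped <- gr_reads
  GenomicRanges::strand(flipped) <-
    ifelse(as.character(GenomicRanges::strand(gr_reads)) == "+", "-", "+")
  hits <- GenomicRanges::findOverlaps(flipped, gr_ex, minoverlap = 1L)
  if (!length(hits)) return(out)
  pair <- unique(data.frame(
    read = S4Vectors::queryHits(hits),
    gene = gr_ex$gene_id[S4Vectors::subjectHits(hits)]))
  w <- 1 / reads$multiplicity[pair$read]
  agg <- tapply(w, pair$gene, sum)
  out[names(agg)] <- agg
  out
}

#' Construct a count matrix with feature lengths
#'
#' @param counts numeric matrix, features x samples, fractional counts >= 0.
#' @param lengths named numeric vector of feature lengths in bp (exonic
#'   length for genes).
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts)))
    stop("counts must have feature ids as rownames", call. = FALSE)
  lengths <- lengths[rownames(counts)]
  structure(list(counts = counts, lengths = lengths), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " features x ", ncol(x$counts),
      " samples\n", sep = "")
  invisible(x)
}

#' Library-size and length normalization
#'
#' RPM scales each sample to one million counted reads; TPM first divides by
#' feature length in kb, then scales the rates to one million. With
#' `pseudo = TRUE`, 1 is added to the *normalized* value (never to the raw
#' counts), the convention used before log transformation to avoid zeros.
#'
#' @param cm a [count_matrix()].
#' @param mode `"TPM"` or `"RPM"`.
#' @param pseudo add 1 to the normalized values.
#' @return numeric matrix of the same shape as `cm$counts`.
#' @export
normalize_counts <- function(cm, mode = c("TPM", "RPM"), pseudo = FALSE) {
  mode <- match.arg(mode)
  counts <- cm$counts
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[totals == 0], collapse = ", "), call. = FALSE)
  if (mode == "RPM") {
    out <- sweep(counts, 2, totals, "/") * 1e6
  } else {
    if (is.null(cm$lengths) || anyNA(cm$lengths))
      stop("TPM requires feature lengths", call. = FALSE)
    rate <- counts / (cm$lengths / 1000)
    out <- sweep(rate, 2, colSums(rate), "/") * 1e6
  }
  if (pseudo) out <- out + 1
  out
}
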