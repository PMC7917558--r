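#' Construct and validate an annotation set
#'
#' The container for gene models (with exons and free-form labels), piRNA
#' loci (with annotated 5'U position and motif class) and transposon copies.
#' All coordinates are internal convention: 0-based half-open.
#'
#' @param genes data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and optionally `labels` (comma-separated tags such as
#'   `germline`, `piRNA_target`, `HRDE1_target`, `CSR1_target`).
#' @param exons data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`; every exon must lie within its gene span.
#' @param pirna_loci data frame with columns `locus_id`, `chrom`, `u5_pos`,
#'   `strand`, `kind` (`motif_dependent` or `motif_independent`).
#' @param te_copies data frame with columns `te_id`, `family`, `chrom`,
#'   `start`, `end`, `strand`.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(genes, exons, pirna_loci, te_copies,
                           chrom_lengths) {
  if (is.null(genes$labels)) genes$labels <- rep("", nrow(genes))
  ann <- structure(list(genes = genes, exons = exons,
                        pirna_loci = pirna_loci, te_copies = te_copies,
                        chrom_lengths = chrom_lengths),
                   class = "annotation_set")
  validate_annotation_set(ann)
}

validate_annotation_set <- function(ann) {
  g <- ann$genes
  if (anyDuplicated(g$gene_id))
    stop("annotation_set: duplicate gene ids", call. = FALSE)
  if (nrow(ann$pirna_loci) && anyDuplicated(ann$pirna_loci$locus_id))
    stop("annotation_set: duplicate piRNA locus ids", call. = FALSE)
  if (any(g$end <= g$start))
    stop("annotation_set: gene end must exceed start", call. = FALSE)
  ex <- ann$exons
  if (nrow(ex)) {
    m <- match(ex$gene_id, g$gene_id)
    if (anyNA(m))
      stop("annotation_set: exon references unknown gene", call. = FALSE)
    if (any(ex$start < g$start[m] | ex$end > g$end[m]))
      stop("annotation_set: exon outside its gene span", call. = FALSE)
  }
  pl <- ann$pirna_loci
  if (nrow(pl)) {
    cl <- ann$chrom_lengths[pl$chrom]
    if (anyNA(cl) || any(pl$u5_pos < 0L) || any(pl$u5_pos >= cl))
      stop("annotation_set: piRNA 5'U position outside its chromosome",
           call. = FALSE)
    if (!all(pl$kind %in% c("motif_dependent", "motif_independent")))
      stop("annotation_set: unknown piRNA locus kind", call. = FALSE)
  }
  ann
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set: ", nrow(x$genes), " genes (", nrow(x$exons),
      " exons), ", nrow(x$pirna_loci), " piRNA loci, ",
      nrow(x$te_copies), " TE copies on ", length(x$chrom_lengths),
      " chromosome(s)\n", sep = "")
  invisible(x)
}

# GRanges view of exons (1-based closed, as GenomicRanges expects)
exons_granges <- function(ann) {
  ex <- ann$exons
  GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = ex$strand, gene_id = ex$gene_id)
}

reads_granges <- function(reads) {
  GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = reads$start + 1L, end = reads$end),
    strand = reads$strand)
}

#' Genes carrying a given annotation label
#'
#' @param ann an `annotation_set`.
#' @param label a single label, e.g. `"piRNA_target"`.
#' @return character vector of gene ids.
#' @export
genes_with_label <- function(ann, label) {
  has <- vapply(strsplit(ann$genes$labels, ","), function(l) label %in% l,
                logical(1))
  ann$genes$gene_id[has]
}
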