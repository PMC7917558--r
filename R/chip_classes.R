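#' Mean log2 fold enrichment over gene bodies
#'
#' Arithmetic per-base mean of a log2 fold-enrichment track over each gene's
#' full span (introns included). Genes with any uncovered base get `NA` and
#' the number of such genes is reported as an attribute.
#'
#' @param track a GRanges with a `score` column (e.g. from
#'   [make_chip_tracks()] or [read_bedgraph()]).
#' @param ann an `annotation_set`.
#' @param genes optional character vector restricting to these gene ids.
#' @return named numeric vector of per-gene means (NA where uncovered), with
#'   attribute `n_uncovered`.
#' @export
gene_body_enrichment <- function(track, ann, genes = NULL) {
  g <- ann$genes
  if (!is.null(genes)) g <- g[g$gene_id %in% genes, , drop = FALSE]
  gr_g <- GenomicRanges::GRanges(g$chrom,
                                 IRanges::IRanges(g$start + 1L, g$end))
  hits <- GenomicRanges::findOverlaps(gr_g, track, ignore.strand = TRUE)
  out <- setNames(rep(NA_real_, nrow(g)), g$gene_id)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::pintersect(IRanges::ranges(gr_g)[qh],
                              IRanges::ranges(track)[sh])
    w <- IRanges::width(ov)
    sc <- track$score[sh]
    sums <- tapply(w * sc, qh, sum)
    covs <- tapply(w, qh, sum)
    idx <- as.integer(names(sums))
    full <- covs == IRanges::width(gr_g)[idx]
    out[idx[full]] <- sums[full] / covs[full]
  }
  attr(out, "n_uncovered") <- sum(is.na(out))
  out
}

#' Assign Pol II binding classes by the 1.5x gene-body enrichment rule
#'
#' Class I where the mutant mean log2 fold enrichment is at least
#' `ratio` times the wild-type mean; class III where it is at most the
#' wild-type mean divided by `ratio`; class II otherwise. The ratio rule is
#' applied directly on the log2-scale means. Genes with a non-positive
#' wild-type mean (ratio undefined) or a missing mean are reported as
#' unclassifiable.
#'
#' @param mut_means,wt_means named numeric vectors on the same genes.
#' @param ratio class boundary multiplier (default 1.5).
#' @return object of class `polii_classes`: list with `class` (named factor
#'   I/II/III), `unclassifiable` (gene ids) and the input means.
#' @export
assign_classes <- function(mut_means, wt_means, ratio = 1.5) {
  stopifnot(identical(names(mut_means), names(wt_means)))
  bad <- is.na(wt_means) | is.na(mut_means) | wt_means <= 0
  cls <- rep(NA_character_, length(wt_means))
  ok <- !bad
  cls[ok & mut_means >= ratio * wt_means] <- "I"
  cls[ok & mut_means <= wt_means / ratio] <- "III"
  cls[ok & is.na(cls)] <- "II"
  structure(list(
    class = setNames(factor(cls[ok], levels = c("I", "II", "III")),
                     names(wt_means)[ok]),
    unclassifiable = names(wt_means)[bad],
    mut_means = mut_means, wt_means = wt_means, ratio = ratio),
    class = "polii_classes")
}

#' @export
print.polii_classes <- function(x, ...) {
  tb <- table(x$class)
  cat("Pol II classes (ratio ", x$ratio, "): ",
      paste(names(tb), tb, sep = "=", collapse = ", "),
      "; unclassifiable: ", length(x$unclassifiable), "\n", sep = "")
  invisible(x)
}

#' Mann-Whitney U test of mutant vs wild-type means within a class
#'
#' Two-sided rank-sum comparison of the per-gene mutant and wild-type
#' gene-body means restricted to one class. All-tied inputs give p = 1.
#'
#' @param classes a [assign_classes()] result.
#' @param class one of `"I"`, `"II"`, `"III"`.
#' @return list with `p_value`, `statistic` and `n`.
#' @export
class_group_test <- function(classes, class = c("I", "II", "III")) {
  class <- match.arg(class)
  ids <- names(classes$class)[classes$class == class]
  if (length(ids) < 2L)
    stop("fewer than 2 genes in class ", class, call. = FALSE)
  a <- classes$wt_means[ids]; b <- classes$mut_means[ids]
  if (all(a == b) || (length(unique(c(a, b))) == 1L))
    return(list(p_value = 1, statistic = length(a) * length(b) / 2,
                n = length(ids)))
  wt <- suppressWarnings(wilcox.test(b, a, alternative = "two.sided"))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(p_value = min(1, p), statistic = unname(wt$statistic), n = length(ids))
}
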