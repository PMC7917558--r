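#' Call differential expression by threshold
#'
#' A feature is `up` when log2FC > `lfc` and adjusted p < `alpha`, `down`
#' when log2FC < -`lfc` and adjusted p < `alpha`, `ns` otherwise (the
#' conventional |log2FC| > 1 and adjusted P < 0.01 thresholds by default).
#'
#' @param de data frame with columns `feature_id`, `log2FC` and `padj`.
#' @param lfc log2 fold-change threshold.
#' @param alpha adjusted-p threshold.
#' @return the input with an added `direction` factor (`up`/`down`/`ns`).
#' @export
call_deg <- function(de, lfc = 1, alpha = 0.01) {
  if (is.null(de$padj) || anyNA(de$padj))
    stop("adjusted p-values ('padj') are required", call. = FALSE)
  dir <- rep("ns", nrow(de))
  dir[de$log2FC > lfc & de$padj < alpha] <- "up"
  dir[de$log2FC < -lfc & de$padj < alpha] <- "down"
  de$direction <- factor(dir, levels = c("up", "down", "ns"))
  de
}

#' Summary of a called DE table
#'
#' @param de a [call_deg()] result.
#' @return list with counts of up/down/total deregulated features and their
#'   percentage shares of the deregulated total, truncated (not rounded) to
#'   two decimals so the two shares never exceed 100 jointly.
#' @export
deg_summary <- function(de) {
  up <- sum(de$direction == "up"); down <- sum(de$direction == "down")
  tot <- up + down
  pct <- function(x) trunc(1e4 * x / tot) / 100
  list(n_up = up, n_down = down, n_deregulated = tot,
       pct_up = if (tot) pct(up) else NA_real_,
       pct_down = if (tot) pct(down) else NA_real_)
}

#' Filter upregulated transposons overlapping upregulated gene exons
#'
#' Removes every upregulated TE whose span overlaps (>= 1 bp) any exon of
#' any statistically significant upregulated gene - these TE calls are
#' explained by the host gene's own upregulation. Intron-only overlap, or
#' overlap with non-upregulated genes, does not remove a TE.
#'
#' @param te_up character vector of upregulated TE ids.
#' @param gene_up character vector of upregulated gene ids.
#' @param ann an `annotation_set`.
#' @return the retained TE ids.
#' @export
filter_te_upregulation <- function(te_up, gene_up, ann) {
  te <- ann$te_copies[ann$te_copies$te_id %in% te_up, , drop = FALSE]
  ex <- ann$exons[ann$exons$gene_id %in% gene_up, , drop = FALSE]
  if (!nrow(te) || !nrow(ex)) return(te$te_id)
  gr_te <- GenomicRanges::GRanges(te$chrom,
                                  IRanges::IRanges(te$start + 1L, te$end))
  gr_ex <- GenomicRanges::GRanges(ex$chrom,
                                  IRanges::IRanges(ex$start + 1L, ex$end))
  hit <- GenomicRanges::countOverlaps(gr_te, gr_ex,
                                      ignore.strand = TRUE) > 0L
  te$te_id[!hit]
}

#' Gene-set overlap statistics
#'
#' Exact hypergeometric upper-tail probability P(X >= k) of observing at
#' least the actual overlap between two sets drawn from a common universe,
#' and the representation factor k / (n1 * n2 / N), the observed overlap
#' relative to the expectation under independence.
#'
#' @param set1,set2 character vectors (subsets of `universe`).
#' @param universe character vector of all features tested.
#' @return list: `n1`, `n2`, `N`, `k`, `expected`, `representation_factor`,
#'   `p_value`.
#' @export
overlap_stats <- function(set1, set2, universe) {
  N <- length(unique(universe))
  if (N == 0L) stop("empty universe", call. = FALSE)
  s1 <- unique(intersect(set1, universe))
  s2 <- unique(intersect(set2, universe))
  n1 <- length(s1); n2 <- length(s2)
  k <- length(intersect(s1, s2))
  expected <- n1 * n2 / N
  rf <- if (expected > 0) k / expected else NA_real_
  p <- phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
  list(n1 = n1, n2 = n2, N = N, k = k, expected = expected,
       representation_factor = rf, p_value = p)
}

#' Shared deregulated features between two called DE tables
#'
#' @param de1,de2 [call_deg()] results on a shared universe.
#' @return list: `shared_up`, `shared_down`, `total`.
#' @export
shared_deg <- function(de1, de2) {
  up1 <- de1$feature_id[de1$direction == "up"]
  up2 <- de2$feature_id[de2$direction == "up"]
  dn1 <- de1$feature_id[de1$direction == "down"]
  dn2 <- de2$feature_id[de2$direction == "down"]
  su <- length(intersect(up1, up2))
  sd_ <- length(intersect(dn1, dn2))
  list(shared_up = su, shared_down = sd_, total = su + sd_)
}
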