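#' Equal-occupancy density binning
#'
#' Features are sorted by ascending density (ties broken lexicographically by
#' id) and cut into `n_bins` contiguous blocks of size floor(N/B) or
#' ceiling(N/B), the larger blocks assigned to the lowest-density bins first,
#' so occupancies never differ by more than one. Bin labels are `A`, `B`, ...
#' from lowest to highest density (zero-padded `bin01`-style labels beyond
#' 26 bins).
#'
#' @param density named numeric vector (e.g. antisense 22G TPM per gene).
#' @param n_bins number of bins.
#' @return object of class `bin_assignment`: list with `assignment` (named
#'   factor feature -> bin), `occupancy` (per-bin counts) and `n_bins`.
#' @export
assign_bins <- function(density, n_bins) {
  if (n_bins < 1L) stop("n_bins must be >= 1", call. = FALSE)
  n <- length(density)
  if (n < n_bins)
    stop("fewer features (", n, ") than bins (", n_bins, ")", call. = FALSE)
  if (is.null(names(density))) names(density) <- as.character(seq_len(n))
  ord <- order(density, names(density))
  sizes <- rep(n %/% n_bins, n_bins)
  r <- n %% n_bins
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  labels <- if (n_bins <= 26L) LETTERS[seq_len(n_bins)] else
    sprintf("bin%03d", seq_len(n_bins))
  assignment <- factor(rep(labels, sizes), levels = labels)
  names(assignment) <- names(density)[ord]
  assignment <- assignment[names(density)]  # original feature order
  structure(list(assignment = assignment,
                 occupancy = setNames(sizes, labels),
                 n_bins = n_bins),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat("bin_assignment: ", length(x$assignment), " features in ", x$n_bins,
      " bins (occupancy ", min(x$occupancy), "-", max(x$occupancy), ")\n",
      sep = "")
  invisible(x)
}

#' Per-bin expression summaries and genotype comparison
#'
#' For each bin, computes the median and quartiles of per-feature expression
#' in each genotype and a two-sample t-test comparing genotypes (pooled
#' variance by default, the plain "two-sample t-test"; Welch available).
#' Expression is expected on a log scale with the pseudo-count policy already
#' applied (e.g. `log2(TPM + 1)`).
#'
#' @param bins a [assign_bins()] result.
#' @param expr named list of two numeric vectors (one per genotype), each
#'   indexed by feature id.
#' @param var_equal pooled-variance t-test when `TRUE` (default), Welch
#'   otherwise.
#' @return data frame with one row per bin and genotype-wise summaries plus
#'   the per-bin p-value (`NA` where a bin holds fewer than two features).
#' @export
bin_expression_summary <- function(bins, expr, var_equal = TRUE) {
  stopifnot(length(expr) == 2L, !is.null(names(expr)))
  gnames <- names(expr)
  feats <- names(bins$assignment)
  lv <- levels(bins$assignment)
  out <- lapply(lv, function(b) {
    ids <- feats[bins$assignment == b]
    a <- expr[[1]][ids]; bb <- expr[[2]][ids]
    p <- if (length(ids) < 2L) NA_real_
    else if (isTRUE(all.equal(a, bb)) ||
             (sd(a) == 0 && sd(bb) == 0 && mean(a) == mean(bb))) 1
    else t.test(a, bb, var.equal = var_equal)$p.value
    data.frame(bin = b, n = length(ids),
               median_1 = median(a), q25_1 = unname(quantile(a, 0.25)),
               q75_1 = unname(quantile(a, 0.75)), mean_1 = mean(a),
               median_2 = median(bb), q25_2 = unname(quantile(bb, 0.25)),
               q75_2 = unname(quantile(bb, 0.75)), mean_2 = mean(bb),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  names(out) <- sub("_1$", paste0("_", gnames[1]), names(out))
  names(out) <- sub("_2$", paste0("_", gnames[2]), names(out))
  out
}

#' Distribution of feature sets across bins
#'
#' For each set and bin, the proportion of the set's members falling in the
#' bin; rows sum to 1. Empty sets give an all-zero row and are flagged.
#'
#' @param bins a [assign_bins()] result.
#' @param sets named list of feature-id vectors (subsets of the binned
#'   features).
#' @return matrix sets x bins of proportions, with attribute `empty_sets`.
#' @export
bin_set_composition <- function(bins, sets) {
  lv <- levels(bins$assignment)
  feats <- names(bins$assignment)
  out <- matrix(0, length(sets), length(lv),
                dimnames = list(names(sets), lv))
  empty <- character(0)
  for (s in names(sets)) {
    ids <- intersect(sets[[s]], feats)
    if (!length(ids)) { empty <- c(empty, s); next }
    tab <- table(bins$assignment[ids])
    out[s, names(tab)] <- as.numeric(tab) / length(ids)
  }
  attr(out, "empty_sets") <- empty
  out
}
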