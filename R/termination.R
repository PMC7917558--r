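#' Assign capped reads to piRNA loci and collect precursor lengths
#'
#' A capped read is assigned to a locus when its strand matches and its
#' strand-aware 5' end lies within `assign_window` nt of the locus 5'U site;
#' a read assignable to several loci goes to the nearest 5'U, ties broken
#' toward the lower genomic coordinate. Lengths are collected separately per
#' locus kind (motif-dependent / motif-independent) and per fraction.
#'
#' @param reads an `aligned_reads` table with `assay == "capped"`.
#' @param ann an `annotation_set`.
#' @param assign_window maximum |5' end - 5'U| distance in nt.
#' @return named list `kind.fraction` -> integer vector of read lengths.
#' @export
extract_precursors <- function(reads, ann, assign_window = 25L) {
  reads <- reads[reads$assay == "capped", , drop = FALSE]
  pl <- ann$pirna_loci
  empty <- list()
  if (!nrow(reads) || !nrow(pl)) return(empty)
  p5 <- five_prime_end(reads$start, reads$end, reads$strand)
  len <- reads$end - reads$start
  assigned_kind <- rep(NA_character_, nrow(reads))
  for (i in seq_len(nrow(reads))) {
    cand <- which(pl$chrom == reads$chrom[i] & pl$strand == reads$strand[i] &
                    abs(pl$u5_pos - p5[i]) <= assign_window)
    if (!length(cand)) next
    d <- abs(pl$u5_pos[cand] - p5[i])
    cand <- cand[order(d, pl$u5_pos[cand])]
    assigned_kind[i] <- pl$kind[cand[1L]]
  }
  keep <- !is.na(assigned_kind)
  key <- paste(assigned_kind[keep], reads$fraction[keep], sep = ".")
  split(len[keep], key)
}

#' Bootstrap bimodal peak estimation of a length distribution
#'
#' Repeatedly subsamples the lengths without replacement, builds a 1-nt
#' histogram, smooths it with a centred moving average, finds local maxima
#' and keeps the two highest-count maxima separated by at least
#' `min_separation` nt (ties broken toward the smaller length). Reports the
#' per-subsample (lower, upper) peak pair and their medians. A unimodal
#' subsample reports its single peak as the lower peak and `NA` for the
#' upper.
#'
#' @param lengths integer vector of precursor lengths (nt).
#' @param n_subsamples number of subsamples.
#' @param subsample_size sequences per subsample, drawn without replacement;
#'   must not exceed `length(lengths)`.
#' @param seed RNG seed for the subsampling.
#' @param smooth_window centred moving-average window (odd, default 3).
#' @param min_separation minimal peak separation in nt.
#' @return object of class `peak_estimate`: list with `peaks` (data frame
#'   lower/upper per subsample), `median_lower`, `median_upper` and the
#'   parameters used.
#' @export
estimate_peaks <- function(lengths, n_subsamples = 2000L,
                           subsample_size = 5000L, seed = 1L,
                           smooth_window = 3L, min_separation = 8L) {
  lengths <- as.integer(lengths)
  if (any(lengths < 1L)) stop("lengths must be >= 1", call. = FALSE)
  n <- length(lengths)
  if (n < subsample_size)
    stop("only ", n, " lengths available; subsampling without replacement ",
         "needs at least subsample_size = ", subsample_size,
         " - use a smaller subsample_size", call. = FALSE)
  set.seed(seed)
  rmin <- min(lengths); rmax <- max(lengths)
  nb <- rmax - rmin + 1L
  lower <- numeric(n_subsamples); upper <- numeric(n_subsamples)
  for (s in seq_len(n_subsamples)) {
    sub <- lengths[sample.int(n, subsample_size)]
    counts <- tabulate(sub - rmin + 1L, nbins = nb)
    pk <- find_two_peaks(counts, smooth_window, min_separation)
    lower[s] <- if (is.na(pk[1L])) NA else pk[1L] + rmin - 1L
    upper[s] <- if (is.na(pk[2L])) NA else pk[2L] + rmin - 1L
  }
  structure(list(
    peaks = data.frame(lower = lower, upper = upper),
    median_lower = median(lower, na.rm = TRUE),
    median_upper = if (all(is.na(upper))) NA_real_ else
      median(upper, na.rm = TRUE),
    n_subsamples = n_subsamples, subsample_size = subsample_size,
    smooth_window = smooth_window, min_separation = min_separation),
    class = "peak_estimate")
}

#' @export
print.peak_estimate <- function(x, ...) {
  cat("peak_estimate: median peaks (", x$median_lower, ", ", x$median_upper,
      ") nt over ", x$n_subsamples, " subsamples of ", x$subsample_size,
      "\n", sep = "")
  invisible(x)
}

# two highest smoothed local maxima separated by >= min_separation bins;
# returns 1-based bin indices (lower, upper), upper NA when unimodal
find_two_peaks <- function(counts, smooth_window = 3L, min_separation = 8L) {
  nb <- length(counts)
  half <- smooth_window %/% 2L
  s <- vapply(seq_len(nb), function(i) {
    w <- max(1L, i - half):min(nb, i + half)
    mean(counts[w])
  }, numeric(1))
  is_max <- vapply(seq_len(nb), function(i) {
    left <- if (i > 1L) s[i] >= s[i - 1L] else TRUE
    right <- if (i < nb) s[i] >= s[i + 1L] else TRUE
    left && right && s[i] > 0
  }, logical(1))
  cand <- which(is_max)
  if (!length(cand)) return(c(NA_integer_, NA_integer_))
  cand <- cand[order(-s[cand], cand)]  # highest first, ties to smaller length
  p1 <- cand[1L]
  rest <- cand[abs(cand - p1) >= min_separation]
  if (!length(rest)) return(c(p1, NA_integer_))
  p2 <- rest[1L]
  c(min(p1, p2), max(p1, p2))
}

#' Median length shift between two distributions
#'
#' `median(b) - median(a)`, with a percentile confidence interval built from
#' per-subsample median differences (subsampling without replacement).
#'
#' @param a,b integer length vectors.
#' @param n_subsamples number of subsamples.
#' @param subsample_size per-subsample size; defaults to 80% of the smaller
#'   input.
#' @param seed RNG seed.
#' @param conf confidence level of the percentile interval.
#' @return list with `shift`, `ci` (two quantiles) and `shifts`.
#' @export
median_shift <- function(a, b, n_subsamples = 1000L, subsample_size = NULL,
                         seed = 1L, conf = 0.95) {
  if (!length(a) || !length(b)) stop("both inputs must be non-empty",
                                     call. = FALSE)
  if (is.null(subsample_size))
    subsample_size <- max(1L, as.integer(0.8 * min(length(a), length(b))))
  set.seed(seed)
  shifts <- vapply(seq_len(n_subsamples), function(i)
    median(b[sample.int(length(b), subsample_size)]) -
      median(a[sample.int(length(a), subsample_size)]), numeric(1))
  alpha <- (1 - conf) / 2
  list(shift = median(b) - median(a),
       ci = unname(quantile(shifts, c(alpha, 1 - alpha))),
       shifts = shifts)
}

#' Aggregate capped-read 5' ends relative to 5'U sites
#'
#' For every motif-dependent locus, counts strand-matched read 5' ends at
#' each signed offset within a window centred on the 5'U site (negative =
#' upstream of the 5'U in the transcription direction, regardless of genomic
#' strand) and sums the per-locus profiles.
#'
#' @param reads an `aligned_reads` table with capped reads.
#' @param ann an `annotation_set`.
#' @param window total window width in bp (even); offsets span
#'   `[-window/2, +window/2]`.
#' @return data frame `offset`, `count`.
#' @export
offset_profile <- function(reads, ann, window = 50L) {
  if (window <= 0L || window %% 2L != 0L)
    stop("window must be a positive even width", call. = FALSE)
  half <- window %/% 2L
  reads <- reads[reads$assay == "capped", , drop = FALSE]
  pl <- ann$pirna_loci[ann$pirna_loci$kind == "motif_dependent", , drop = FALSE]
  offsets <- (-half):half
  count <- setNames(numeric(length(offsets)), offsets)
  if (nrow(reads) && nrow(pl)) {
    p5 <- five_prime_end(reads$start, reads$end, reads$strand)
    for (i in seq_len(nrow(pl))) {
      j <- which(reads$chrom == pl$chrom[i] & reads$strand == pl$strand[i])
      if (!length(j)) next
      off <- if (pl$strand[i] == "+") p5[j] - pl$u5_pos[i] else
        pl$u5_pos[i] - p5[j]
      off <- off[off >= -half & off <= half]
      if (length(off)) {
        tb <- table(off)
        count[names(tb)] <- count[names(tb)] + as.numeric(tb)
      }
    }
  }
  data.frame(offset = offsets, count = unname(count))
}

#' Positional profile of 5'-monophosphate cleavage fragments
#'
#' Uses uniquely mapped (multiplicity 1) monoP reads. Reads longer than
#' `min_len_filter` nt whose 5' end sits exactly on an annotated piRNA 5'U
#' site (strand-matched) are removed - these are mature piRNA contaminants,
#' not cleavage fragments. The remaining 5' ends are histogrammed relative
#' to each motif-dependent locus TSS (defined as 5'U - 2 in the
#' transcription direction) and normalized to reads per million mapped.
#'
#' @param reads an `aligned_reads` table with `assay == "monoP"`.
#' @param ann an `annotation_set`.
#' @param min_len_filter reads longer than this that initiate at a 5'U are
#'   discarded (default 15 nt).
#' @param range integer pair: positions relative to the TSS to report.
#' @return data frame `position`, `count`, `rpm`, with attributes
#'   `n_mapped` and `n_retained`.
#' @export
cleavage_profile <- function(reads, ann, min_len_filter = 15L,
                             range = c(-25L, 75L)) {
  reads <- reads[reads$assay == "monoP" & reads$multiplicity == 1L, ,
                 drop = FALSE]
  n_mapped <- nrow(reads)
  if (n_mapped == 0L) stop("no mapped 5'-monophosphate reads", call. = FALSE)
  pl <- ann$pirna_loci
  p5 <- five_prime_end(reads$start, reads$end, reads$strand)
  len <- reads$end - reads$start
  at_u5 <- rep(FALSE, nrow(reads))
  if (nrow(pl)) {
    key_reads <- paste(reads$chrom, reads$strand, p5)
    key_loci <- paste(pl$chrom, pl$strand, pl$u5_pos)
    at_u5 <- key_reads %in% key_loci
  }
  keep <- !(at_u5 & len > min_len_filter)
  reads <- reads[keep, , drop = FALSE]; p5 <- p5[keep]

  md <- pl[pl$kind == "motif_dependent", , drop = FALSE]
  positions <- range[1]:range[2]
  count <- setNames(numeric(length(positions)), positions)
  for (i in seq_len(nrow(md))) {
    j <- which(reads$chrom == md$chrom[i] & reads$strand == md$strand[i])
    if (!length(j)) next
    tss <- if (md$strand[i] == "+") md$u5_pos[i] - 2L else md$u5_pos[i] + 2L
    rel <- if (md$strand[i] == "+") p5[j] - tss else tss - p5[j]
    rel <- rel[rel >= range[1] & rel <= range[2]]
    if (length(rel)) {
      tb <- table(rel)
      count[names(tb)] <- count[names(tb)] + as.numeric(tb)
    }
  }
  out <- data.frame(position = positions, count = unname(count),
                    rpm = unname(count) * 1e6 / n_mapped)
  attr(out, "n_mapped") <- n_mapped
  attr(out, "n_retained") <- sum(count)
  out
}
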