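#' Mismatch-tolerant antisense piRNA target scan
#'
#' Slides the reverse complement of each piRNA along every target sequence
#' (ungapped) and reports every window whose Hamming distance is at most
#' `k_max`. Ambiguous bases (anything outside A/C/G/T, e.g. N) always count
#' as mismatches. The naive O(n*m) scan is the reference implementation;
#' inputs are desk-scale (piRNA complements vs transcript or TE consensus
#' sequences).
#'
#' @param pirnas named character vector of piRNA sequences (DNA alphabet,
#'   21 nt each).
#' @param targets named character vector of target sequences.
#' @param k_max maximum number of mismatches (default 3).
#' @return data frame of hits: `pirna_id`, `target_id`, `pos` (0-based
#'   target-relative window start), `mismatches`, `strand` (always `"+"`:
#'   the window is reported on the target's forward sequence; the piRNA
#'   pairs with it in antisense).
#' @export
scan_targets <- function(pirnas, targets, k_max = 3L) {
  stopifnot(!is.null(names(pirnas)), !is.null(names(targets)))
  if (any(nchar(pirnas) != 21L))
    stop("piRNA sequences must be 21 nt", call. = FALSE)
  rc <- revcomp(pirnas)
  valid <- c("A", "C", "G", "T")
  hits <- list()
  tchars <- lapply(targets, function(t) strsplit(t, "")[[1]])
  for (pi in seq_along(rc)) {
    p <- strsplit(rc[pi], "")[[1]]
    p_ok <- p %in% valid
    for (ti in seq_along(targets)) {
      tc <- tchars[[ti]]
      L <- length(tc)
      if (L < 21L) next
      nw <- L - 20L
      mm <- integer(nw)
      for (j in 1:21) {
        seg <- tc[j:(nw + j - 1L)]
        mm <- mm + !(seg == p[j] & p_ok[j] & seg %in% valid)
      }
      ok <- which(mm <= k_max)
      if (length(ok))
        hits[[length(hits) + 1L]] <- data.frame(
          pirna_id = names(pirnas)[pi], target_id = names(targets)[ti],
          pos = ok - 1L, mismatches = mm[ok], strand = "+",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(pirna_id = character(), target_id = character(),
                      pos = integer(), mismatches = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Cumulative per-family piRNA match counts
#'
#' For each target family, counts distinct piRNAs whose minimal mismatch
#' level against any member of the family is <= k, for k = 0..3. Counts are
#' cumulative (non-decreasing in k); a piRNA contributes once per family at
#' its minimal mismatch level.
#'
#' @param hits hit table from [scan_targets()] (computed with `k_max >= 3`).
#' @param families named character vector mapping `target_id` -> family.
#' @return data frame: family, `k0`..`k3` cumulative counts.
#' @export
cumulative_match_table <- function(hits, families) {
  fams <- sort(unique(families))
  out <- data.frame(family = fams, k0 = 0L, k1 = 0L, k2 = 0L, k3 = 0L,
                    stringsAsFactors = FALSE)
  if (nrow(hits)) {
    hits$family <- families[hits$target_id]
    minmm <- stats::aggregate(mismatches ~ pirna_id + family, data = hits,
                              FUN = min)
    for (k in 0:3) {
      cnt <- table(minmm$family[minmm$mismatches <= k])
      out[[paste0("k", k)]] <- as.integer(cnt[out$family])
      out[[paste0("k", k)]][is.na(out[[paste0("k", k)]])] <- 0L
    }
  }
  out
}
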