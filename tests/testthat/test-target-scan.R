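# independent reverse complement for the oracle
rc <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = ""), "", USE.NAMES = FALSE)
}

test_that("scan_targets finds perfect and mismatched antisense sites", {
  pirna <- c(p1 = paste0("T", strrep("ACG", 6), "GG"))  # 21 nt
  site <- rc(pirna)  # the target window a perfect antisense match needs
  target <- c(t1 = paste0("AAAA", site, "CCCC"))
  hits <- scan_targets(pirna, target)
  perfect <- hits[hits$mismatches == 0, ]
  expect_equal(nrow(perfect), 1L)
  expect_equal(perfect$pos, 4L)
  expect_equal(perfect$strand, "+")
  # one substitution in the site -> exactly one mismatch at the same pos
  site1 <- site
  substr(site1, 10, 10) <- if (substr(site1, 10, 10) == "A") "C" else "A"
  hits1 <- scan_targets(pirna, c(t1 = paste0("AAAA", site1, "CCCC")))
  expect_equal(hits1$mismatches[hits1$pos == 4L], 1L)
  # k_max filters
  expect_equal(nrow(scan_targets(pirna,
                                 c(t1 = paste0("AAAA", site1, "CCCC")),
                                 k_max = 0L)), 0L)
})

test_that("ambiguous bases count as mismatches and short targets are skipped", {
  pirna <- c(p1 = paste0("T", strrep("A", 20)))
  siteN <- rc(pirna)
  substr(siteN, 5, 5) <- "N"
  hits <- scan_targets(pirna, c(t1 = siteN), k_max = 3L)
  expect_equal(hits$mismatches, 1L)
  expect_equal(nrow(scan_targets(pirna, c(short = strrep("A", 20)))), 0L)
  expect_error(scan_targets(c(p = strrep("A", 20)), c(t = strrep("A", 30))),
               "21 nt")
})

test_that("scan_targets matches a brute-force oracle on random sequences", {
  set.seed(99)
  alph <- c("A", "C", "G", "T")
  pirnas <- setNames(
    vapply(1:4, function(i) paste(sample(alph, 21, TRUE), collapse = ""), ""),
    paste0("p", 1:4))
  targets <- setNames(
    vapply(1:3, function(i) paste(sample(c(alph, "N"), 120, TRUE,
                                         prob = c(rep(0.24, 4), 0.04)),
                                  collapse = ""), ""),
    paste0("t", 1:3))
  got <- scan_targets(pirnas, targets, k_max = 3L)
  oracle <- list()
  for (pn in names(pirnas)) {
    q <- strsplit(rc(pirnas[[pn]]), "")[[1]]
    for (tn in names(targets)) {
      tc <- strsplit(targets[[tn]], "")[[1]]
      for (pos in 0:(length(tc) - 21L)) {
        w <- tc[(pos + 1):(pos + 21)]
        mm <- sum(w != q | !(w %in% alph) | !(q %in% alph))
        if (mm <= 3L)
          oracle[[length(oracle) + 1L]] <- data.frame(
            pirna_id = pn, target_id = tn, pos = pos, mismatches = mm,
            strand = "+", stringsAsFactors = FALSE)
      }
    }
  }
  oracle <- if (length(oracle)) do.call(rbind, oracle) else got[0, ]
  key <- function(df) {
    df <- df[order(df$pirna_id, df$target_id, df$pos), ]
    rownames(df) <- NULL
    df
  }
  expect_equal(key(got), key(oracle))
})

test_that("planted TE target sites are recovered by the scan", {
  cfg <- tiny_cfg(te_target_frac = 1)
  gen <- make_genome(cfg)
  pl <- gen$ann$pirna_loci
  te <- gen$ann$te_copies
  getseq <- function(chrom, start, end, strand) {
    s <- as.character(Biostrings::subseq(gen$genome[[chrom]],
                                         start + 1L, end))
    if (strand == "-")
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    s
  }
  pirnas <- setNames(vapply(seq_len(nrow(pl)), function(i)
    getseq(pl$chrom[i],
           if (pl$strand[i] == "+") pl$u5_pos[i] else pl$u5_pos[i] - 20L,
           if (pl$strand[i] == "+") pl$u5_pos[i] + 21L else pl$u5_pos[i] + 1L,
           pl$strand[i]), ""), pl$locus_id)
  targets <- setNames(vapply(seq_len(nrow(te)), function(i)
    getseq(te$chrom[i], te$start[i], te$end[i], te$strand[i]), ""),
    te$te_id)
  hits <- scan_targets(pirnas, targets, k_max = 3L)
  # every TE received a planted site with at most 3 substitutions
  expect_setequal(unique(hits$target_id), te$te_id)
  mt <- cumulative_match_table(hits, setNames(te$family, te$te_id))
  expect_gte(sum(mt$k3), nrow(te))
})

test_that("cumulative match counts are per-family minima, cumulative in k", {
  hits <- data.frame(
    pirna_id = c("p1", "p1", "p1", "p2", "p2"),
    target_id = c("t1", "t2", "t3", "t1", "t3"),
    pos = 0L,
    mismatches = c(0L, 2L, 1L, 3L, 0L),
    strand = "+", stringsAsFactors = FALSE)
  fam <- c(t1 = "famA", t2 = "famA", t3 = "famB")
  mt <- cumulative_match_table(hits, fam)
  mt <- mt[order(mt$family), ]
  # famA: p1 min 0 (t1), p2 min 3 -> k0 = 1 ... k3 = 2
  expect_equal(unlist(mt[mt$family == "famA", c("k0", "k1", "k2", "k3")],
                      use.names = FALSE), c(1L, 1L, 1L, 2L))
  # famB: p1 min 1, p2 min 0
  expect_equal(unlist(mt[mt$family == "famB", c("k0", "k1", "k2", "k3")],
                      use.names = FALSE), c(1L, 2L, 2L, 2L))
  # cumulative: non-decreasing across k for every family
  expect_true(all(apply(mt[, c("k0", "k1", "k2", "k3")], 1,
                        function(x) all(diff(x) >= 0))))
  # empty hit table gives zero counts for every family
  mt0 <- cumulative_match_table(hits[0, ], fam)
  expect_true(all(mt0[, c("k0", "k1", "k2", "k3")] == 0L))
})
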