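test_that("extract_precursors assigns by strand, window and nearest 5'U", {
  ann <- toy_annotation()  # p1: +, u5 400, motif_dependent; p2: -, u5 900
  r <- aligned_reads(
    paste0("r", 1:5), "chrT",
    start = c(398L, 430L, 398L, 874L, 700L),
    end = c(424L, 475L, 424L, 901L, 726L),
    strand = c("+", "+", "-", "-", "+"),
    assay = "capped", fraction = "chromatin")
  # r1: 5' end 398, 2 nt from p1 -> assigned (len 26)
  # r2: 5' end 430, 30 nt away -> outside the 25-nt window, dropped
  # r3: minus strand, no minus locus nearby -> dropped
  # r4: minus, 5' end 900 = p2 -> assigned (len 27)
  # r5: 5' end 700, no locus within 25 -> dropped
  out <- extract_precursors(r, ann)
  expect_equal(out$motif_dependent.chromatin, 26L)
  expect_equal(out$motif_independent.chromatin, 27L)
  # non-capped assays are ignored
  r2 <- r; r2$assay <- "smallRNA"
  expect_equal(length(extract_precursors(r2, ann)), 0L)
})

test_that("ties between equidistant loci resolve to the lower coordinate", {
  ann <- annotation_set(
    genes = data.frame(gene_id = "g", chrom = "chrT", start = 0L, end = 50L,
                       strand = "+", labels = "", stringsAsFactors = FALSE),
    exons = data.frame(gene_id = "g", chrom = "chrT", start = 0L, end = 50L,
                       strand = "+", stringsAsFactors = FALSE),
    pirna_loci = data.frame(
      locus_id = c("lo", "hi"), chrom = "chrT", u5_pos = c(400L, 420L),
      strand = "+", kind = c("motif_dependent", "motif_independent"),
      stringsAsFactors = FALSE),
    te_copies = data.frame(te_id = character(), family = character(),
                           chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           stringsAsFactors = FALSE),
    chrom_lengths = c(chrT = 1000L))
  # 5' end 410: 10 nt from both loci -> goes to the lower coordinate (lo)
  r <- aligned_reads("r1", "chrT", 410L, 436L, "+", assay = "capped")
  out <- extract_precursors(r, ann)
  expect_equal(names(out), "motif_dependent.none")
})

test_that("estimate_peaks recovers a clean bimodal distribution exactly", {
  lengths <- rep(c(26L, 45L), c(1200L, 800L))
  pk <- estimate_peaks(lengths, n_subsamples = 50L, subsample_size = 500L,
                       seed = 3L)
  expect_s3_class(pk, "peak_estimate")
  expect_equal(pk$median_lower, 26)
  expect_equal(pk$median_upper, 45)
  expect_true(all(pk$peaks$lower == 26))
  expect_true(all(pk$peaks$upper == 45))
})

test_that("estimate_peaks handles unimodal input and guards its inputs", {
  pk <- estimate_peaks(rep(30L, 1000L), n_subsamples = 10L,
                       subsample_size = 100L)
  expect_equal(pk$median_lower, 30)
  expect_true(is.na(pk$median_upper))
  expect_error(estimate_peaks(rep(30L, 10L), n_subsamples = 5L,
                              subsample_size = 100L), "subsample_size")
  expect_error(estimate_peaks(c(0L, 30L), n_subsamples = 1L,
                              subsample_size = 1L), ">= 1")
})

test_that("peaks closer than the separation floor collapse to one", {
  # two modes 5 nt apart (< 8): the estimator must report a single peak
  lengths <- rep(c(26L, 31L), each = 1000L)
  pk <- estimate_peaks(lengths, n_subsamples = 20L, subsample_size = 400L)
  expect_true(all(is.na(pk$peaks$upper)))
})

test_that("median_shift recovers a known location shift", {
  set.seed(1)
  a <- as.integer(round(rnorm(4000, 26, 1.5)))
  b <- a + 2L
  ms <- median_shift(a, b, n_subsamples = 200L, seed = 2L)
  expect_equal(ms$shift, 2)
  expect_true(ms$ci[1] <= 2 && ms$ci[2] >= 2)
  expect_error(median_shift(integer(0), b), "non-empty")
})

test_that("offset_profile counts 5' ends upstream as negative on both strands", {
  ann <- toy_annotation()  # motif-dependent locus p1: +, u5 400
  # plus-strand reads at offsets -2 (x2) and +1; minus reads ignored for p1
  r <- aligned_reads(
    paste0("c", 1:4), "chrT",
    start = c(398L, 398L, 401L, 380L),
    end = c(424L, 430L, 427L, 406L),
    strand = c("+", "+", "+", "-"),
    assay = "capped")
  prof <- offset_profile(r, ann, window = 10L)
  expect_equal(prof$offset, -5:5)
  expect_equal(prof$count[prof$offset == -2], 2)
  expect_equal(prof$count[prof$offset == 1], 1)
  expect_equal(sum(prof$count), 3)
  # a minus-strand motif-dependent locus: upstream is still negative
  ann2 <- toy_annotation()
  ann2$pirna_loci$kind <- c("motif_independent", "motif_dependent")
  # p2: -, u5 900; read with 5' end at 902 is 2 nt upstream
  r2 <- aligned_reads("m1", "chrT", 877L, 903L, "-", assay = "capped")
  prof2 <- offset_profile(r2, ann2, window = 10L)
  expect_equal(prof2$count[prof2$offset == -2], 1)
  expect_error(offset_profile(r2, ann2, window = 7L), "even")
})

test_that("cleavage_profile filters mature contaminants and normalizes", {
  ann <- toy_annotation()  # p1: +, u5 400 -> TSS 398
  r <- aligned_reads(
    paste0("f", 1:5), "chrT",
    start = c(436L, 436L, 400L, 400L, 420L),
    end = c(456L, 457L, 421L, 414L, 440L),
    strand = "+",
    multiplicity = c(1L, 1L, 1L, 1L, 2L),
    assay = "monoP")
  # f1, f2: 5' ends at +38 from TSS -> counted
  # f3: 21 nt initiating exactly at the 5'U -> contaminant, removed
  # f4: 14 nt at the 5'U (<= 15 nt) -> kept, position +2
  # f5: multimapper -> excluded before anything else
  prof <- cleavage_profile(r, ann)
  expect_equal(attr(prof, "n_mapped"), 4L)
  expect_equal(attr(prof, "n_retained"), 3)
  expect_equal(prof$count[prof$position == 38], 2)
  expect_equal(prof$count[prof$position == 2], 1)
  # rpm uses the mapped total (4), not the retained total
  expect_equal(prof$rpm[prof$position == 38], 2 * 1e6 / 4)
  expect_error(cleavage_profile(r[r$assay != "monoP", ], ann), "no mapped")
})

test_that("cleavage_profile places the TSS 2 nt upstream on minus loci", {
  ann <- toy_annotation()
  ann$pirna_loci$kind <- c("motif_independent", "motif_dependent")
  # p2: -, u5 900 -> TSS 902; a 5' end at 902 - 38 = 864 sits at +38
  r <- aligned_reads("f1", "chrT", 845L, 865L, "-", assay = "monoP")
  prof <- cleavage_profile(r, ann)
  expect_equal(prof$position[prof$count == 1], 38)
})
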