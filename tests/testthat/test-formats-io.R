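test_that("five_prime_end follows the strand-aware convention", {
  expect_equal(five_prime_end(10L, 31L, "+"), 10L)
  expect_equal(five_prime_end(10L, 31L, "-"), 30L)
  expect_equal(five_prime_end(c(0L, 5L), c(21L, 27L), c("+", "-")),
               c(0L, 26L))
})

test_that("genome FASTA round-trips", {
  fx <- tiny_fixture()
  path <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(fx$gen$genome, path)
  back <- read_genome_fasta(path)
  expect_identical(names(back), names(fx$gen$genome))
  expect_identical(as.character(back), as.character(fx$gen$genome))
})

test_that("annotations round-trip through GFF3 + BED", {
  fx <- tiny_fixture()
  d <- withr::local_tempdir()
  gff <- file.path(d, "ann.gff3")
  pb <- file.path(d, "pirna.bed")
  tb <- file.path(d, "te.bed")
  write_annotations(fx$gen$ann, gff, pb, tb)
  back <- read_annotations(gff, pb, tb)
  a <- fx$gen$ann
  norm <- function(df, key) {
    df <- df[do.call(order, df[key]), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  expect_equal(norm(back$genes, "gene_id"), norm(a$genes, "gene_id"))
  expect_equal(norm(back$exons, c("gene_id", "start")),
               norm(a$exons, c("gene_id", "start")))
  expect_equal(norm(back$pirna_loci, "locus_id"),
               norm(a$pirna_loci, "locus_id"))
  expect_equal(norm(back$te_copies, "te_id"), norm(a$te_copies, "te_id"))
  expect_equal(back$chrom_lengths[names(a$chrom_lengths)], a$chrom_lengths)
})

test_that("empty piRNA/TE annotation tables round-trip", {
  ann <- annotation_set(
    genes = data.frame(gene_id = "g1", chrom = "chrT", start = 0L,
                       end = 100L, strand = "+", labels = "",
                       stringsAsFactors = FALSE),
    exons = data.frame(gene_id = "g1", chrom = "chrT", start = 0L,
                       end = 100L, strand = "+", stringsAsFactors = FALSE),
    pirna_loci = data.frame(locus_id = character(), chrom = character(),
                            u5_pos = integer(), strand = character(),
                            kind = character(), stringsAsFactors = FALSE),
    te_copies = data.frame(te_id = character(), family = character(),
                           chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           stringsAsFactors = FALSE),
    chrom_lengths = c(chrT = 1000L))
  d <- withr::local_tempdir()
  write_annotations(ann, file.path(d, "a.gff3"), file.path(d, "p.bed"),
                    file.path(d, "t.bed"))
  back <- read_annotations(file.path(d, "a.gff3"), file.path(d, "p.bed"),
                           file.path(d, "t.bed"))
  expect_equal(nrow(back$pirna_loci), 0L)
  expect_equal(nrow(back$te_copies), 0L)
  expect_equal(back$genes$gene_id, "g1")
})

test_that("read tables round-trip through BED6+, including NA sequences", {
  r <- aligned_reads(
    read_id = c("r1", "r2", "r3"), chrom = "chrT",
    start = c(0L, 10L, 20L), end = c(21L, 32L, 45L),
    strand = c("+", "-", "+"), multiplicity = c(1L, 2L, 1L),
    assay = c("smallRNA", "capped", "monoP"),
    fraction = c("none", "chromatin", "none"),
    genotype = c("wildtype", "mutant", "rescue"),
    sequence = c(strrep("A", 21), NA, strrep("G", 25)))
  path <- withr::local_tempfile(fileext = ".bed")
  write_reads_bed(r, path)
  back <- read_reads(path)
  expect_equal(as.data.frame(back), as.data.frame(r))
})

test_that("minimal BED6 reads get documented defaults", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrT\t5\t26\trx\t0\t+", path)
  r <- read_reads(path)
  expect_equal(r$multiplicity, 1L)
  expect_equal(r$assay, "smallRNA")
  expect_equal(r$fraction, "none")
  expect_equal(r$genotype, "wildtype")
  expect_true(is.na(r$sequence))
})

test_that("malformed read files raise errors naming the file", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrT\t5\t26", path)  # too few columns
  expect_error(read_reads(path), basename(path), fixed = TRUE)
  # invalid record: end <= start
  writeLines("chrT\t30\t26\trx\t0\t+", path)
  expect_error(read_reads(path), "end must exceed start")
  # invalid strand
  writeLines("chrT\t5\t26\trx\t0\t*", path)
  expect_error(read_reads(path), "strand")
})

test_that("count tables round-trip through TSV", {
  m <- matrix(c(1.5, 0, 3.25, 7), 2, 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  cm <- count_matrix(m, lengths = c(gA = 500, gB = 1200))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts_tsv(cm, path)
  back <- read_counts_tsv(path)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$lengths, cm$lengths)
})

test_that("bedGraph tracks round-trip", {
  gr <- GenomicRanges::GRanges("chrT",
                               IRanges::IRanges(c(1, 26), c(25, 50)),
                               score = c(1.25, -0.5))
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(gr, path)
  back <- read_bedgraph(path)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
  expect_equal(back$score, gr$score)
})

test_that("16-bit TIFF images round-trip at full scale", {
  set.seed(5)
  img <- matrix(sample(0:65535, 64 * 64, replace = TRUE), 64, 64)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(img, path)
  back <- read_image_tiff(path)
  expect_equal(back, img)
  # values above max_value clip rather than wrap
  path2 <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(matrix(c(0, 5000), 1, 2), path2, max_value = 4096)
  expect_equal(read_image_tiff(path2, max_value = 4096),
               matrix(c(0, 4096), 1, 2))
})

test_that("filter_length_window keeps the closed length interval", {
  r <- aligned_reads(paste0("r", 1:4), "chrT",
                     start = c(0L, 0L, 0L, 0L),
                     end = c(13L, 14L, 32L, 33L), strand = "+")
  kept <- filter_length_window(r, 14L, 32L)
  expect_equal(kept$read_id, c("r2", "r3"))
})
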