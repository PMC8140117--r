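test_that("BED6 peaks round-trip with validation of intervals and ids", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t160\tpk1\t0\t+",
               "chr2\t5\t15\tpk2\t0\t-",
               "chr2\t20\t30\tpk3\t0\t."), bed)
  pk <- read_peaks_bed(bed)
  expect_equal(length(pk), 3L)
  expect_equal(BiocGenerics::start(pk)[1], 101L)  # 0-based BED -> 1-based
  expect_equal(BiocGenerics::end(pk)[1], 160L)
  expect_equal(pk$peak_id, c("pk1", "pk2", "pk3"))
  expect_equal(as.character(BiocGenerics::strand(pk)),
               c("+", "-", "*"))
  out <- withr::local_tempfile(fileext = ".bed")
  write_peaks_bed(pk, out)
  rt <- read_peaks_bed(out)
  expect_identical(as.character(GenomicRanges::seqnames(rt)),
                   as.character(GenomicRanges::seqnames(pk)))
  expect_identical(IRanges::ranges(rt), IRanges::ranges(pk))
  expect_identical(rt$peak_id, pk$peak_id)

  writeLines("chr1\t160\t100\tbad\t0\t+", bed)
  expect_error(read_peaks_bed(bed), "start >= end")
  writeLines(c("chr1\t1\t5\tpk1\t0\t+", "chr1\t6\t9\tpk1\t0\t+"), bed)
  expect_error(read_peaks_bed(bed), "duplicate")
  writeLines("chr1\t1\t5", bed)
  expect_error(read_peaks_bed(bed), "6 columns")
})

test_that("GTF parsing derives UTRs and introns in transcript orientation", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  attr1 <- "gene_id \"g1\"; transcript_id \"g1.t1\";"
  # plus strand: exons [2,201],[302,501], CDS 102..401
  writeLines(c(
    sprintf("chr1\tx\texon\t2\t201\t.\t+\t.\t%s", attr1),
    sprintf("chr1\tx\texon\t302\t501\t.\t+\t.\t%s", attr1),
    sprintf("chr1\tx\tCDS\t102\t201\t.\t+\t.\t%s", attr1),
    sprintf("chr1\tx\tCDS\t302\t401\t.\t+\t.\t%s", attr1)), gtf)
  ann <- read_gtf(gtf)
  expect_equal(BiocGenerics::start(ann$five_utr), 2)
  expect_equal(BiocGenerics::end(ann$five_utr), 101)
  expect_equal(BiocGenerics::start(ann$introns), 202)
  expect_equal(BiocGenerics::end(ann$introns), 301)
  expect_equal(BiocGenerics::start(ann$three_utr), 402)
  expect_equal(BiocGenerics::end(ann$three_utr), 501)
  # partition identity: 5'UTR + CDS + 3'UTR = exonic length
  expect_equal(sum(BiocGenerics::width(ann$five_utr)) +
                 sum(BiocGenerics::width(ann$cds)) +
                 sum(BiocGenerics::width(ann$three_utr)),
               sum(BiocGenerics::width(ann$exons)))

  # minus strand: same geometry, 5'UTR flips to the high-coordinate side
  writeLines(gsub("\\+", "-", readLines(gtf)), gtf)
  annm <- read_gtf(gtf)
  expect_equal(BiocGenerics::start(annm$five_utr), 402)
  expect_equal(BiocGenerics::start(annm$three_utr), 2)

  # single-exon non-coding transcript: no CDS, UTRs or introns
  writeLines(sprintf("chr1\tx\texon\t10\t99\t.\t+\t.\t%s", attr1), gtf)
  annnc <- read_gtf(gtf)
  expect_equal(length(annnc$cds), 0L)
  expect_equal(length(annnc$introns), 0L)
  expect_equal(length(annnc$five_utr), 0L)
})

test_that("GTF write/read round-trip is the identity", {
  sim <- simulate_annotation(20, seed = 3)
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(sim$annotation, gtf)
  ann2 <- read_gtf(gtf)
  norm <- function(gr) {
    o <- order(BiocGenerics::start(gr), gr$transcript_id)
    data.frame(s = BiocGenerics::start(gr)[o], e = BiocGenerics::end(gr)[o],
               st = as.character(BiocGenerics::strand(gr))[o],
               tx = gr$transcript_id[o])
  }
  expect_equal(norm(ann2$exons), norm(sim$annotation$exons))
  expect_equal(norm(ann2$cds), norm(sim$annotation$cds))
  expect_equal(norm(ann2$introns), norm(sim$annotation$introns))
  expect_equal(norm(ann2$three_utr), norm(sim$annotation$three_utr))
})

test_that("read counting follows the >=1-base overlap rule and library sizes", {
  peaks <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 160),
                                  strand = "+")
  peaks$peak_id <- "pk1"
  reads <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(start = c(91, 156, 201), end = c(105, 200, 210)))
  res <- count_reads_in_peaks(peaks, reads, reads[0])
  expect_equal(res$peaks$count_x, 2L)
  expect_equal(res$peaks$count_y, 0L)

  # 3 peaks, 10 reads of which 7 overlap some peak -> library size 7,
  # a read spanning two peaks increments both but counts once in lib size
  peaks3 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, 301, 501), width = 50))
  peaks3$peak_id <- c("a", "b", "c")
  hits <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(110, 120, 310, 320, 330, 510, 140), width = 220))
  misses <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(1, 10, 20), width = 5))
  res3 <- count_reads_in_peaks(peaks3, c(hits, misses), hits[0])
  expect_equal(res3$lib_size_x, 7L)
  expect_true(sum(res3$peaks$count_x) > 7)  # multi-peak reads double counted

  # invariant to shuffling read and peak order
  set.seed(1)
  res_shuf <- count_reads_in_peaks(peaks3[c(2, 3, 1)],
                                   c(hits, misses)[sample(10)], hits[0])
  expect_equal(res_shuf$peaks$count_x[match(res3$peaks$peak_id,
                                            res_shuf$peaks$peak_id)],
               res3$peaks$count_x)
  expect_equal(res_shuf$lib_size_x, res3$lib_size_x)

  # unknown chromosome -> warning and skip
  with_odd <- GenomicRanges::GRanges(
    c(rep("chr1", 7), "chrZ"),
    IRanges::IRanges(start = c(110, 120, 310, 320, 330, 510, 140, 1),
                     width = c(rep(220, 7), 50)))
  expect_warning(res_skip <- count_reads_in_peaks(peaks3, with_odd, hits[0]),
                 "skipped")
  expect_equal(res_skip$lib_size_x, 7L)
  expect_equal(unname(res_skip$skipped["x"]), 1L)
})

test_that("results TSV writes scientific p-values and round-trips", {
  df <- data.frame(peak_id = c("a", "b"), x = c(1L, 2L),
                   p = c(1e-12, 0.25), q = c(2e-11, 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_tsv(df, path)
  raw <- readLines(path)
  expect_match(raw[2], "1.000000e-12", fixed = TRUE)
  back <- read_results_tsv(path)
  expect_equal(back$p, df$p)
  expect_equal(back$peak_id, df$peak_id)

  empty <- df[0, ]
  write_results_tsv(empty, path)
  expect_equal(length(readLines(path)), 1L)  # header only
})
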