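test_that("simulated annotations satisfy the gene-model invariants and are
           seed-deterministic", {
  sim <- simulate_annotation(50, seed = 1)
  ann <- sim$annotation
  # coding transcripts: UTR + CDS lengths tile the exonic length
  coding <- unique(ann$cds$transcript_id)
  for (tx in coding) {
    len <- function(gr) sum(BiocGenerics::width(gr[gr$transcript_id == tx]))
    expect_equal(len(ann$five_utr) + len(ann$cds) + len(ann$three_utr),
                 len(ann$exons))
  }
  # introns tile exactly the inter-exon gaps
  for (tx in ann$transcripts$transcript_id) {
    ex <- IRanges::ranges(ann$exons[ann$exons$transcript_id == tx])
    iv <- IRanges::ranges(ann$introns[ann$introns$transcript_id == tx])
    gaps <- IRanges::setdiff(range(ex), ex)
    expect_equal(sort(BiocGenerics::start(iv)), sort(BiocGenerics::start(gaps)))
    expect_equal(sum(BiocGenerics::width(iv)), sum(BiocGenerics::width(gaps)))
  }
  # byte-identical GTF under the same seed
  g1 <- withr::local_tempfile(); g2 <- withr::local_tempfile()
  write_gtf(sim$annotation, g1)
  write_gtf(simulate_annotation(50, seed = 1)$annotation, g2)
  expect_identical(readLines(g1), readLines(g2))
  expect_identical(as.character(sim$genome),
                   as.character(simulate_annotation(50, seed = 1)$genome))
  expect_error(simulate_annotation(0), "n_genes")
})

test_that("CLIP generator: seed determinism, Poisson limit, and trend
           self-consistency", {
  a <- simulate_clip_experiment(500, seed = 3)
  b <- simulate_clip_experiment(500, seed = 3)
  expect_identical(a$peaks$count_x, b$peaks$count_x)
  expect_identical(a$truth, b$truth)

  # phi = 0, near-constant rate: count variance ~ mean (Poisson limit)
  p0 <- simulate_clip_experiment(10000, frac_enriched = 0, phi = 0,
                                 trend = function(A) 0 * A, lib_ratio = 1,
                                 mean_count = 50, sdlog = 1e-9, min_rate = 0,
                                 seed = 4)
  expect_equal(var(p0$peaks$count_y) / mean(p0$peaks$count_y), 1,
               tolerance = 0.05)

  # with no enrichment the binned raw M follows the injected trend shape
  sim <- simulate_clip_experiment(20000, frac_enriched = 0, phi = 0.1,
                                  seed = 7)
  pk <- sim$peaks
  ma <- compute_ma(pk$count_x, pk$count_y, sim$lib_size_x, sim$lib_size_y)
  bins <- cut(ma$A, quantile(ma$A, seq(0.05, 0.95, 0.05)))
  bm <- tapply(ma$M, bins, mean)
  ba <- tapply(ma$A, bins, mean)
  tr <- default_ma_trend(ba)
  expect_lt(max(abs((bm - mean(bm)) - (tr - mean(tr)))), 0.1)
  expect_error(simulate_clip_experiment(10, frac_enriched = 1.2), "frac")
})

test_that("read realization reproduces the counts with unimodal coverage", {
  sim <- simulate_clip_experiment(50, mean_count = 40, seed = 9, reads = TRUE)
  cnt <- count_reads_in_peaks(sim$peaks, sim$reads_x, sim$reads_y)
  # every read was placed to overlap its peak
  expect_gte(cor(cnt$peaks$count_x, sim$peaks$count_x), 0.98)
  cov <- peak_coverage(sim$peaks[1], sim$reads_x)
  expect_gt(max(cov), 0)
})

test_that("stability generator: genotypes exchangeable at 0 h, archetype
           logFC by construction, seed-deterministic", {
  sim <- simulate_stability_timecourse(800, frac_stabilized = 0.2, seed = 6)
  sim2 <- simulate_stability_timecourse(800, frac_stabilized = 0.2, seed = 6)
  expect_identical(sim$counts$t0, sim2$counts$t0)
  expect_identical(sim$counts$t24, sim2$counts$t24)
  tr <- sim$truth
  grp <- sim$group
  lfc <- function(m) log2((rowMeans(m[, grp == "B"]) + 0.5) /
                            (rowMeans(m[, grp == "A"]) + 0.5))
  # late-stabilized genes show positive logFC at 24 h, none at 0 h
  late <- tr$stabilized & tr$archetype == "stabilized_24h"
  expect_gt(mean(lfc(sim$counts$t24)[late]), 0.7)
  expect_lt(abs(mean(lfc(sim$counts$t0)[late])), 0.15)
  mid <- tr$stabilized & tr$archetype == "stabilized_12h"
  expect_gt(mean(lfc(sim$counts$t12)[mid]), 0.7)
  expect_error(simulate_stability_timecourse(10, halflife_shift = 0), "positive")
})

test_that("proteomics generator controls missingness and is deterministic", {
  full <- simulate_proteomics(200, missing_rate = 0, seed = 2)
  expect_false(anyNA(full$intensities))
  a <- simulate_proteomics(200, seed = 8)
  b <- simulate_proteomics(200, seed = 8)
  expect_identical(a$intensities, b$intensities)
  # missing-not-at-random: missing cells sit at lower intensities
  m <- simulate_proteomics(2000, missing_rate = 0.2, seed = 3)$intensities
  expect_gt(mean(is.na(m)), 0.15)
  expect_error(simulate_proteomics(10, missing_rate = 1), "missing_rate")
})
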