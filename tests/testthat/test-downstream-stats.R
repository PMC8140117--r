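test_that("cpm and the three expression filters follow their definitions", {
  m <- matrix(c(10, 0), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(cpm(m, 1e6)[, 1], c(g1 = 10, g2 = 0))
  set.seed(3)
  mm <- matrix(rpois(60, 40), 10, 6,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  expect_equal(cpm(cbind(mm[, 1] * 2), sum(mm[, 1] * 2)),
               cpm(cbind(mm[, 1]), sum(mm[, 1])))

  zero <- rbind(mm, gz = 0)
  for (rule in c("cpm_median", "count_fraction", "cpm_all"))
    expect_false(filter_expressed(zero, rule)["gz"])

  # cpm_median minimum-total clause: total 14 dropped regardless of cpm
  low <- rbind(mm, gl = c(3, 3, 3, 3, 1, 1))
  expect_false(filter_expressed(low, "cpm_median")["gl"])

  # direct enumeration of the cpm_median rule on a toy matrix
  keep <- filter_expressed(mm, "cpm_median")
  thr <- 10 / median(colSums(mm)) * 1e6
  manual <- rowSums(sweep(mm, 2, colSums(mm), "/") * 1e6 >= thr) >= 4 &
    rowSums(mm) >= 15
  expect_equal(unname(keep), unname(manual))

  # count_fraction: > 10 in at least 2/3 of samples
  cf <- matrix(c(11, 11, 11, 11, 2, 2,
                 11, 11, 11, 2, 2, 2), 2, 6, byrow = TRUE,
               dimnames = list(c("hi", "lo"), NULL))
  expect_equal(unname(filter_expressed(cf, "count_fraction")), c(TRUE, FALSE))
})

test_that("BH q-values match the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})

test_that("correlation distance has the Pearson limits and invariances", {
  p <- rbind(a = 1:4, b = c(2, 4, 6, 8), c = 4:1, d = c(1, -1, 1, -1),
             e = c(1, 1, -1, -1))
  d <- correlation_distance(p)$d
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)
  expect_equal(d["d", "e"], 0.5)
  expect_equal(diag(d), rep(0, 5), ignore_attr = TRUE)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
  # affine invariance
  p2 <- p; p2["a", ] <- 5 * p["a", ] - 3
  expect_equal(correlation_distance(p2)$d, d)
  # degenerate profile flagged with uninformative distance
  pz <- rbind(p, z = rep(2, 4))
  rz <- correlation_distance(pz)
  expect_true(rz$degenerate["z"])
  expect_equal(rz$d["z", "a"], 0.5)
})

test_that("average-linkage merges match the O(n^3) brute-force oracle", {
  set.seed(17)
  x <- matrix(rnorm(24), 12, 2)
  d <- as.matrix(dist(x))
  oracle <- average_linkage_oracle(d)
  hc <- hclust(as.dist(d), method = "average")
  expect_equal(sort(hc$height), sort(oracle$heights), tolerance = 1e-12)
  # merge sets identical step by step (distinct heights -> unique order)
  sets_from_hclust <- function(hc) {
    members <- list()
    out <- list()
    for (i in seq_len(nrow(hc$merge))) {
      get <- function(v) if (v < 0) -v else members[[v]]
      members[[i]] <- sort(c(get(hc$merge[i, 1]), get(hc$merge[i, 2])))
      out[[i]] <- members[[i]]
    }
    out
  }
  expect_identical(sets_from_hclust(hc), oracle$merges)
  # partition at k = 3 agrees
  expect_equal(ari(average_linkage_cut(d, 3),
                   labels_from_partition(oracle$partitions[[3]], 12)), 1)
  expect_equal(average_linkage_cut(d, 12), 1:12, ignore_attr = TRUE)
  expect_error(average_linkage_cut(d, 13), "exceeds")
})

test_that("archetype decay profiles are recovered by correlation-distance
           clustering", {
  pr <- simulate_decay_profiles(20, noise_sd = 0.1, seed = 3)
  cl <- average_linkage_cut(correlation_distance(pr$profiles)$d, 3)
  expect_gte(ari(cl, pr$truth), 0.9)
})

test_that("one-sided Fisher equals exhaustive enumeration on all small
           populations", {
  expect_equal(fisher_one_sided(4, 4, 5, 10), 6 / 252, tolerance = 1e-12)
  expect_equal(fisher_one_sided(0, 4, 5, 10), 1)
  for (N in c(5, 8, 12)) {
    for (K in seq(0, N, by = 2)) {
      for (n in seq(1, N, by = 3)) {
        for (k in max(0, n + K - N):min(K, n)) {
          expect_equal(fisher_one_sided(k, K, n, N),
                       fisher_enum_oracle(k, K, n, N), tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(fisher_one_sided(5, 4, 5, 10), "inconsistent")
})

test_that("Pearson chi-square matches the 2x2 closed form and applies the
           expected-frequency guard", {
  even <- matrix(c(10, 10, 10, 10), 2)
  r <- chi_square_association(even)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  skew <- matrix(c(20, 10, 10, 20), 2)
  r2 <- chi_square_association(skew)
  expect_equal(r2$statistic, 20 / 3, tolerance = 1e-9)
  expect_equal(r2$p, pchisq(20 / 3, 1, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(r2$p, chisq.test(skew, correct = FALSE)$p.value,
               tolerance = 1e-12)
  r3 <- chi_square_association(matrix(c(1, 2, 9, 8), 2))
  expect_true(r3$excluded)   # expected cell 1.5 < 5
  expect_true(is.na(r3$p))
  expect_error(chi_square_association(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
})

test_that("binding-location classes follow the majority/tie rules", {
  expect_equal(binding_location_class(c(rep("exon", 3), "three_prime_utr")),
               "exon")
  expect_equal(binding_location_class(rep(c("exon", "three_prime_utr"), 2)),
               "exon_plus_other")
  expect_equal(binding_location_class(c("exon", rep("intron", 3))), "intron")
  expect_equal(binding_location_class(c("three_prime_utr", "three_prime_utr",
                                        "intron")), "three_prime_utr")
  expect_error(binding_location_class(character(0)), "no peaks")
})

test_that("feature lengths come from the longest transcript and respect the
           partition identity", {
  ann <- toy_annotation()
  fl <- feature_lengths("geneA", ann)
  expect_equal(unname(fl["transcript"]), 600)   # 200 + 400 exonic
  expect_equal(unname(fl["cds"]), 300)
  expect_equal(unname(fl["five_utr"]), 100)
  expect_equal(unname(fl["three_utr"]), 200)
  expect_equal(sum(fl[c("cds", "five_utr", "three_utr")]), fl[["transcript"]])
  # non-coding gene: all feature lengths zero
  flc <- feature_lengths("geneC", ann)
  expect_equal(unname(flc["cds"]), 0)
  expect_equal(unname(flc["transcript"]), 300)
  expect_error(feature_lengths("nope", ann), "unknown gene")
})

test_that("length comparisons: symmetric inputs are null, separated means
           are detected, equal clusters stay non-significant", {
  g <- rep(c("a", "b"), each = 20)
  x <- rep(c(5, 5), each = 20)
  r <- length_tests(x + rep(c(0.001, -0.001), 20), g)
  expect_equal(r$t$p, 0.5, tolerance = 0.2)
  set.seed(12)
  y <- c(rnorm(30, 10), rnorm(30, 20))
  r2 <- length_tests(y, rep(c("a", "b"), each = 30))
  expect_lt(r2$t$p, 1e-10)
  # 3 equal-mean clusters: Tukey pairwise p > 0.05 in >= 90% of runs
  set.seed(5)
  ok <- vapply(1:100, function(i) {
    v <- rnorm(45, 10)
    all(length_tests(v, rep(c("a", "b", "c"), each = 15))$tukey[, 4] > 0.05)
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("PCA uses the top-variance genes and conserves variance", {
  set.seed(7)
  base <- rnorm(6)
  m <- rbind(g1 = base, g2 = 2 * base + 1,
             g3 = rnorm(6, sd = 0.01), g4 = rnorm(6, sd = 0.01))
  r <- pca_qc(m, top_n = 2)
  expect_equal(r$var_explained[1], 1, tolerance = 1e-10)
  expect_setequal(r$genes_used, c("g1", "g2"))
  full <- pca_qc(matrix(rnorm(50 * 6), 50, 6,
                        dimnames = list(paste0("g", 1:50), NULL)))
  expect_equal(sum(full$var_explained), 1, tolerance = 1e-12)
  expect_equal(length(full$genes_used), 50L)  # top_n clamped
  expect_error(pca_qc(matrix(1, 5, 4)), "constant")
})

test_that("the two-group NB test is calibrated under the null and recovers
           four-fold changes", {
  set.seed(101)
  n <- 5000
  mu <- rlnorm(n, log(200), 1)
  counts <- matrix(rnbinom(n * 12, size = 1 / 0.05, mu = mu), n, 12,
                   dimnames = list(paste0("g", seq_len(n)), NULL))
  grp <- rep(c("A", "B"), each = 6)
  null_res <- nb_de_two_group(counts, grp)
  expect_gte(mean(null_res$p < 0.05), 0.03)
  expect_lte(mean(null_res$p < 0.05), 0.08)

  # identical counts across samples (equal library sizes, so offsets are
  # equal too): logFC 0, p = 1
  flat <- matrix(rep(c(7L, 40L, 1000L), 12), 3, 12,
                 dimnames = list(c("f1", "f2", "f3"), NULL))
  fr <- nb_de_two_group(flat, grp)
  expect_equal(fr$logFC, rep(0, 3))
  expect_equal(fr$p, rep(1, 3))

  de <- rep(FALSE, n); de[seq_len(n / 10)] <- TRUE
  counts2 <- counts
  counts2[de, 7:12] <- matrix(
    rnbinom(sum(de) * 6, size = 1 / 0.05, mu = 4 * mu[de]), ncol = 6)
  res <- nb_de_two_group(counts2, grp)
  expect_lt(median(res$q[de]), 0.05)
  expect_gte(mean(res$logFC[de] > 0), 0.95)
  expect_error(nb_de_two_group(counts[, 1:7], rep(c("A", "B"), c(6, 1))),
               "2 replicates")
})
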