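#' Counts per million
#'
#' @param counts Matrix of counts (genes x samples).
#' @param lib_sizes Per-column library sizes; defaults to column sums.
#' @return Matrix of CPM values.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts, 2, lib_sizes, "/") * 1e6
}

#' Expression filters
#'
#' Three named rules:
#' \describe{
#'   \item{cpm_median}{CPM at least \code{10 / median(lib sizes) * 1e6} in at least
#'     \code{min_samples} samples AND total count at least \code{min_total}.}
#'   \item{count_fraction}{raw count > \code{threshold} in at least
#'     \code{fraction} of the samples.}
#'   \item{cpm_all}{CPM at least \code{threshold} in every sample.}
#' }
#'
#' @param counts Matrix of counts (genes x samples, rownames = gene ids).
#' @param rule One of \code{"cpm_median"}, \code{"count_fraction"},
#'   \code{"cpm_all"}.
#' @param min_count,min_samples,min_total Parameters of the cpm_median rule.
#' @param threshold,fraction Parameters of the other two rules.
#' @return Logical vector (names = gene ids): \code{TRUE} for kept genes.
#' @export
filter_expressed <- function(counts,
                             rule = c("cpm_median", "count_fraction", "cpm_all"),
                             min_count = 10, min_samples = 4, min_total = 15,
                             threshold = NULL, fraction = 2 / 3) {
  rule <- match.arg(rule)
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  keep <- switch(rule,
    cpm_median = {
      cpm_thr <- min_count / stats::median(lib) * 1e6
      v <- cpm(counts, lib)
      rowSums(v >= cpm_thr) >= min_samples & rowSums(counts) >= min_total
    },
    count_fraction = {
      thr <- if (is.null(threshold)) 10 else threshold
      rowMeans(counts > thr) >= fraction
    },
    cpm_all = {
      thr <- if (is.null(threshold)) 1 else threshold
      rowSums(cpm(counts, lib) >= thr) == ncol(counts)
    })
  stats::setNames(keep, rownames(counts))
}

# group-wise NB rate MLE, vectorized over genes: counts (genes x samples in
# the group), offsets per sample; returns mu-hat and Fisher information of
# log(mu) per gene
nb_group_mu <- function(counts, offsets, phi) {
  eo <- exp(offsets)
  tot <- rowSums(counts)
  beta <- log(pmax(tot, 0.5)) - log(sum(eo))
  active <- tot > 0
  for (it in 1:50) {
    m <- exp(beta) %o% eo
    sc <- rowSums((counts - m) / (1 + phi * m))
    d1 <- -rowSums(m * (1 + phi * counts) / (1 + phi * m)^2)
    step <- pmax(pmin(sc / d1, 2), -2)
    conv <- abs(sc) < 1e-12 * (1 + tot)
    upd <- active & !conv
    if (!any(upd)) break
    beta[upd] <- beta[upd] - step[upd]
  }
  mu <- exp(beta)
  mu[!active] <- 0
  m <- mu %o% eo
  info <- rowSums(m / (1 + phi * m))
  list(mu = mu, info = info, means = m)
}

nb_matrix_loglik <- function(counts, means, phi) {
  ll <- nb_loglik(as.vector(counts), as.vector(means), phi)
  rowSums(matrix(ll, nrow = nrow(counts)))
}

#' Two-group negative-binomial differential expression test
#'
#' A deliberately simple two-group NB fit: TMM effective library sizes as
#' offsets, one common dispersion estimated by Cox-Reid adjusted profile
#' likelihood with the two group means profiled out, then a per-gene LRT of
#' the shared-mean null against group-specific means, referred to
#' \eqn{\chi^2_1}. The log2 fold change is \code{log2(mu2 / mu1)} of the
#' fitted group rates (library size absorbed by the offsets).
#'
#' @param counts Matrix (genes x samples), rownames = gene ids.
#' @param group Factor or vector with exactly two levels; the second level is
#'   the numerator of the fold change.
#' @param phi Optional fixed dispersion (estimated when \code{NULL}).
#' @return A data.frame with \code{gene_id, logFC, stat, p, q, direction}
#'   (\code{"increased"}/\code{"decreased"}/\code{"unchanged"} by logFC sign),
#'   and attribute \code{dispersion}.
#' @export
nb_de_two_group <- function(counts, group, phi = NULL) {
  counts <- as.matrix(counts)
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required")
  if (any(table(group) < 2L)) stop("each group needs at least 2 replicates")
  g1 <- group == levels(group)[1L]
  g2 <- group == levels(group)[2L]
  eff <- tmm_factors(counts)$effective_lib_sizes
  off <- log(eff)
  if (is.null(phi)) {
    apl <- function(log_phi) {
      ph <- exp(log_phi)
      f1 <- nb_group_mu(counts[, g1, drop = FALSE], off[g1], ph)
      f2 <- nb_group_mu(counts[, g2, drop = FALSE], off[g2], ph)
      ll <- nb_matrix_loglik(counts[, g1, drop = FALSE], f1$means, ph) +
        nb_matrix_loglik(counts[, g2, drop = FALSE], f2$means, ph)
      cr <- 0.5 * (log(pmax(f1$info, 1e-300)) + log(pmax(f2$info, 1e-300)))
      sum((ll - cr)[rowSums(counts) > 0])
    }
    opt <- stats::optimize(apl, c(log(1e-8), log(10)), maximum = TRUE,
                           tol = 1e-6)
    phi <- exp(opt$maximum)
    if (apl(log(1e-8)) >= opt$objective) phi <- 1e-8
  }
  f0 <- nb_group_mu(counts, off, phi)
  f1 <- nb_group_mu(counts[, g1, drop = FALSE], off[g1], phi)
  f2 <- nb_group_mu(counts[, g2, drop = FALSE], off[g2], phi)
  ll0 <- nb_matrix_loglik(counts, f0$means, phi)
  ll1 <- nb_matrix_loglik(counts[, g1, drop = FALSE], f1$means, phi) +
    nb_matrix_loglik(counts[, g2, drop = FALSE], f2$means, phi)
  stat <- pmax(2 * (ll1 - ll0), 0)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  # fold change with a half-count guard against zero groups
  tiny <- 1e-8
  logFC <- log2(pmax(f2$mu, tiny) / pmax(f1$mu, tiny))
  logFC[f1$mu == 0 & f2$mu == 0] <- 0
  p[rowSums(counts) == 0] <- 1
  q <- bh_fdr(p)
  out <- data.frame(
    gene_id = if (is.null(rownames(counts)))
      as.character(seq_len(nrow(counts))) else rownames(counts),
    logFC = logFC, stat = stat, p = p, q = q,
    direction = ifelse(logFC > 0, "increased",
                       ifelse(logFC < 0, "decreased", "unchanged")),
    stringsAsFactors = FALSE)
  attr(out, "dispersion") <- phi
  out
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted p-values with monotonicity enforcement (identical to
#' \code{p.adjust(method = "BH")}).
#'
#' @param p Vector of p-values in [0, 1].
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Correlation distance between stability profiles
#'
#' \eqn{d(i, j) = (1 - R_{ij}) / 2} with R the Pearson correlation of the
#' per-gene logFC time-course vectors; d is in [0, 1] with 0 on the diagonal.
#' Zero-variance profiles have undefined R; their distances are set to the
#' uninformative 0.5 and flagged.
#'
#' @param profiles Matrix (genes x time points) of logFC values.
#' @return A list with \code{d} (symmetric matrix) and \code{degenerate}
#'   (logical per gene).
#' @export
correlation_distance <- function(profiles) {
  profiles <- as.matrix(profiles)
  degen <- apply(profiles, 1, stats::sd) == 0
  r <- suppressWarnings(stats::cor(t(profiles)))
  d <- (1 - r) / 2
  d[is.na(d)] <- 0.5
  diag(d) <- 0
  list(d = d, degenerate = degen)
}

#' Average-linkage clustering cut into k groups
#'
#' Unweighted average (UPGMA) agglomeration on a distance matrix, cut into
#' \code{k} clusters.
#'
#' @param d Symmetric distance matrix (or \code{dist}).
#' @param k Number of clusters (default 3).
#' @return Integer cluster labels (1..k) in input order.
#' @export
average_linkage_cut <- function(d, k = 3) {
  if (!inherits(d, "dist")) d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (k > n) stop("k exceeds number of points")
  hc <- stats::hclust(d, method = "average")
  stats::cutree(hc, k = k)
}

#' One-sided Fisher (hypergeometric upper-tail) enrichment test
#'
#' \eqn{P(X \ge k)} for the overlap of a size-\code{n} draw with \code{K}
#' marked elements in a population of \code{N} — the standard
#' over-representation test of a gene set against a background universe.
#'
#' @param k Observed overlap.
#' @param K Number of marked elements (e.g. pathway genes).
#' @param n Draw size (e.g. significant genes).
#' @param N Population (background universe) size.
#' @return The one-sided p-value.
#' @export
fisher_one_sided <- function(k, K, n, N) {
  if (K > N || n > N || k > min(K, n) || k < 0)
    stop("inconsistent contingency configuration")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Pearson chi-squared association test with expected-frequency guard
#'
#' Pearson \eqn{X^2 = \sum (O - E)^2 / E} without continuity correction,
#' df = (r-1)(c-1). Tables with any expected cell below \code{min_expected}
#' return an excluded status instead of a p-value.
#'
#' @param table Matrix of non-negative integer counts (2-dimensional).
#' @param min_expected Minimum expected cell frequency (default 5).
#' @return A list with \code{statistic}, \code{df}, \code{p},
#'   \code{expected}, and \code{excluded} (logical).
#' @export
chi_square_association <- function(table, min_expected = 5) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal in contingency table")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < min_expected))
    return(list(statistic = NA_real_, df = NA_integer_, p = NA_real_,
                expected = expected, excluded = TRUE))
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected, excluded = FALSE)
}

#' Majority binding-location class of a gene
#'
#' Strict majority over the gene's peak classes; an exact tie between exon
#' and any other class gives \code{"exon_plus_other"}; 5'UTR peaks count
#' within "other".
#'
#' @param classes Character vector of peak feature classes for one gene.
#' @return One of \code{"exon"}, \code{"exon_plus_other"},
#'   \code{"three_prime_utr"}, \code{"intron"}.
#' @export
binding_location_class <- function(classes) {
  if (length(classes) == 0L) stop("gene has no peaks")
  n_exon <- sum(classes == "exon")
  n_3utr <- sum(classes == "three_prime_utr")
  n_intron <- sum(classes == "intron")
  n_other <- length(classes) - n_exon
  if (n_exon > n_other) return("exon")
  if (n_exon == n_other && n_exon > 0L) return("exon_plus_other")
  # no exon majority: majority among the rest
  if (n_3utr >= n_intron && n_3utr >= n_exon) return("three_prime_utr")
  if (n_intron > n_3utr && n_intron >= n_exon) return("intron")
  "exon_plus_other"
}

#' Feature lengths of a gene's longest transcript
#'
#' Lengths are taken from the transcript with the largest total exonic
#' length; missing features (non-coding transcripts) give 0.
#'
#' @param gene_id Gene identifier.
#' @param ann A \code{genome_annotation}.
#' @return Named numeric: \code{transcript} (total exonic length),
#'   \code{cds}, \code{three_utr}, \code{five_utr}.
#' @export
feature_lengths <- function(gene_id, ann) {
  txs <- ann$transcripts$transcript_id[ann$transcripts$gene_id == gene_id]
  if (length(txs) == 0L) stop("unknown gene: ", gene_id)
  exlen <- vapply(txs, function(tx)
    sum(BiocGenerics::width(ann$exons[ann$exons$transcript_id == tx])), 0)
  best <- txs[which.max(exlen)]
  flen <- function(gr) sum(BiocGenerics::width(gr[gr$transcript_id == best]))
  c(transcript = max(exlen), cds = flen(ann$cds),
    three_utr = flen(ann$three_utr), five_utr = flen(ann$five_utr))
}

#' Feature-length comparisons between groups and across clusters
#'
#' One-sided pooled-variance unpaired t-test between two groups, plus a
#' one-way ANOVA with Tukey HSD pairwise comparisons across clusters.
#'
#' @param lengths Numeric vector of feature lengths.
#' @param group Factor of group/cluster labels (>= 2 observations each).
#' @param alternative Direction for the two-group t-test
#'   (\code{"greater"}: second level larger).
#' @return A list with \code{t} (two-group case: statistic and one-sided p,
#'   \code{NULL} otherwise), \code{anova_p}, and \code{tukey} (matrix of
#'   pairwise adjusted p-values).
#' @export
length_tests <- function(lengths, group,
                         alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  group <- factor(group)
  if (any(table(group) < 2L)) stop("each group needs at least 2 observations")
  t_res <- NULL
  if (nlevels(group) == 2L) {
    g2 <- lengths[group == levels(group)[2L]]
    g1 <- lengths[group == levels(group)[1L]]
    tt <- stats::t.test(g2, g1, var.equal = TRUE, alternative = alternative)
    t_res <- list(statistic = unname(tt$statistic), p = tt$p.value)
  }
  fit <- stats::aov(lengths ~ group)
  an_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  tuk <- stats::TukeyHSD(fit)$group
  list(t = t_res, anova_p = an_p, tukey = tuk)
}

#' PCA on the most variable genes of a log-CPM matrix
#'
#' Genes are ranked by variance (ties broken by row name), the top
#' \code{top_n} retained, and principal components of the centered,
#' transposed matrix returned with explained-variance fractions.
#'
#' @param logcpm Matrix (genes x samples) of log-CPM values.
#' @param top_n Number of most-variable genes (clamped to the gene count).
#' @return A list with \code{scores} (samples x components),
#'   \code{var_explained} (fractions summing to 1), and \code{genes_used}.
#' @export
pca_qc <- function(logcpm, top_n = 1000) {
  logcpm <- as.matrix(logcpm)
  if (ncol(logcpm) < 2L) stop("need at least two samples")
  v <- apply(logcpm, 1, stats::var)
  if (all(v == 0)) stop("constant matrix")
  ord <- order(-v, rownames(logcpm))
  keep <- ord[seq_len(min(top_n, nrow(logcpm)))]
  pc <- stats::prcomp(t(logcpm[keep, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, var_explained = ve,
       genes_used = rownames(logcpm)[keep])
}
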