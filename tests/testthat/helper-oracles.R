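# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / closed form, never by calling the code paths
# they check.

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# grid-search MLE of the shared NB rate and the resulting LRT statistic,
# step 1e-4 in log(mu)
lrt_grid_oracle <- function(x, y, ox, oy, phi) {
  ll <- function(mu) {
    m1 <- mu * exp(ox); m2 <- mu * exp(oy)
    dnbinom(x, size = 1 / phi, mu = m1, log = TRUE) +
      dnbinom(y, size = 1 / phi, mu = m2, log = TRUE)
  }
  b0 <- log((x + y) / (exp(ox) + exp(oy)))
  grid <- exp(seq(b0 - 2, b0 + 2, by = 1e-4))
  ll_null <- max(ll(grid))
  ll_sat_x <- if (x == 0) 0 else dnbinom(x, size = 1 / phi, mu = x, log = TRUE)
  ll_sat_y <- if (y == 0) 0 else dnbinom(y, size = 1 / phi, mu = y, log = TRUE)
  max(2 * (ll_sat_x + ll_sat_y - ll_null), 0)
}

# one-sided Fisher p by exhaustive enumeration of all size-n subsets
fisher_enum_oracle <- function(k, K, n, N) {
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K)
  mean(hits >= k)
}

# per-point local linear (tricube) regression, non-robust: the reference
# evaluation for the LOESS fit
local_linear_oracle <- function(A, M, span, at) {
  n <- length(A)
  q <- max(2L, floor(span * n))
  vapply(at, function(a0) {
    d <- abs(A - a0)
    dmax <- sort(d, partial = q)[q]
    w <- pmax(1 - (d / dmax)^3, 0)^3
    use <- w > 0
    fit <- stats::lm.wfit(cbind(1, A[use] - a0), M[use], w[use])
    fit$coefficients[1L]
  }, 0)
}

# O(n^3) average-linkage agglomeration: returns merge heights and the
# partition at each k, with clusters as sorted member sets
average_linkage_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  merges <- list()
  partitions <- list()
  partitions[[n]] <- lapply(clusters, sort)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best[1] - 1e-12) best <- c(h, i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    merges[[length(merges) + 1L]] <- sort(c(clusters[[i]], clusters[[j]]))
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    partitions[[m - 1L]] <- lapply(clusters, sort)
  }
  list(heights = heights, merges = merges, partitions = partitions)
}

labels_from_partition <- function(partition, n) {
  lab <- integer(n)
  for (i in seq_along(partition)) lab[partition[[i]]] <- i
  lab
}

# direct evaluation of the TMM trimmed weighted mean for a two-column count
# matrix, following the published algorithm (reference = second column)
tmm_two_col_oracle <- function(obs, ref, lib_obs = sum(obs),
                               lib_ref = sum(ref),
                               trim_M = 0.3, trim_A = 0.05) {
  keep0 <- obs > 0 & ref > 0
  o <- obs[keep0]; r <- ref[keep0]
  M <- log2((o / lib_obs) / (r / lib_ref))
  A <- 0.5 * log2((o / lib_obs) * (r / lib_ref))
  w <- (lib_obs - o) / (lib_obs * o) + (lib_ref - r) / (lib_ref * r)
  n <- length(M)
  loL <- floor(n * trim_M) + 1; hiL <- n + 1 - loL
  loS <- floor(n * trim_A) + 1; hiS <- n + 1 - loS
  keep <- rank(M) >= loL & rank(M) <= hiL & rank(A) >= loS & rank(A) <= hiS
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}
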