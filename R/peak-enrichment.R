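# Negative-binomial likelihood machinery for the two-sample, no-replicate
# design: each peak contributes one observation per sample, both sharing a
# single rate under the null, with sample- and peak-specific offsets on the
# natural-log scale. variance = mu + phi * mu^2.

# log-likelihood; phi below ~1e-10 is treated as the Poisson limit because
# dnbinom loses accuracy for extreme size parameters
nb_loglik <- function(count, mu, phi) {
  if (phi < 1e-10) {
    ll <- stats::dpois(count, lambda = mu, log = TRUE)
  } else {
    ll <- stats::dnbinom(count, size = 1 / phi, mu = mu, log = TRUE)
  }
  # mean 0: point mass at 0 (loglik 0 for count 0, -Inf otherwise)
  zero <- mu == 0
  if (any(zero)) ll[zero] <- ifelse(count[zero] == 0, 0, -Inf)
  ll
}

# Vectorized safeguarded Newton MLE of the shared rate mu per peak.
# Score in beta = log(mu): sum_j (c_j - m_j) / (1 + phi * m_j), m_j = mu e^{o_j};
# strictly decreasing in beta, so the root is unique.
nb_null_mu <- function(x, y, ox, oy, phi) {
  tot <- x + y
  denom <- exp(ox) + exp(oy)
  beta <- log(pmax(tot, 0.5)) - log(denom)  # start near the Poisson MLE
  active <- tot > 0
  for (it in 1:50) {
    mx <- exp(beta + ox); my <- exp(beta + oy)
    sc <- (x - mx) / (1 + phi * mx) + (y - my) / (1 + phi * my)
    d1 <- -mx * (1 + phi * x) / (1 + phi * mx)^2 -
           my * (1 + phi * y) / (1 + phi * my)^2
    step <- sc / d1
    step <- pmax(pmin(step, 2), -2)  # damp huge steps far from the root
    conv <- abs(sc) < 1e-12 * (1 + tot)
    upd <- active & !conv
    if (!any(upd)) break
    beta[upd] <- beta[upd] - step[upd]
  }
  mu <- exp(beta)
  mu[!active] <- 0
  mu
}

#' Mask of peaks in the central MA cloud
#'
#' Strict window on the raw (unadjusted) M values, default \eqn{-3 < M < 1},
#' marking the bulk of unenriched peaks used to estimate the common
#' dispersion.
#'
#' @param profile A data.frame with a raw \code{M} column (e.g. an
#'   \code{\link{ma_profile}}).
#' @param lo,hi Window bounds (strict).
#' @return Logical vector, \code{TRUE} inside the window.
#' @export
center_cloud_mask <- function(profile, lo = -3, hi = 1) {
  if (lo >= hi) stop("lo must be < hi")
  M <- if (is.data.frame(profile)) profile$M else profile
  M > lo & M < hi
}

#' Common NB dispersion by Cox-Reid adjusted profile likelihood
#'
#' With no replicates, each peak supplies a pair of counts sharing one rate
#' (given their offsets); a single dispersion \eqn{\phi} is estimated across
#' peaks by maximizing the sum of per-peak profile log-likelihoods with the
#' Cox-Reid adjustment \eqn{-\tfrac12\log I(\hat\mu)} (Fisher information of
#' the profiled rate), over \eqn{\log\phi \in [\log 10^{-8}, \log 10]}.
#' Peaks with zero total count carry no information and are dropped.
#'
#' @param x,y Counts of the (typically cloud-masked) peaks.
#' @param offset_x,offset_y Natural-log offsets per peak (may be scalar).
#' @return A list with \code{phi}, \code{n_peaks_used}, and \code{at_bound}
#'   (\code{"lower"}, \code{"upper"} or \code{"no"}).
#' @export
estimate_common_dispersion <- function(x, y, offset_x = 0, offset_y = 0) {
  ox <- rep_len(offset_x, length(x))
  oy <- rep_len(offset_y, length(y))
  keep <- (x + y) > 0
  x <- x[keep]; y <- y[keep]; ox <- ox[keep]; oy <- oy[keep]
  if (length(x) < 50) stop("need at least 50 informative peaks")
  apl <- function(log_phi) {
    phi <- exp(log_phi)
    mu <- nb_null_mu(x, y, ox, oy, phi)
    mx <- mu * exp(ox); my <- mu * exp(oy)
    ll <- nb_loglik(x, mx, phi) + nb_loglik(y, my, phi)
    info <- mx / (1 + phi * mx) + my / (1 + phi * my)
    sum(ll - 0.5 * log(info))
  }
  lo <- log(1e-8); hi <- log(10)
  opt <- stats::optimize(apl, interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-6)
  phi <- exp(opt$maximum)
  at_bound <- "no"
  # optimize never returns the exact endpoints; snap when the boundary wins
  if (apl(lo) >= opt$objective) { phi <- 1e-8; at_bound <- "lower" }
  else if (apl(hi) >= opt$objective) {
    phi <- 10; at_bound <- "upper"
    warning("dispersion estimate at upper bound")
  }
  list(phi = phi, n_peaks_used = length(x), at_bound = at_bound)
}

#' Per-peak likelihood-ratio test for compartment enrichment
#'
#' Tests, for every peak, the null of a single rate generating both counts
#' (means \eqn{\mu e^{o_x}}, \eqn{\mu e^{o_y}}) against the saturated
#' alternative (fitted mean = observation), with a fixed common dispersion.
#' The LOESS correction enters through the offsets: the compartment offset is
#' \eqn{\log(L_x) - \hat M \ln 2} where \eqn{\hat M} is the fitted LOESS value
#' (log2) at the peak's A. The statistic \eqn{2(\ell_{sat} - \ell_0)} is
#' referred to \eqn{\chi^2_1}.
#'
#' @param x,y Counts.
#' @param offset_x,offset_y Natural-log offsets (scalar or per peak).
#' @param phi Common NB dispersion.
#' @return A data.frame with columns \code{stat} and \code{p}. Peaks with
#'   \code{x = y = 0} get \code{stat = 0, p = 1}.
#' @export
peak_lrt <- function(x, y, offset_x = 0, offset_y = 0, phi) {
  if (phi < 0) stop("phi must be >= 0")
  ox <- rep_len(offset_x, length(x))
  oy <- rep_len(offset_y, length(y))
  if (!all(is.finite(ox)) || !all(is.finite(oy)))
    stop("offsets must be finite")
  mu <- nb_null_mu(x, y, ox, oy, phi)
  ll_null <- nb_loglik(x, mu * exp(ox), phi) + nb_loglik(y, mu * exp(oy), phi)
  ll_sat <- nb_loglik(x, x, phi) + nb_loglik(y, y, phi)
  stat <- pmax(2 * (ll_sat - ll_null), 0)
  zero <- (x + y) == 0
  stat[zero] <- 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  data.frame(stat = stat, p = p)
}

#' Offsets for the enrichment test
#'
#' Peak-specific natural-log offsets: \code{log(effective library size)} per
#' sample, with the LOESS-fitted M (log2) converted to natural log and
#' subtracted from the reference sample's offset, so the relative offset
#' satisfies \eqn{o_x - o_y = \ln(L_x/L_y) + \hat{M}\ln 2} and a peak sitting
#' exactly on the LOESS trend is a perfect null fit. (Subtracting from the
#' compartment offset instead would flip the sign of the correction and
#' double the trend misfit; only this direction feeds the LOESS adjustment
#' into the inference.)
#'
#' @param lib_x,lib_y Effective library sizes.
#' @param fitted LOESS-fitted M per peak (log2 scale).
#' @return A list with vectors \code{offset_x} and \code{offset_y}.
#' @export
adjusted_offsets <- function(lib_x, lib_y, fitted) {
  list(offset_x = rep_len(log(lib_x), length(fitted)),
       offset_y = log(lib_y) - fitted * log(2))
}

#' Run the full enrichment test on an MA profile
#'
#' Estimates the common dispersion on the central-cloud peaks and applies the
#' per-peak LRT with LOESS-adjusted offsets.
#'
#' @param profile An \code{\link{ma_profile}}.
#' @param mask_lo,mask_hi Central-cloud window on raw M.
#' @param phi Optional fixed dispersion; estimated when \code{NULL}.
#' @return The profile with columns \code{offset_x}, \code{offset_y},
#'   \code{lrt_stat}, \code{p} added and attribute \code{dispersion}.
#' @export
enrichment_test <- function(profile, mask_lo = -3, mask_hi = 1, phi = NULL) {
  off <- adjusted_offsets(attr(profile, "lib_x"), attr(profile, "lib_y"),
                          profile$fitted)
  if (is.null(phi)) {
    mask <- center_cloud_mask(profile, mask_lo, mask_hi)
    disp <- estimate_common_dispersion(profile$x[mask], profile$y[mask],
                                       off$offset_x[mask], off$offset_y[mask])
    phi <- disp$phi
  } else {
    disp <- list(phi = phi, n_peaks_used = NA_integer_, at_bound = "no")
  }
  lrt <- peak_lrt(profile$x, profile$y, off$offset_x, off$offset_y, phi)
  profile$offset_x <- off$offset_x
  profile$offset_y <- off$offset_y
  profile$lrt_stat <- lrt$stat
  profile$p <- lrt$p
  attr(profile, "dispersion") <- disp
  profile
}

#' Select peaks below a p-value cutoff
#'
#' Ranks by p-value ascending, ties broken lexicographically by peak id, and
#' selects \code{p < cutoff} (strict).
#'
#' @param results A data.frame with \code{peak_id} and \code{p} columns.
#' @param cutoff P-value cutoff (default \code{1e-5}).
#' @return \code{results} with \code{rank} and \code{selected} columns,
#'   ordered by rank.
#' @export
select_peaks <- function(results, cutoff = 1e-5) {
  ord <- order(results$p, results$peak_id)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$selected <- out$p < cutoff
  rownames(out) <- NULL
  out
}

#' Matched-count p-value cutoff for the reverse contrast
#'
#' Returns the cutoff under which exactly \code{n_target} peaks are taken in
#' (p, peak_id) rank order — the rule used to pick a reverse-direction set of
#' the same size as the forward selection.
#'
#' @param results A data.frame with \code{peak_id} and \code{p}.
#' @param n_target Number of peaks to select (> 0).
#' @return A list with \code{cutoff} (the \code{n_target}-th smallest p) and
#'   \code{selected} (the ranked data.frame of exactly \code{n_target} rows).
#' @export
matched_count_cutoff <- function(results, n_target) {
  if (n_target <= 0) stop("n_target must be positive")
  if (n_target > nrow(results)) stop("n_target exceeds number of peaks")
  ord <- order(results$p, results$peak_id)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  sel <- out[seq_len(n_target), , drop = FALSE]
  rownames(sel) <- NULL
  list(cutoff = sel$p[n_target], selected = sel)
}
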