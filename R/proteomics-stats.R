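#' Filter proteins by peptide support and missingness
#'
#' Retains proteins identified by at least \code{min_peptides} peptides with
#' at most \code{max_missing} missing intensity cells across all samples.
#' Idempotent.
#'
#' @param intensities Matrix (proteins x samples) with \code{NA} for missing.
#' @param peptides Integer vector of peptide counts per protein.
#' @param min_peptides Minimum peptides (default 2).
#' @param max_missing Maximum missing cells (default 4).
#' @return A list with \code{intensities} and \code{peptides} of the kept
#'   proteins, plus \code{kept} (logical on the input rows).
#' @export
filter_proteins <- function(intensities, peptides, min_peptides = 2,
                            max_missing = 4) {
  intensities <- as.matrix(intensities)
  keep <- peptides >= min_peptides & rowSums(is.na(intensities)) <= max_missing
  list(intensities = intensities[keep, , drop = FALSE],
       peptides = peptides[keep], kept = keep)
}

#' Robust z-score normalization with grand-scale restoration
#'
#' Per sample, log2 intensities are standardized robustly
#' (\code{(v - median) / (1.4826 * MAD)}) and then mapped back to
#' intensity-like units with the grand location and scale (median of sample
#' medians, median of sample MADs), so fold changes remain in log2 units.
#' After normalization every sample has the same median. Missing values stay
#' missing.
#'
#' @param intensities Matrix of log2 intensities (proteins x samples),
#'   \code{NA} for missing.
#' @return The normalized matrix.
#' @export
robust_z_normalize <- function(intensities) {
  intensities <- as.matrix(intensities)
  med <- apply(intensities, 2, stats::median, na.rm = TRUE)
  mads <- apply(intensities, 2, stats::mad, na.rm = TRUE)  # 1.4826 scaled
  if (any(mads == 0)) stop("sample MAD is zero")
  z <- sweep(sweep(intensities, 2, med, "-"), 2, mads, "/")
  grand_loc <- stats::median(med)
  grand_scale <- stats::median(mads)
  z * grand_scale + grand_loc
}

#' Pooled-variance two-sample t-test on log2 intensities
#'
#' Two-sided t-test with pooled variance (df = nA + nB - 2); the fold change
#' is \code{mean(B) - mean(A)} on the log2 scale. With one group entirely
#' missing the protein should be routed to \code{\link{pseudo_fold_change}}.
#'
#' @param a,b Present (non-NA) log2 intensities of the two groups.
#' @return A list with \code{logFC}, \code{statistic}, \code{df}, \code{p}.
#' @export
pooled_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 present values per group")
  tt <- stats::t.test(b, a, var.equal = TRUE)
  list(logFC = mean(b) - mean(a), statistic = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' Pseudo fold change for an all-missing condition
#'
#' When a protein is entirely missing in one condition, its group average is
#' substituted by the mean of the lowest \code{q} fraction (default 10\%) of
#' all protein intensities observed in that condition; the fold change is the
#' observed group mean minus that substitute (direction: present group vs
#' missing group when the missing group is A).
#'
#' @param condition_intensities All observed log2 intensities in the
#'   all-missing condition (across proteins).
#' @param observed_mean Mean log2 intensity of the protein in the other
#'   condition.
#' @param missing_group \code{"A"} or \code{"B"}: which group is all-missing.
#' @param q Fraction of smallest intensities to average (default 0.10); the
#'   substitution set has size \code{max(1, floor(q * n))}.
#' @return A list with \code{logFC} (B minus A convention) and
#'   \code{substitute}.
#' @export
pseudo_fold_change <- function(condition_intensities, observed_mean,
                               missing_group = c("B", "A"), q = 0.10) {
  missing_group <- match.arg(missing_group)
  v <- sort(condition_intensities[!is.na(condition_intensities)])
  if (length(v) == 0L) stop("no observed intensities in the condition")
  m <- max(1L, floor(q * length(v)))
  substitute <- mean(v[seq_len(m)])
  fc <- if (missing_group == "B") substitute - observed_mean
        else observed_mean - substitute
  list(logFC = fc, substitute = substitute)
}

#' Full label-free proteomics differential abundance analysis
#'
#' Filters, normalizes, and tests every protein: pooled-variance t-test where
#' both groups have at least two present values; pseudo fold change where one
#' group is entirely missing; skipped (flagged) otherwise. BH-FDR across the
#' tested proteins.
#'
#' @param intensities Matrix of raw (linear) intensities, \code{NA} missing.
#' @param peptides Peptide counts per protein.
#' @param group Two-level factor over the columns (level 2 vs level 1).
#' @param min_peptides,max_missing Filter parameters.
#' @param q_pseudo Decile fraction for \code{\link{pseudo_fold_change}}.
#' @return A data.frame with \code{protein, logFC, p, q, flag} where flag is
#'   one of \code{"tested"}, \code{"pseudo_fc"}, \code{"skipped"}.
#' @export
proteomics_de <- function(intensities, peptides, group, min_peptides = 2,
                          max_missing = 4, q_pseudo = 0.10) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required")
  flt <- filter_proteins(intensities, peptides, min_peptides, max_missing)
  mat <- log2(flt$intensities)
  norm <- robust_z_normalize(mat)
  ga <- group == levels(group)[1L]
  gb <- group == levels(group)[2L]
  n <- nrow(norm)
  logFC <- rep(NA_real_, n); p <- rep(NA_real_, n)
  flag <- rep("skipped", n)
  for (i in seq_len(n)) {
    a <- norm[i, ga]; b <- norm[i, gb]
    na <- sum(!is.na(a)); nb <- sum(!is.na(b))
    if (na >= 2L && nb >= 2L) {
      r <- pooled_t_test(a, b)
      logFC[i] <- r$logFC; p[i] <- r$p; flag[i] <- "tested"
    } else if (na == 0L && nb > 0L) {
      r <- pseudo_fold_change(as.vector(norm[, ga]), mean(b, na.rm = TRUE),
                              missing_group = "A", q = q_pseudo)
      logFC[i] <- r$logFC; flag[i] <- "pseudo_fc"
    } else if (nb == 0L && na > 0L) {
      r <- pseudo_fold_change(as.vector(norm[, gb]), mean(a, na.rm = TRUE),
                              missing_group = "B", q = q_pseudo)
      logFC[i] <- r$logFC; flag[i] <- "pseudo_fc"
    }
  }
  q <- rep(NA_real_, n)
  tested <- flag == "tested"
  q[tested] <- bh_fdr(p[tested])
  data.frame(protein = rownames(norm) %||% as.character(seq_len(n)),
             logFC = logFC, p = p, q = q, flag = flag,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
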