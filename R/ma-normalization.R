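#' TMM normalization factors and effective library sizes
#'
#' Trimmed-mean-of-M-values factors between samples: per-sample scaling
#' factors such that effective library size = library size x factor. The
#' reference sample is the one whose 75th percentile of scaled counts is
#' closest to the mean of those percentiles; per-row log2 ratios against the
#' reference are trimmed (30\% on M, 5\% on A by default) and averaged with
#' inverse delta-method variance weights; factors are rescaled to geometric
#' mean 1. The computation is delegated to \code{edgeR::calcNormFactors}.
#'
#' @param counts Integer matrix (rows = peaks or genes, columns = samples).
#' @param lib_sizes Per-column library sizes; defaults to column sums.
#' @param trim_M,trim_A Trim fractions for the M and A tails.
#' @param weighted Use delta-method precision weights (default \code{TRUE}).
#' @return A list with \code{factors} (geometric mean 1) and
#'   \code{effective_lib_sizes} (= \code{lib_sizes * factors}).
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(30, 60, 90))
#' tmm_factors(m)$factors  # c(1, 1): scale absorbed by library size
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts),
                        trim_M = 0.3, trim_A = 0.05, weighted = TRUE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least two samples")
  if (any(counts < 0)) stop("negative counts")
  if (any(colSums(counts) == 0)) stop("sample with all-zero counts")
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  f <- edgeR::calcNormFactors(counts, lib.size = lib_sizes, method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A,
                              doWeighting = weighted)
  list(factors = f, effective_lib_sizes = lib_sizes * f)
}

#' Per-peak M and A statistics
#'
#' M is the library-size-adjusted log2 fold change and A the average log2
#' count, both with a pseudo-offset \code{o} guarding against zeros:
#' \deqn{M = \log_2\frac{x+o}{L_x+o} - \log_2\frac{y+o}{L_y+o}, \qquad
#'       A = \frac{\log_2(x+o) + \log_2(y+o)}{2}}
#' where \eqn{L_x, L_y} are effective library sizes. Direction
#' \code{"y_vs_x"} negates M (the reverse contrast); A is unchanged.
#'
#' @param x,y Non-negative counts (vectors of equal length).
#' @param lib_x,lib_y Effective library sizes (positive scalars).
#' @param o Offset, default 1.
#' @param direction \code{"x_vs_y"} (default) or \code{"y_vs_x"}.
#' @return A data.frame with columns \code{M} and \code{A}.
#' @examples
#' compute_ma(7, 0, 999, 999)  # M = 3, A = 1.5
#' @export
compute_ma <- function(x, y, lib_x, lib_y, o = 1,
                       direction = c("x_vs_y", "y_vs_x")) {
  direction <- match.arg(direction)
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (lib_x <= 0 || lib_y <= 0) stop("library sizes must be positive")
  if (o <= 0) stop("offset o must be positive")
  M <- log2((x + o) / (lib_x + o)) - log2((y + o) / (lib_y + o))
  if (direction == "y_vs_x") M <- -M
  A <- (log2(x + o) + log2(y + o)) / 2
  data.frame(M = M, A = A)
}

#' Robust LOESS fit of M on A
#'
#' Local linear regression of M on A with tricube weights over the
#' span-nearest neighbours, robustified by bisquare reweighting of residuals
#' (the \code{"symmetric"} family) for a fixed number of iterations. Defaults
#' reproduce \code{loess(M ~ A, span = 1/4, family = "symmetric",
#' degree = 1, iterations = 4)}.
#'
#' @param A,M Numeric vectors of equal length.
#' @param span LOESS span (fraction of points in each local window).
#' @param degree Local polynomial degree.
#' @param robust_iterations Total fitting iterations (1 initial + 3 robust
#'   reweightings when 4).
#' @return Fitted M value at every input A, in input order.
#' @export
fit_robust_loess <- function(A, M, span = 1 / 4, degree = 1,
                             robust_iterations = 4) {
  n <- length(A)
  if (length(M) != n) stop("A and M must have equal length")
  if (!all(is.finite(A))) stop("A must be finite")
  if (n < max(10, ceiling(span * n))) stop("too few points for the window")
  if (length(unique(A)) == 1L) stop("degenerate abscissa: all A identical")
  dat <- data.frame(A = A, M = M)
  # a plain local-linear fit that already interpolates the data exactly
  # (constant or globally linear M) is a fixed point of the robust
  # iterations, whose bisquare weights would be 0/0 on zero residuals
  fit0 <- stats::loess(M ~ A, span = span, degree = degree,
                       family = "gaussian", data = dat)
  if (max(abs(stats::residuals(fit0))) < 1e-8 * (1 + max(abs(M))))
    return(as.numeric(stats::predict(fit0, newdata = dat)))
  fit <- stats::loess(
    M ~ A, span = span, degree = degree, family = "symmetric",
    iterations = robust_iterations, data = dat)
  as.numeric(stats::predict(fit, newdata = dat))
}

#' Build an MA profile for a two-sample peak count table
#'
#' Convenience constructor combining \code{\link{compute_ma}},
#' \code{\link{fit_robust_loess}} and \code{\link{adjust_m}}.
#'
#' @param peak_id Peak identifiers.
#' @param x,y Counts.
#' @param lib_x,lib_y Effective library sizes.
#' @param o Offset (default 1).
#' @param direction Contrast direction, see \code{\link{compute_ma}}.
#' @param span,degree,robust_iterations LOESS parameters.
#' @return A data.frame (class \code{ma_profile}) with columns
#'   \code{peak_id, x, y, M, A, fitted, adjusted_M} and attributes
#'   \code{lib_x}, \code{lib_y}, \code{o}.
#' @export
ma_profile <- function(peak_id, x, y, lib_x, lib_y, o = 1,
                       direction = c("x_vs_y", "y_vs_x"),
                       span = 1 / 4, degree = 1, robust_iterations = 4) {
  direction <- match.arg(direction)
  ma <- compute_ma(x, y, lib_x, lib_y, o = o, direction = direction)
  prof <- data.frame(peak_id = as.character(peak_id), x = x, y = y,
                     M = ma$M, A = ma$A, stringsAsFactors = FALSE)
  prof$fitted <- fit_robust_loess(prof$A, prof$M, span = span,
                                  degree = degree,
                                  robust_iterations = robust_iterations)
  prof <- adjust_m(prof)
  attr(prof, "lib_x") <- lib_x
  attr(prof, "lib_y") <- lib_y
  attr(prof, "o") <- o
  attr(prof, "direction") <- direction
  class(prof) <- c("ma_profile", "data.frame")
  prof
}

#' Subtract the LOESS fit from M
#'
#' \code{adjusted_M = M - fitted}; after adjustment a LOESS refit on
#' \code{(A, adjusted_M)} is flat at zero, i.e. the normalized MA cloud is
#' centered.
#'
#' @param profile A data.frame with columns \code{M}, \code{A}, \code{fitted}.
#' @return The profile with an \code{adjusted_M} column.
#' @export
adjust_m <- function(profile) {
  if (is.null(profile$fitted) || anyNA(profile$fitted))
    stop("fitted values missing")
  profile$adjusted_M <- profile$M - profile$fitted
  profile
}
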