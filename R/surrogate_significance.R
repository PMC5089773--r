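#' Surrogate-data configuration
#'
#' Null distributions are built by applying an independent random circular
#' offset to the source series and recomputing the statistic. Offsets are
#' drawn uniformly over the middle of the series (default 10-90% of its
#' length) so that near-zero offsets, which would leak true coupling into
#' the null, are excluded.
#'
#' @param n_surrogates number of surrogates (>= 100 recommended for the
#'   Gaussian z approximation).
#' @param lag_range offset range as fractions of the series length.
#' @param seed integer RNG seed (`NULL` leaves the RNG state alone).
#' @return An object of class `surrogate_config`.
#' @export
surrogate_config <- function(n_surrogates = 1000, lag_range = c(0.1, 0.9),
                             seed = NULL) {
  stopifnot(n_surrogates >= 1, length(lag_range) == 2,
            lag_range[1] >= 0, lag_range[2] <= 1, lag_range[1] < lag_range[2])
  structure(list(n_surrogates = as.integer(n_surrogates),
                 lag_range = lag_range, seed = seed),
            class = "surrogate_config")
}

# random circular offsets in samples
draw_shifts <- function(config, n) {
  lo <- max(1L, floor(config$lag_range[1] * n))
  hi <- max(lo + 1L, floor(config$lag_range[2] * n))
  sample(lo:hi, config$n_surrogates, replace = TRUE)
}

#' Surrogate null distribution of a coupling statistic
#'
#' Applies `n_surrogates` independent circular offsets to the source series
#' and recomputes `estimator(shifted_source, target, ...)` each time. If the
#' estimator is invariant to the offset, the degenerate null (zero spread)
#' is flagged via attribute `"degenerate"`.
#'
#' @param estimator function of `(source, target, ...)` returning a scalar.
#' @param source,target aligned series; `source` must not be constant.
#' @param config a [surrogate_config()].
#' @param ... passed on to `estimator`.
#' @return Numeric vector of surrogate statistics, attribute `"degenerate"`
#'   set when all surrogates are identical.
#' @export
surrogate_null <- function(estimator, source, target,
                           config = surrogate_config(), ...) {
  n <- length(source)
  stopifnot(length(target) == n)
  if (length(unique(source)) == 1) stop("degenerate (constant) source series")
  if (!is.null(config$seed)) set.seed(config$seed)
  shifts <- draw_shifts(config, n)
  out <- vapply(shifts, function(tau) {
    idx <- ((seq_len(n) - 1 + tau) %% n) + 1
    estimator(source[idx], target, ...)
  }, numeric(1))
  attr(out, "degenerate") <- (max(out) - min(out)) == 0
  out
}

#' Surrogate z-score and two-sided Gaussian p-value
#'
#' `z = (stat - mean(surrogates)) / sd(surrogates)`; `p` is the two-sided
#' standard-normal tail probability.
#'
#' @param stat observed statistic.
#' @param surrogates numeric vector of surrogate statistics.
#' @return List with `z`, `p`, and the surrogate moments `mu`, `sigma`.
#' @export
z_and_p <- function(stat, surrogates) {
  mu <- mean(surrogates)
  sigma <- sd(surrogates)
  if (!is.finite(sigma) || sigma == 0) {
    stop("surrogate distribution has zero spread; z-score undefined")
  }
  z <- (stat - mu) / sigma
  list(z = z, p = 2 * pnorm(-abs(z)), mu = mu, sigma = sigma)
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up false discovery rate control over all simultaneously tested
#' p-values; returns the rejection mask.
#'
#' @param pvalues p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return Logical vector, `TRUE` where rejected.
#' @export
fdr_mask <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0) stop("empty p-value vector")
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BH") <= alpha
}

#' Significance of a single coupling statistic
#'
#' Convenience wrapper: builds the surrogate null, returns the statistic with
#' z, p and the surrogate moments.
#'
#' @inheritParams surrogate_null
#' @param stat observed statistic (computed with the same `estimator` on the
#'   unshifted series if omitted).
#' @return List with `stat`, `z`, `p`, `mu`, `sigma`, `surrogates`.
#' @export
significance_test <- function(estimator, source, target,
                              config = surrogate_config(), stat = NULL, ...) {
  if (is.null(stat)) stat <- estimator(source, target, ...)
  surr <- surrogate_null(estimator, source, target, config, ...)
  c(list(stat = stat, surrogates = surr), z_and_p(stat, surr))
}
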