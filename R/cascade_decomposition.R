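#' Exact decomposition of an indirect coupling
#'
#' For three series forming a chain `y1 -> y2 -> y3`, the lag-averaged
#' conditional transfer entropy of the indirect link decomposes exactly into
#' the two direct links plus a residual of mutual-information terms:
#' `cTE(y1 ~> y3) = cTE(y1 -> y2) + cTE(y2 -> y3) + I_residual`,
#' where `cTE(y1 ~> y3)` conditions on `(y2, y3)`, `cTE(y1 -> y2)` on
#' `(y2, y3)` and `cTE(y2 -> y3)` on `(y1, y3)`. All terms are plug-in
#' estimates on a shared discretization and common per-lag sample windows,
#' so the identity holds to machine precision by construction.
#'
#' `y1` is typically an instantaneous phase, `y3` an amplitude, and `y2` any
#' feature (phase, amplitude or instantaneous frequency) of the relay
#' population.
#'
#' @param y1,y2,y3 aligned series; numeric series are discretized with
#'   `scheme`, integer-coded series are used as is.
#' @param n_lags number of future lags averaged.
#' @param scheme a [discretization_scheme()].
#' @param circular logical length-3: which series are phases (circular
#'   binning).
#' @return Object of class `decomposition_result` with `indirect`,
#'   `direct12`, `direct23`, `residual` (bits) and `identity_gap`
#'   (`indirect - direct12 - direct23 - residual`, numerically ~0).
#' @export
decompose_indirect <- function(y1, y2, y3, n_lags = 100,
                               scheme = discretization_scheme(),
                               circular = c(FALSE, FALSE, FALSE)) {
  n <- length(y1)
  stopifnot(length(y2) == n, length(y3) == n, n_lags >= 1, n_lags < n)
  code_of <- function(y, circ) {
    if (!is.null(attr(y, "n_levels")) || is.integer(y) || is.factor(y)) {
      as_codes(y)
    } else {
      discretize_series(y, scheme, circular = circ)
    }
  }
  c1 <- code_of(y1, circular[1])
  c2 <- code_of(y2, circular[2])
  c3 <- code_of(y3, circular[3])
  mi2 <- function(a, b_list, win) {
    # MI between a and the joint of b_list over the sample window
    bl <- lapply(b_list, function(s) s[win])
    m <- combine_codes(bl)
    av <- as_codes(a[win])
    mi_disc_cpp(av - 1L, m, attr(av, "n_levels"), attr(m, "n_levels"))
  }
  ind <- d12 <- d23 <- res <- 0
  i_y2_y1y3_full <- NA_real_
  for (d in seq_len(n_lags)) {
    win <- seq_len(n - d)
    c2d <- c2[win + d]; attr(c2d, "n_levels") <- attr(c2, "n_levels")
    c3d <- c3[win + d]; attr(c3d, "n_levels") <- attr(c3, "n_levels")
    i1_23 <- mi2(c1, list(c2, c3), win)
    i2_13 <- mi2(c2, list(c1, c3), win)
    i1_233d <- mi2(c1, list(c2, c3, c3d), win)
    i1_22d3 <- mi2(c1, list(c2, c2d, c3), win)
    i2_133d <- mi2(c2, list(c1, c3, c3d), win)
    ind <- ind + (i1_233d - i1_23)
    d12 <- d12 + (i1_22d3 - i1_23)
    d23 <- d23 + (i2_133d - i2_13)
    res <- res + (i2_13 + i1_233d - i1_22d3 - i2_133d)
  }
  out <- list(indirect = ind / n_lags, direct12 = d12 / n_lags,
              direct23 = d23 / n_lags, residual = res / n_lags)
  out$identity_gap <- out$indirect -
    (out$direct12 + out$direct23 + out$residual)
  structure(out, class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf(paste0("indirect cTE = %.5f bits = direct12 (%.5f) + ",
                     "direct23 (%.5f) + residual (%.5f); gap %.2e\n"),
              x$indirect, x$direct12, x$direct23, x$residual,
              x$identity_gap))
  invisible(x)
}

# Table of the ten cascade regression models. Each predictor is
# "<TYPE>_<srcband><srcpop>_<tgtband><tgtpop>"; the relay band is delta in
# case I and beta in case II.
#' Cascade model definitions
#'
#' The ten regression models expressing the indirect coupling
#' `PAC_theta1_gamma3` as sums of direct cross- and same-frequency couplings
#' through the relay population 2 (relay band delta for case I, beta for
#' case II).
#'
#' @param case `"I"` (relay oscillates below population 1) or `"II"` (above).
#' @return Named list of character vectors of predictor names.
#' @export
cascade_models <- function(case = c("I", "II")) {
  case <- match.arg(case)
  rb <- if (case == "I") "delta" else "beta"
  th <- "theta"; gm <- "gamma"
  pred <- function(type, b1, k1, b2, k2) {
    paste0(type, "_", b1, k1, "_", b2, k2)
  }
  list(
    m1 = c(pred("PPC", th, 1, th, 2), pred("PAC", th, 2, gm, 3)),
    m2 = c(pred("PAC", th, 1, th, 2), pred("AAC", th, 2, gm, 3)),
    m3 = c(pred("PPC", th, 1, rb, 2), pred("PAC", rb, 2, gm, 3)),
    m4 = c(pred("PAC", th, 1, rb, 2), pred("AAC", rb, 2, gm, 3)),
    m5 = c(pred("PPC", th, 1, th, 2), pred("PPC", th, 2, th, 3),
           pred("PAC", th, 3, gm, 3)),
    m6 = c(pred("PPC", th, 1, rb, 2), pred("PPC", rb, 2, th, 3),
           pred("PAC", th, 3, gm, 3)),
    m7 = c(pred("PPC", th, 1, rb, 2), pred("PPC", rb, 2, rb, 3),
           pred("PAC", rb, 3, gm, 3)),
    m8 = c(pred("PAC", th, 1, th, 2), pred("APC", th, 2, th, 3),
           pred("PAC", th, 3, gm, 3)),
    m9 = c(pred("PAC", th, 1, rb, 2), pred("APC", rb, 2, th, 3),
           pred("PAC", th, 3, gm, 3)),
    m10 = c(pred("PAC", th, 1, rb, 2), pred("APC", rb, 2, rb, 3),
            pred("PAC", rb, 3, gm, 3))
  )
}

# the 16 distinct predictors appearing in the ten models
cascade_predictor_names <- function(case = c("I", "II")) {
  unique(unlist(cascade_models(case), use.names = FALSE))
}

# single (type, band-pop -> band-pop) masked cTE with surrogate z-test
cfc_pair <- function(decomp, type, src_band, src_pop, tgt_band, tgt_pop,
                     scheme, n_lags, surrogates, alpha = 0.05,
                     lag_stride = 1) {
  sf <- switch(type, PAC = "phase", PPC = "phase", APC = "amplitude",
               AAC = "amplitude", PFC = "phase")
  tf <- switch(type, PAC = "amplitude", PPC = "phase", APC = "phase",
               AAC = "amplitude", PFC = "frequency")
  s <- discretize_feature(feature_series(decomp, src_band, src_pop, sf),
                          sf, scheme)
  tg <- discretize_feature(feature_series(decomp, tgt_band, tgt_pop, tf),
                           tf, scheme)
  m <- structure(rep(0L, length(s)), n_levels = 1L)
  val <- cte_disc_cpp(s - 1L, tg - 1L, m, attr(s, "n_levels"),
                      attr(tg, "n_levels"), attr(m, "n_levels"),
                      as.integer(n_lags), as.integer(lag_stride), TRUE)
  if (is.null(surrogates)) {
    return(list(value = max(val, 0), z = NA_real_, p = NA_real_,
                significant = NA))
  }
  shifts <- draw_shifts(surrogates, length(s))
  surr <- cte_surrogates_cpp(s - 1L, tg - 1L, m, attr(s, "n_levels"),
                             attr(tg, "n_levels"), attr(m, "n_levels"),
                             as.integer(n_lags), as.integer(lag_stride),
                             TRUE, shifts)
  zp <- z_and_p(val, surr)
  list(value = max(val, 0), z = zp$z, p = zp$p,
       significant = abs(zp$z) > qnorm(1 - alpha / 2))
}

#' Cascade predictors for the three-population chain
#'
#' Computes the 16 cross- and same-frequency coupling terms used as
#' regression predictors of indirect PAC, each a surrogate-tested cTE value,
#' plus the response `PAC_theta1_gamma3`. Values whose surrogate z-test is
#' not significant are set to zero (masked), mirroring how the coupling
#' matrices are thresholded.
#'
#' @param decomp an [decompose_bands()] result for the 3-channel chain
#'   simulation; must contain the theta and gamma bands and the relay band
#'   for the chosen case (delta for `"I"`, beta for `"II"`).
#' @param case `"I"` or `"II"`.
#' @param scheme a [discretization_scheme()].
#' @param n_lags lags averaged by the cTE.
#' @param lag_stride lag unit in samples.
#' @param surrogates a [surrogate_config()] (`NULL` skips masking).
#' @param alpha z-test level for masking.
#' @return Named numeric vector: 16 predictors plus `response`.
#' @export
cascade_predictors <- function(decomp, case = c("I", "II"),
                               scheme = discretization_scheme(),
                               n_lags = 100, lag_stride = 1,
                               surrogates = surrogate_config(),
                               alpha = 0.05) {
  case <- match.arg(case)
  rb <- if (case == "I") "delta" else "beta"
  need <- c("theta", "gamma", rb)
  missing_b <- setdiff(need, decomp$band_names)
  if (length(missing_b)) {
    stop("decomposition lacks band(s): ", paste(missing_b, collapse = ", "))
  }
  if (!is.null(surrogates) && !is.null(surrogates$seed)) {
    set.seed(surrogates$seed)
  }
  nms <- cascade_predictor_names(case)
  parse_term <- function(nm) {
    parts <- strsplit(nm, "_")[[1]]
    ends <- lapply(parts[2:3], function(s) {
      b <- sub("[0-9]+$", "", s)
      k <- as.integer(sub("^[a-z]+", "", s))
      list(band = b, pop = k)
    })
    list(type = parts[1], src = ends[[1]], tgt = ends[[2]])
  }
  vals <- vapply(nms, function(nm) {
    tm <- parse_term(nm)
    r <- cfc_pair(decomp, tm$type, tm$src$band, tm$src$pop, tm$tgt$band,
                  tm$tgt$pop, scheme, n_lags, surrogates, alpha, lag_stride)
    if (!is.null(surrogates) && !isTRUE(r$significant)) 0 else r$value
  }, numeric(1))
  resp <- cfc_pair(decomp, "PAC", "theta", 1, "gamma", 3, scheme, n_lags,
                   surrogates, alpha, lag_stride)
  c(vals, response = if (!is.null(surrogates) && !isTRUE(resp$significant))
    0 else resp$value)
}

#' Fit one cascade regression model
#'
#' Ordinary least squares of the response coupling on the model's predictor
#' terms (free coefficients with intercept), fitted separately for each
#' column of the sweep (each value of the second connection strength), with
#' the coefficient of determination reported per column.
#'
#' @param predictors named list of matrices (one per predictor term), each
#'   `length(gamma12 grid)` by `length(gamma23 grid)`.
#' @param response matrix of the response coupling over the same grid.
#' @param model character vector of predictor names (one entry of
#'   [cascade_models()]).
#' @return Numeric vector of R-squared values, one per gamma23 grid column.
#'   Rank-deficient fits are flagged with attribute `"rank_deficient"`.
#' @export
fit_cascade <- function(predictors, response, model) {
  miss <- setdiff(model, names(predictors))
  if (length(miss)) stop("missing predictors: ", paste(miss, collapse = ", "))
  ncols <- ncol(response)
  rank_def <- FALSE
  r2 <- vapply(seq_len(ncols), function(j) {
    y <- response[, j]
    X <- do.call(cbind, lapply(model, function(nm) predictors[[nm]][, j]))
    if (length(y) < 3) stop("need >= 3 sweep points per regression")
    if (sd(y) == 0) return(0)
    fit <- lm(y ~ X)
    if (fit$rank < ncol(X) + 1) rank_def <<- TRUE
    yhat <- fitted(fit)
    1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  }, numeric(1))
  attr(r2, "rank_deficient") <- rank_def
  r2
}

#' Nonlinear (Fourier-series) correlation coefficient
#'
#' Fits `Y ~ a0 + sum_k a_k sin(b_k X + c_k)` (K terms) by nonlinear least
#' squares with multi-start over the frequencies `b_k` (the amplitudes and
#' phases are profiled out by linear least squares at each candidate), and
#' reports the nonlinear correlation `r_nl = |cor(Y, Yhat)|`. Significance
#' is assessed against shuffle surrogates of `Y`.
#'
#' @param X regressor vector (e.g. a swept parameter).
#' @param Y response vector (e.g. coupling strengths); must not be constant.
#' @param K number of Fourier terms.
#' @param n_restarts random multi-starts for the frequency search.
#' @param n_surrogates shuffle surrogates for the significance of `r_nl`
#'   (0 skips the test).
#' @param seed RNG seed.
#' @return Object of class `fourier_fit`: coefficients `a0`, `a`, `b`, `c`,
#'   fitted values, `r_nl`, and when tested `p` plus the surrogate `r_nl`
#'   values.
#' @export
fourier_nonlinear_correlation <- function(X, Y, K = 10, n_restarts = 20,
                                          n_surrogates = 200, seed = NULL) {
  n <- length(X)
  stopifnot(length(Y) == n, n > 3)
  if (sd(Y) == 0) stop("constant response Y")
  if (!is.null(seed)) set.seed(seed)
  xr <- diff(range(X))
  if (xr == 0) stop("constant regressor X")
  design <- function(b) {
    cbind(1, do.call(cbind, lapply(b, function(bk) {
      cbind(sin(bk * X), cos(bk * X))
    })))
  }
  # rank-tolerant least squares (collinear designs arise when the
  # frequency search duplicates a component; dropped columns get zero)
  ls_solve <- function(M, y) {
    qr_ <- qr(M)
    cf <- qr.coef(qr_, y)
    cf[is.na(cf)] <- 0
    cf
  }
  sse_of <- function(b) {
    M <- design(b)
    cf <- tryCatch(ls_solve(M, Y), error = function(e) NULL)
    if (is.null(cf)) return(list(sse = Inf))
    yhat <- M %*% cf
    list(sse = sum((Y - yhat)^2), coef = cf, yhat = yhat)
  }
  fit_once <- function(b0) {
    opt <- if (length(b0) == 1) {
      optim(b0, function(b) sse_of(b)$sse, method = "Brent",
            lower = 1e-6, upper = 40 * pi / xr)
    } else {
      optim(b0, function(b) sse_of(b)$sse, method = "Nelder-Mead",
            control = list(maxit = 400))
    }
    list(b = opt$par, sse = opt$value)
  }
  base_freq <- 2 * pi / xr
  starts <- c(list((1:K) * base_freq / 2),
              lapply(seq_len(max(0, n_restarts - 1)), function(i) {
                runif(K, 0.05 * base_freq, K * base_freq)
              }))
  best <- NULL
  for (b0 in starts) {
    f <- fit_once(b0)
    if (is.null(best) || f$sse < best$sse) best <- f
  }
  final <- sse_of(best$b)
  cf <- as.numeric(final$coef)
  a0 <- cf[1]
  alpha <- cf[seq(2, 2 * K, by = 2)]
  beta <- cf[seq(3, 2 * K + 1, by = 2)]
  r_nl <- abs(as.numeric(cor(Y, as.numeric(final$yhat))))
  out <- list(a0 = a0, a = sqrt(alpha^2 + beta^2), b = best$b,
              c = atan2(beta, alpha), fitted = as.numeric(final$yhat),
              r_nl = r_nl, K = K)
  if (n_surrogates > 0) {
    surr <- vapply(seq_len(n_surrogates), function(i) {
      Ys <- sample(Y)
      bestS <- NULL
      for (b0 in starts[seq_len(min(3, length(starts)))]) {
        M <- design(fit_once_y(b0, X, Ys)$b)
        cfS <- ls_solve(M, Ys)
        r <- abs(as.numeric(cor(Ys, as.numeric(M %*% cfS))))
        if (is.null(bestS) || r > bestS) bestS <- r
      }
      bestS
    }, numeric(1))
    out$surrogate_r <- surr
    out$p <- mean(surr >= r_nl)
  }
  structure(out, class = "fourier_fit")
}

# reduced-effort frequency fit used inside the shuffle surrogate loop
fit_once_y <- function(b0, X, Y) {
  design <- function(b) {
    cbind(1, do.call(cbind, lapply(b, function(bk) {
      cbind(sin(bk * X), cos(bk * X))
    })))
  }
  obj <- function(b) {
    M <- design(b)
    cf <- tryCatch({
      qr_ <- qr(M)
      out <- qr.coef(qr_, Y)
      out[is.na(out)] <- 0
      out
    }, error = function(e) NULL)
    if (is.null(cf)) return(Inf)
    sum((Y - M %*% cf)^2)
  }
  opt <- if (length(b0) == 1) {
    optim(b0, obj, method = "Brent", lower = 1e-6,
          upper = 40 * pi / diff(range(X)))
  } else {
    optim(b0, obj, method = "Nelder-Mead", control = list(maxit = 400))
  }
  list(b = opt$par)
}

#' @export
print.fourier_fit <- function(x, ...) {
  cat(sprintf("fourier_fit: K = %d, r_nl = %.4f", x$K, x$r_nl))
  if (!is.null(x$p)) cat(sprintf(" (shuffle p = %.3f)", x$p))
  cat("\n")
  invisible(x)
}
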