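#' Coupling-measure specification
#'
#' Which feature of which band drives which feature of which band. Types:
#' `PAC` phase -> amplitude (source band below target band),
#' `APC` amplitude -> phase (source band above target band),
#' `AAC` amplitude -> amplitude, `PPC` phase -> phase,
#' `PFC` phase -> instantaneous frequency, and same-frequency coupling
#' `SFC-amp` / `SFC-phase` (identical band at both ends).
#'
#' @param type coupling type.
#' @param source_band,target_band band names (must exist in the
#'   decomposition passed to [estimate_cfc()]).
#' @param n_lags number of future lags `N` averaged by the conditional
#'   transfer entropy.
#' @param lag_stride lag unit in samples: the cTE averages over
#'   `delta = lag_stride * (1..n_lags)`. A stride above one extends the
#'   prediction horizon on heavily oversampled band signals so that it
#'   reaches beyond the target's deterministic short-time continuation.
#' @return An object of class `coupling_spec` with `source_feature` and
#'   `target_feature` filled from the type.
#' @export
coupling_spec <- function(type = c("PAC", "APC", "AAC", "PPC", "PFC",
                                   "SFC-amp", "SFC-phase"),
                          source_band, target_band, n_lags = 100,
                          lag_stride = 1) {
  type <- match.arg(type)
  stopifnot(n_lags >= 1, lag_stride >= 1)
  feats <- switch(type,
    "PAC" = c("phase", "amplitude"),
    "APC" = c("amplitude", "phase"),
    "AAC" = c("amplitude", "amplitude"),
    "PPC" = c("phase", "phase"),
    "PFC" = c("phase", "frequency"),
    "SFC-amp" = c("amplitude", "amplitude"),
    "SFC-phase" = c("phase", "phase"))
  if (startsWith(type, "SFC") && source_band != target_band) {
    stop("SFC requires the same band at both ends")
  }
  structure(list(type = type, source_band = source_band,
                 target_band = target_band,
                 source_feature = feats[1], target_feature = feats[2],
                 n_lags = as.integer(n_lags),
                 lag_stride = as.integer(lag_stride)),
            class = "coupling_spec")
}

#' Discretization scheme for the information estimators
#'
#' Phases are binned uniformly on `[-pi, pi)` (circular); amplitudes and
#' frequencies into equiprobable quantile bins (robust to heavy tails).
#'
#' @param n_bins number of bins per series (>= 2).
#' @return An object of class `discretization_scheme`.
#' @export
discretization_scheme <- function(n_bins = 8) {
  stopifnot(n_bins >= 2)
  structure(list(n_bins = as.integer(n_bins)), class = "discretization_scheme")
}

#' Discretize a series into integer codes
#'
#' @param x numeric series (or integer codes, returned unchanged with their
#'   observed alphabet).
#' @param scheme a [discretization_scheme()].
#' @param circular `TRUE` for phases: uniform bins over `[-pi, pi)`;
#'   otherwise equiprobable rank-based bins.
#' @return Integer vector of codes in `1..n_bins` with attribute
#'   `"n_levels"`.
#' @export
discretize_series <- function(x, scheme = discretization_scheme(),
                              circular = FALSE) {
  stopifnot(inherits(scheme, "discretization_scheme"))
  B <- scheme$n_bins
  if (circular) {
    code <- pmin(B, floor((x + pi) / (2 * pi) * B) + 1L)
    code <- pmax(1L, code)
  } else {
    rk <- rank(x, ties.method = "first")
    code <- floor((rk - 1) * B / length(x)) + 1L
  }
  code <- as.integer(code)
  attr(code, "n_levels") <- B
  code
}

# integer codes (1-based) from anything; keeps n_levels attr if present
as_codes <- function(x) {
  nl <- attr(x, "n_levels")
  if (is.null(nl)) {
    f <- as.integer(factor(x))
    nl <- max(f)
    x <- f
  }
  x <- as.integer(x)
  attr(x, "n_levels") <- as.integer(nl)
  x
}

# combine several code series into a single 0-based code vector
combine_codes <- function(series_list) {
  if (length(series_list) == 0) {
    return(structure(integer(0), n_levels = 1L))
  }
  series_list <- lapply(series_list, as_codes)
  n <- length(series_list[[1]])
  code <- rep(0L, n)
  nl <- 1
  for (s in series_list) {
    stopifnot(length(s) == n)
    k <- attr(s, "n_levels")
    code <- code * k + (s - 1L)
    nl <- nl * k
  }
  if (nl > 2^31 - 1) stop("combined alphabet too large")
  attr(code, "n_levels") <- as.integer(nl)
  code
}

check_undersampling <- function(cells, n) {
  if (cells > n) {
    warning("joint alphabet (", cells, " cells) exceeds the series length (",
            n, " samples); the plug-in estimate is undersampled",
            call. = FALSE)
  }
}

#' Modulation index
#'
#' Magnitude of the amplitude-weighted phase vector sum,
#' `|sum_t a(t) exp(i phi(t))|`. The un-normalized sum is the default; set
#' `normalize = TRUE` to divide by the series length.
#'
#' @param phase phase series, radians.
#' @param amplitude amplitude series (same length).
#' @param normalize divide by the number of samples.
#' @return Scalar modulation index.
#' @export
modulation_index <- function(phase, amplitude, normalize = FALSE) {
  if (length(phase) != length(amplitude)) stop("length mismatch")
  m <- Mod(sum(amplitude * exp(1i * phase)))
  if (normalize) m <- m / length(phase)
  m
}

#' Envelope-to-signal correlation
#'
#' Pearson correlation between `cos(phase)` and the amplitude series.
#'
#' @inheritParams modulation_index
#' @return Correlation in `[-1, 1]`.
#' @export
esc <- function(phase, amplitude) {
  if (length(phase) != length(amplitude)) stop("length mismatch")
  cp <- cos(phase)
  if (sd(cp) == 0 || sd(amplitude) == 0) stop("zero-variance input")
  cor(cp, amplitude)
}

#' Conditional mutual information (plug-in, chain rule)
#'
#' `I(X; Y | M) = I(X; (Y, M)) - I(X; M)` on discrete (or discretized)
#' series, in bits. With an empty conditioning set this is the plain mutual
#' information. Negative plug-in values are reported as computed (they can
#' only arise from the chain-rule difference of finite-sample estimates).
#'
#' @param x,y discrete series (integer codes, factors, or output of
#'   [discretize_series()]).
#' @param conditioning list of discrete series to condition on (may be
#'   empty / `NULL`).
#' @return cMI in bits.
#' @export
conditional_mutual_information <- function(x, y, conditioning = NULL) {
  x <- as_codes(x)
  y <- as_codes(y)
  if (length(x) != length(y)) stop("length mismatch")
  if (is.null(conditioning) || length(conditioning) == 0) {
    check_undersampling(attr(x, "n_levels") * attr(y, "n_levels"), length(x))
    return(mi_disc_cpp(x - 1L, y - 1L,
                       attr(x, "n_levels"), attr(y, "n_levels")))
  }
  m <- combine_codes(conditioning)
  if (length(m) != length(x)) stop("conditioning length mismatch")
  check_undersampling(
    as.double(attr(x, "n_levels")) * attr(y, "n_levels") * attr(m, "n_levels"),
    length(x))
  cmi_chain_cpp(x - 1L, y - 1L, m, attr(x, "n_levels"),
                attr(y, "n_levels"), attr(m, "n_levels"))
}

#' Conditional transfer entropy (lag-averaged cMI)
#'
#' `cTE(source -> target | M) = (1/N) sum_{delta=1..N}
#' I(source_t; target_{t+delta} | M_t)` in bits, where the conditioning set
#' `M` excludes the source but normally includes the target's own (past)
#' series plus any exogenous conditioning series. The lag unit is one
#' sample.
#'
#' @param source,target discrete series (see
#'   [conditional_mutual_information()]).
#' @param conditioning list of exogenous discrete conditioning series
#'   (already excluding source and target).
#' @param n_lags number of future lags `N` averaged.
#' @param target_past also condition on the target's own series at the
#'   source's time point (the standard transfer-entropy conditioning).
#' @param lag_stride lag unit in samples (`delta = lag_stride * (1..N)`).
#' @return cTE in bits.
#' @export
conditional_transfer_entropy <- function(source, target, conditioning = NULL,
                                         n_lags = 100, target_past = TRUE,
                                         lag_stride = 1) {
  source <- as_codes(source)
  target <- as_codes(target)
  if (length(source) != length(target)) stop("length mismatch")
  if (n_lags >= length(source)) stop("n_lags must be below the series length")
  m <- combine_codes(conditioning)  # already 0-based
  if (length(m) == 0) m <- structure(rep(0L, length(source)), n_levels = 1L)
  if (length(m) != length(source)) stop("conditioning length mismatch")
  nt <- attr(target, "n_levels")
  check_undersampling(
    as.double(attr(source, "n_levels")) * nt * attr(m, "n_levels") *
      (if (target_past) nt else 1), length(source))
  cte_disc_cpp(source - 1L, target - 1L, m, attr(source, "n_levels"),
               nt, attr(m, "n_levels"), as.integer(n_lags),
               as.integer(lag_stride), isTRUE(target_past))
}

# extract one feature series for (band, channel) from a decomposition
feature_series <- function(decomp, band, channel, feature) {
  b <- match(band, decomp$band_names)
  if (is.na(b)) stop("band '", band, "' not in decomposition")
  k <- if (is.character(channel)) match(channel, decomp$channels) else channel
  if (is.na(k)) stop("channel '", channel, "' not in decomposition")
  switch(feature,
         phase = decomp$phase[, b, k],
         amplitude = decomp$amplitude[, b, k],
         frequency = instantaneous_frequency(decomp$phase[, b, k], decomp$fs),
         stop("unknown feature ", feature))
}

discretize_feature <- function(x, feature, scheme) {
  discretize_series(x, scheme, circular = (feature == "phase"))
}

# exogenous conditioning codes (0-based combined) + target-past flag for
# source channel k -> target channel l under a policy
conditioning_codes <- function(decomp, spec, scheme, policy, k, l,
                               custom = NULL) {
  n_samp <- dim(decomp$amplitude)[1]
  empty <- structure(rep(0L, n_samp), n_levels = 1L)
  if (is.function(policy)) {
    ex <- combine_codes(policy(decomp, spec, scheme, k, l))
    if (!length(ex)) ex <- empty
    return(list(exog = ex, target_past = TRUE))
  }
  switch(policy,
    none = list(exog = empty, target_past = FALSE),
    target_past = list(exog = empty, target_past = TRUE),
    others = {
      # target past + the source-feature series of every other channel:
      # a tractable stand-in for conditioning on all phases and amplitudes
      oth <- setdiff(seq_along(decomp$channels), c(k, l))
      ex <- if (length(oth)) {
        combine_codes(lapply(oth, function(j) {
          discretize_feature(
            feature_series(decomp, spec$source_band, j, spec$source_feature),
            spec$source_feature, scheme)
        }))
      } else empty
      list(exog = ex, target_past = TRUE)
    },
    custom = {
      stopifnot(!is.null(custom))
      list(exog = combine_codes(lapply(custom, as_codes)),
           target_past = TRUE)
    },
    all = {
      warning("conditioning on all phases and amplitudes: the histogram ",
              "estimator is severely undersampled at this dimensionality",
              call. = FALSE)
      cond <- list()
      for (b in decomp$band_names) {
        for (j in seq_along(decomp$channels)) {
          for (f in c("phase", "amplitude")) {
            if (b == spec$source_band && j == k && f == spec$source_feature) next
            if (b == spec$target_band && j == l && f == spec$target_feature) next
            cond <- c(cond, list(discretize_feature(
              feature_series(decomp, b, j, f), f, scheme)))
          }
        }
      }
      list(exog = combine_codes(cond), target_past = TRUE)
    },
    stop("unknown conditioning policy"))
}

#' Estimate a coupling matrix with surrogate significance
#'
#' Computes the conditional transfer entropy from the source feature of every
#' channel to the target feature of every channel for one coupling type and
#' band pair, then attaches circular-shift surrogate z-scores, two-sided
#' Gaussian p-values and an FDR-corrected significance mask over all entries
#' of the matrix.
#'
#' @param decomp an [decompose_bands()] result.
#' @param spec a [coupling_spec()].
#' @param scheme a [discretization_scheme()].
#' @param conditioning conditioning policy: `"target_past"` (default),
#'   `"none"`, `"others"`, `"all"` (warned: undersampled), `"custom"` (then
#'   supply `custom_conditioning`, a list of discrete series), or a function
#'   `(decomp, spec, scheme, k, l) -> list of series`.
#' @param surrogates a [surrogate_config()]; `NULL` skips significance.
#' @param alpha significance level for the FDR mask.
#' @param include_self keep diagonal (channel onto itself) entries.
#' @param custom_conditioning list of discrete series for
#'   `conditioning = "custom"`.
#' @return Object of class `cfc_result`: matrices `values` (bits, clipped at
#'   0 with `n_clipped` counting clips), `raw`, `z`, `p`, logical `mask`, the
#'   spec and settings.
#' @export
estimate_cfc <- function(decomp, spec, scheme = discretization_scheme(),
                         conditioning = "target_past",
                         surrogates = surrogate_config(), alpha = 0.05,
                         include_self = TRUE, custom_conditioning = NULL) {
  stopifnot(inherits(decomp, "analytic_decomposition"),
            inherits(spec, "coupling_spec"))
  band_order <- vapply(decomp$bands, function(b) (b$low + b$high) / 2,
                       numeric(1))
  names(band_order) <- decomp$band_names
  if (spec$type == "PAC" &&
      band_order[spec$source_band] >= band_order[spec$target_band]) {
    stop("PAC requires a source band below the target band")
  }
  if (spec$type == "APC" &&
      band_order[spec$source_band] <= band_order[spec$target_band]) {
    stop("APC requires a source band above the target band")
  }
  nch <- length(decomp$channels)
  src_codes <- lapply(seq_len(nch), function(k) {
    discretize_feature(
      feature_series(decomp, spec$source_band, k, spec$source_feature),
      spec$source_feature, scheme)
  })
  tgt_codes <- lapply(seq_len(nch), function(l) {
    discretize_feature(
      feature_series(decomp, spec$target_band, l, spec$target_feature),
      spec$target_feature, scheme)
  })
  vals <- z <- p <- matrix(NA_real_, nch, nch,
                           dimnames = list(decomp$channels, decomp$channels))
  mask <- matrix(FALSE, nch, nch, dimnames = dimnames(vals))
  if (!is.null(surrogates) && !is.null(surrogates$seed)) {
    set.seed(surrogates$seed)
  }
  n_samp <- length(src_codes[[1]])
  for (k in seq_len(nch)) {
    for (l in seq_len(nch)) {
      if (!include_self && k == l) next
      cc <- conditioning_codes(decomp, spec, scheme, conditioning, k, l,
                               custom_conditioning)
      m <- cc$exog
      s <- as_codes(src_codes[[k]])
      tg <- as_codes(tgt_codes[[l]])
      vals[k, l] <- cte_disc_cpp(s - 1L, tg - 1L, m, attr(s, "n_levels"),
                                 attr(tg, "n_levels"), attr(m, "n_levels"),
                                 spec$n_lags, spec$lag_stride, cc$target_past)
      if (!is.null(surrogates)) {
        shifts <- draw_shifts(surrogates, n_samp)
        surr <- cte_surrogates_cpp(s - 1L, tg - 1L, m, attr(s, "n_levels"),
                                   attr(tg, "n_levels"), attr(m, "n_levels"),
                                   spec$n_lags, spec$lag_stride,
                                   cc$target_past, shifts)
        zp <- z_and_p(vals[k, l], surr)
        z[k, l] <- zp$z
        p[k, l] <- zp$p
      }
    }
  }
  if (!is.null(surrogates)) {
    idx <- which(!is.na(p))
    mask[idx] <- fdr_mask(p[idx], alpha) & abs(z[idx]) > qnorm(1 - alpha / 2)
  }
  n_clipped <- sum(vals < 0, na.rm = TRUE)
  out_vals <- pmax(vals, 0)
  structure(list(values = out_vals, raw = vals, z = z, p = p, mask = mask,
                 spec = spec, scheme = scheme,
                 conditioning = if (is.function(conditioning)) "function"
                                else conditioning,
                 alpha = alpha, n_clipped = n_clipped),
            class = "cfc_result")
}

#' @export
print.cfc_result <- function(x, ...) {
  cat("cfc_result:", x$spec$type, x$spec$source_band, "->",
      x$spec$target_band, "|", nrow(x$values), "x", ncol(x$values),
      "channels;", sum(x$mask, na.rm = TRUE), "significant entries\n")
  invisible(x)
}

#' Write a coupling matrix to CSV with a JSON sidecar
#'
#' @param result a [estimate_cfc()] result.
#' @param dir output directory.
#' @return The CSV path, invisibly. Files are named
#'   `{type}_{srcband}-{tgtband}.csv` / `.json`; the CSV holds the masked
#'   values, the sidecar the spec, settings and z/p matrices.
#' @export
write_cfc_csv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- paste0(result$spec$type, "_", result$spec$source_band, "-",
                 result$spec$target_band)
  masked <- result$values * ifelse(is.na(result$mask), 1, result$mask)
  write.csv(masked, file.path(dir, paste0(stem, ".csv")))
  jsonlite::write_json(
    list(spec = unclass(result$spec), alpha = result$alpha,
         conditioning = result$conditioning,
         n_bins = result$scheme$n_bins, n_clipped = result$n_clipped,
         z = result$z, p = result$p),
    file.path(dir, paste0(stem, ".json")), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(file.path(dir, paste0(stem, ".csv")))
}

#' Nearest-neighbour conditional mutual information (continuous backend)
#'
#' Frenzel-Pompe / KSG-type estimator on continuous series, in bits: an
#' alternative to the histogram estimator when the conditioning set is
#' high-dimensional. Quadratic in the series length; intended for series of
#' a few thousand samples.
#'
#' @param x,y numeric series.
#' @param conditioning list of numeric conditioning series (may be empty).
#' @param k number of nearest neighbours.
#' @return cMI estimate in bits.
#' @export
knn_cmi <- function(x, y, conditioning = NULL, k = 5) {
  n <- length(x)
  stopifnot(length(y) == n, n >= k + 2, n <= 8000)
  zmat <- if (length(conditioning)) {
    do.call(cbind, lapply(conditioning, function(s) {
      stopifnot(length(s) == n); as.numeric(s)
    }))
  } else NULL
  cheb <- function(m) {
    # pairwise Chebyshev distances of rows
    d <- matrix(0, n, n)
    for (j in seq_len(ncol(m))) {
      d <- pmax(d, abs(outer(m[, j], m[, j], "-")))
    }
    d
  }
  dx <- cheb(cbind(x))
  dy <- cheb(cbind(y))
  dz <- if (is.null(zmat)) matrix(0, n, n) else cheb(zmat)
  djoint <- pmax(dx, dy, dz)
  diag(djoint) <- Inf
  eps <- apply(djoint, 1, function(r) sort(r, partial = k)[k])
  dxz <- pmax(dx, dz); diag(dxz) <- Inf
  dyz <- pmax(dy, dz); diag(dyz) <- Inf
  diag(dz) <- Inf
  n_xz <- rowSums(dxz < eps)
  n_yz <- rowSums(dyz < eps)
  n_z <- if (is.null(zmat)) rep(n - 1, n) else rowSums(dz < eps)
  val <- digamma(k) - mean(digamma(n_xz + 1) + digamma(n_yz + 1) -
                             digamma(n_z + 1))
  val / log(2)
}
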