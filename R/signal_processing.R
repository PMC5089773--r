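#' Frequency band definition
#'
#' @param name band label.
#' @param low,high band edges, Hz (`0 <= low < high`).
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1, low >= 0, low < high)
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' Canonical EEG band set
#'
#' delta (0.1-4 Hz), theta (4-8), alpha (8-12), beta (12-30) and gamma
#' (30-120). `delta_low` may be raised (e.g. to 0.5 Hz) for short recordings
#' where a 0.1 Hz edge would demand impractically long filters, at the cost
#' of discarding the slowest delta content.
#'
#' @param delta_low lower delta edge, Hz.
#' @param gamma_high upper gamma edge, Hz (must stay below Nyquist).
#' @return Named list of [band_definition()] objects.
#' @export
canonical_bands <- function(delta_low = 0.1, gamma_high = 120) {
  list(delta = band_definition("delta", delta_low, 4),
       theta = band_definition("theta", 4, 8),
       alpha = band_definition("alpha", 8, 12),
       beta  = band_definition("beta", 12, 30),
       gamma = band_definition("gamma", 30, gamma_high))
}

#' Zero-phase band-pass filter
#'
#' Linear-phase FIR band-pass applied forward and backward
#' ([signal::filtfilt()]) so the net phase shift is zero. The default order
#' spans three cycles of the band's low edge, capped so the series stays
#' longer than three filter orders.
#'
#' @param x numeric series.
#' @param band a [band_definition()].
#' @param fs sampling rate, Hz.
#' @param order FIR order (even); default `round(6 * fs / band$low)` (six
#'   cycles of the low band edge, so the windowed design's transition band
#'   stays well inside the band), capped so the series stays longer than
#'   three filter orders.
#' @return Filtered series, same length as `x`. The order used is attached
#'   as attribute `"order"`.
#' @export
bandpass <- function(x, band, fs, order = NULL) {
  stopifnot(inherits(band, "band_definition"))
  if (band$high >= fs / 2) {
    stop("band '", band$name, "' upper edge ", band$high,
         " Hz is at or above Nyquist (fs = ", fs, " Hz)")
  }
  n <- length(x)
  if (is.null(order)) {
    order <- round(6 * fs / max(band$low, 1e-6))
    order <- min(order, 2 * ((n - 1) %/% 6))  # keep n > 3 * order
  }
  order <- max(10, 2 * round(order / 2))  # even, type-I FIR
  if (n <= 3 * order) {
    stop("series too short (", n, " samples) for filter order ", order)
  }
  w <- c(max(band$low, 1e-6), band$high) / (fs / 2)
  fir <- signal::fir1(order, w, type = "pass")
  out <- signal::filtfilt(fir, x)
  attr(out, "order") <- order
  out
}

# analytic signal via the frequency-domain Hilbert transform
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous amplitude and phase of a band-limited series
#'
#' Hilbert decomposition `x(t) = a(t) cos(phi(t))`: the analytic signal's
#' modulus is the instantaneous amplitude and its argument the instantaneous
#' phase in `[-pi, pi)`.
#'
#' @param x band-limited numeric series (non-constant).
#' @return List with `amplitude` (>= 0) and `phase` (radians).
#' @export
analytic_decompose <- function(x) {
  if (sd(x) == 0) stop("constant input: instantaneous phase is undefined")
  a <- analytic_signal(x - mean(x))
  phase <- Arg(a)
  phase[phase >= pi] <- phase[phase >= pi] - 2 * pi
  list(amplitude = Mod(a), phase = phase)
}

#' Instantaneous frequency from a phase series
#'
#' Derivative of the unwrapped phase divided by `2 pi`; the last sample is
#' repeated so the output length matches the input.
#'
#' @param phase phase series, radians.
#' @param fs sampling rate, Hz.
#' @return Instantaneous frequency, Hz.
#' @export
instantaneous_frequency <- function(phase, fs) {
  dphi <- diff(signal::unwrap(phase)) * fs / (2 * pi)
  c(dphi, dphi[length(dphi)])
}

#' Band-wise analytic decomposition of multichannel data
#'
#' Filters every channel into every band (zero-phase FIR), Hilbert-decomposes
#' the filtered series, and (by default) z-normalizes each amplitude series
#' by its temporal mean and standard deviation so bands are comparable.
#' Filter-order samples are discarded from each end of all series to suppress
#' edge transients, and the data may first be decimated to a lower rate since
#' content below the top band edge is heavily oversampled at typical
#' simulation steps.
#'
#' @param x numeric matrix (time by channel) or a [simulate_column()] result.
#' @param bands list of [band_definition()] objects.
#' @param fs sampling rate, Hz (taken from `x` when it is a simulation result).
#' @param normalize z-normalize amplitudes per (band, channel).
#' @param downsample_to target rate, Hz (`NULL` keeps the native rate). Must
#'   leave all band edges below Nyquist.
#' @param filter_order FIR order shared by all bands (`NULL`: per-band
#'   default). A long shared order deepens every band's stop-band, which
#'   matters when strong low-frequency components must not leak into the
#'   high bands.
#' @param edge_discard samples dropped from each end; default is the largest
#'   filter order used.
#' @return Object of class `analytic_decomposition` with arrays `amplitude`
#'   and `phase` of dimension time x band x channel, the band list, channel
#'   names and `fs`.
#' @export
decompose_bands <- function(x, bands = canonical_bands(), fs = NULL,
                            normalize = TRUE, downsample_to = NULL,
                            filter_order = NULL, edge_discard = NULL) {
  if (inherits(x, "simulation_result")) {
    fs <- x$fs
    x <- x$x
  }
  x <- as.matrix(x)
  stopifnot(!is.null(fs), length(bands) >= 1)
  # remove per-channel means first: a DC offset acts as a giant onset step
  # whose filter ringing would otherwise contaminate every band
  x <- sweep(x, 2, colMeans(x))
  if (!is.null(downsample_to) && downsample_to < fs) {
    dec <- floor(fs / downsample_to)
    if (dec > 1) {
      x <- apply(x, 2, signal::decimate, q = dec, ft = "fir")
      fs <- fs / dec
    }
  }
  nt <- nrow(x)
  nch <- ncol(x)
  chn <- colnames(x)
  if (is.null(chn)) chn <- paste0("ch", seq_len(nch))
  bn <- unname(vapply(bands, `[[`, character(1), "name"))
  amp <- array(NA_real_, c(nt, length(bands), nch),
               dimnames = list(NULL, bn, chn))
  phs <- amp
  max_order <- 0
  for (b in seq_along(bands)) {
    for (k in seq_len(nch)) {
      xf <- bandpass(x[, k], bands[[b]], fs, order = filter_order)
      max_order <- max(max_order, attr(xf, "order"))
      d <- analytic_decompose(xf)
      amp[, b, k] <- d$amplitude
      phs[, b, k] <- d$phase
    }
  }
  if (is.null(edge_discard)) edge_discard <- max_order
  edge_discard <- min(edge_discard, (nt - 16) %/% 2)
  if (edge_discard > 0) {
    keep <- (edge_discard + 1):(nt - edge_discard)
    amp <- amp[keep, , , drop = FALSE]
    phs <- phs[keep, , , drop = FALSE]
  }
  if (normalize) {
    for (b in seq_along(bands)) {
      for (k in seq_len(nch)) {
        a <- amp[, b, k]
        amp[, b, k] <- (a - mean(a)) / sd(a)
      }
    }
  }
  structure(list(amplitude = amp, phase = phs, bands = bands,
                 band_names = bn, channels = chn, fs = fs,
                 normalized = normalize, edge_discard = edge_discard),
            class = "analytic_decomposition")
}

#' @export
print.analytic_decomposition <- function(x, ...) {
  cat("analytic_decomposition:", dim(x$amplitude)[1], "samples x",
      length(x$band_names), "bands x", length(x$channels), "channels at",
      x$fs, "Hz\n")
  invisible(x)
}

#' Export an analytic decomposition as CSV
#'
#' One file per quantity (`amplitude.csv`, `phase.csv`) in long-ish wide
#' format with `band.channel` column names, plus a JSON sidecar describing
#' bands, channels and sampling rate.
#'
#' @param decomp an [decompose_bands()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_decomposition_csv <- function(decomp, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat <- function(a) {
    m <- matrix(a, nrow = dim(a)[1])
    colnames(m) <- as.vector(outer(decomp$band_names, decomp$channels,
                                   function(b, ch) paste(b, ch, sep = ".")))
    m
  }
  write.csv(flat(decomp$amplitude), file.path(dir, "amplitude.csv"),
            row.names = FALSE)
  write.csv(flat(decomp$phase), file.path(dir, "phase.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(bands = lapply(decomp$bands, function(b) b[c("name", "low", "high")]),
         channels = decomp$channels, fs = decomp$fs,
         normalized = decomp$normalized),
    file.path(dir, "decomposition.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' One-sided spectral density
#'
#' Periodogram scaled so that the power integrated over frequency equals the
#' series variance (Parseval). The normalized variant subtracts the mean of
#' the power vector and divides by its standard deviation, which makes peak
#' heights comparable across channels.
#'
#' @param x numeric series.
#' @param fs sampling rate, Hz.
#' @param normalized return the z-normalized power vector.
#' @return List with `freq` (Hz) and `power`.
#' @export
spectral_density <- function(x, fs, normalized = FALSE) {
  n <- length(x)
  stopifnot(n >= 8)
  X <- fft(x - mean(x))
  half <- floor(n / 2)
  pow <- (2 / (n * fs)) * Mod(X[2:(half + 1)])^2
  if (n %% 2 == 0) pow[half] <- pow[half] / 2  # Nyquist bin is not doubled
  freq <- (1:half) * fs / n
  if (normalized) pow <- (pow - mean(pow)) / sd(pow)
  list(freq = freq, power = pow)
}

# topographic prominence of each local maximum
peak_prominence <- function(power) {
  n <- length(power)
  idx <- which(diff(sign(diff(power))) == -2) + 1
  prom <- vapply(idx, function(i) {
    h <- power[i]
    left <- if (i > 1) power[1:(i - 1)] else h
    right <- if (i < n) power[(i + 1):n] else h
    lmin <- if (any(left >= h)) min(left[max(which(left >= h)):(i - 1)]) else min(left)
    rmin <- if (any(right >= h)) min(right[1:min(which(right >= h))]) else min(right)
    h - max(lmin, rmin)
  }, numeric(1))
  list(index = idx, prominence = prom)
}

#' Locate spectral peaks
#'
#' Local maxima of the power vector whose topographic prominence exceeds a
#' threshold, sorted by decreasing power.
#'
#' @param freq,power as returned by [spectral_density()].
#' @param min_prominence prominence threshold, in the units of `power`.
#' @return Data frame with `freq`, `power` and `prominence`.
#' @export
find_spectral_peaks <- function(freq, power, min_prominence = 0) {
  pk <- peak_prominence(power)
  keep <- pk$prominence > min_prominence
  idx <- pk$index[keep]
  out <- data.frame(freq = freq[idx], power = power[idx],
                    prominence = pk$prominence[keep])
  out[order(-out$power), , drop = FALSE]
}

#' Layer-wise local field potential
#'
#' The LFP of a layer is modeled as the sum of the PSPs of that layer's
#' excitatory populations.
#'
#' @param result a [simulate_column()] result.
#' @param model the model used (defaults to the one stored in `result`).
#' @return Matrix, time by layer.
#' @export
layer_lfp <- function(result, model = result$model) {
  stopifnot(inherits(result, "simulation_result"),
            inherits(model, "column_model"))
  layers <- unique(vapply(model$populations, `[[`, character(1), "layer"))
  out <- sapply(layers, function(L) {
    idx <- which(vapply(model$populations, function(p) {
      p$layer == L && p$excitatory
    }, logical(1)))
    if (!length(idx)) stop("layer ", L, " has no excitatory population")
    rowSums(result$x[, idx, drop = FALSE])
  })
  colnames(out) <- layers
  out
}
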