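fs <- 500
tt <- seq(0, 10, by = 1 / fs)

test_that("in-band tones pass and out-of-band tones are attenuated with zero phase", {
  alpha <- band_definition("alpha", 8, 12)
  x10 <- sin(2 * pi * 10 * tt)
  y10 <- bandpass(x10, alpha, fs)
  mid <- 1000:4000
  expect_equal(sd(y10[mid]), sd(x10[mid]), tolerance = 0.05)

  x50 <- sin(2 * pi * 50 * tt)
  y50 <- bandpass(x50, alpha, fs)
  expect_lt(sd(y50[mid]) / sd(x50[mid]), 10^(-20 / 20))

  # zero net phase: cross-correlation of an in-band tone peaks at lag 0
  cc <- ccf(y10[mid], x10[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("bandpass validates Nyquist and series length", {
  expect_error(bandpass(rnorm(1000), band_definition("g", 30, 300), fs),
               "Nyquist")
  expect_error(bandpass(rnorm(50), band_definition("a", 8, 12), fs,
                        order = 100), "too short")
})

test_that("analytic decomposition recovers amplitude and phase of tones", {
  x <- cos(2 * pi * 7 * tt)
  d <- analytic_decompose(x)
  mid <- 500:4500
  expect_equal(mean(d$amplitude[mid]), 1, tolerance = 0.01)
  expect_lt(sd(d$amplitude[mid]), 0.02)
  # phase advances at 2 pi f
  ifreq <- instantaneous_frequency(d$phase, fs)
  expect_equal(mean(ifreq[mid]), 7, tolerance = 0.01)
  expect_true(all(d$phase >= -pi & d$phase < pi))

  d3 <- analytic_decompose(3 * cos(2 * pi * 7 * tt))
  expect_equal(mean(d3$amplitude[mid]), 3, tolerance = 0.03)

  expect_error(analytic_decompose(rep(1, 100)), "constant")
})

test_that("instantaneous frequency tracks a chirp within 2%", {
  f0 <- 5; f1 <- 15
  phase <- 2 * pi * (f0 * tt + (f1 - f0) * tt^2 / 20)
  x <- cos(phase)
  d <- analytic_decompose(x)
  ifreq <- instantaneous_frequency(d$phase, fs)
  truth <- f0 + (f1 - f0) * tt / 10
  mid <- 500:4500
  expect_lt(max(abs(ifreq[mid] - truth[mid]) / truth[mid]), 0.02)
})

test_that("amplitude * cos(phase) reconstructs the filtered signal", {
  set.seed(1)
  x <- rnorm(length(tt))
  xf <- bandpass(x, band_definition("beta", 12, 30), fs)
  d <- analytic_decompose(as.numeric(xf))
  rec <- d$amplitude * cos(d$phase)
  mid <- 800:4200
  rmse <- sqrt(mean((rec[mid] - xf[mid])^2)) / sd(xf[mid])
  expect_lt(rmse, 0.05)
})

test_that("spectral density resolves tones and is Parseval-consistent", {
  x8 <- sin(2 * pi * 8 * tt)
  sp <- spectral_density(x8, fs)
  expect_equal(sp$freq[which.max(sp$power)], 8, tolerance = 0.11)
  df <- sp$freq[2] - sp$freq[1]
  expect_equal(sum(sp$power) * df, mean((x8 - mean(x8))^2), tolerance = 0.01)

  x2 <- sin(2 * pi * 4.4 * tt) + 0.8 * sin(2 * pi * 50 * tt)
  sp2 <- spectral_density(x2, fs)
  pk <- find_spectral_peaks(sp2$freq, sp2$power,
                            min_prominence = max(sp2$power) / 20)
  expect_equal(sort(round(head(pk$freq, 2), 1)), c(4.4, 50), tolerance = 0.1)

  spn <- spectral_density(x8, fs, normalized = TRUE)
  expect_equal(mean(spn$power), 0, tolerance = 1e-10)
  expect_equal(sd(spn$power), 1, tolerance = 1e-10)
})

test_that("white noise produces no peak above a Monte-Carlo prominence threshold", {
  set.seed(42)
  n <- 2048
  # calibrate the null prominence distribution
  null_max <- replicate(40, {
    sp <- spectral_density(rnorm(n), fs)
    pk <- laminarpac:::peak_prominence(sp$power)
    max(pk$prominence) / stats::median(sp$power)
  })
  thr <- quantile(null_max, 0.99)
  sp <- spectral_density(rnorm(n), fs)
  pk <- find_spectral_peaks(sp$freq, sp$power,
                            min_prominence = thr * stats::median(sp$power))
  expect_equal(nrow(pk), 0)
  # and a genuine tone exceeds the same threshold
  spt <- spectral_density(rnorm(n) + 2 * sin(2 * pi * 20 * (1:n) / fs), fs)
  pkt <- find_spectral_peaks(spt$freq, spt$power,
                             min_prominence = thr * stats::median(spt$power))
  expect_gt(nrow(pkt), 0)
})

test_that("band decomposition normalizes amplitudes and discards edges", {
  set.seed(2)
  x <- matrix(rnorm(2 * 4000), ncol = 2)
  bands <- list(alpha = band_definition("alpha", 8, 12),
                gamma = band_definition("gamma", 30, 120))
  dec <- decompose_bands(x, bands, fs = fs)
  expect_lt(dim(dec$amplitude)[1], 4000)
  for (b in 1:2) {
    for (k in 1:2) {
      expect_equal(mean(dec$amplitude[, b, k]), 0, tolerance = 1e-10)
      expect_equal(sd(dec$amplitude[, b, k]), 1, tolerance = 1e-10)
    }
  }
  expect_identical(dec$band_names, c("alpha", "gamma"))
})

test_that("filter bank keeps in-band power and rejects far-band power", {
  set.seed(3)
  n <- 8000
  raw <- rnorm(n + 4000)
  inband <- bandpass(raw, band_definition("alpha", 8, 12), fs)
  x <- as.numeric(inband[2001:(2000 + n)])
  y_alpha <- bandpass(x, band_definition("alpha", 8, 12), fs)
  y_gamma <- bandpass(x, band_definition("gamma", 30, 120), fs)
  mid <- 1000:7000
  expect_gt(var(y_alpha[mid]) / var(x[mid]), 0.8)
  expect_lt(var(y_gamma[mid]) / var(x[mid]), 0.01)
})

test_that("layer LFP sums the excitatory populations of each layer", {
  m <- default_column_model()
  fake <- structure(list(
    x = matrix(seq_len(14 * 5), nrow = 5, byrow = FALSE,
               dimnames = list(NULL, names(default_natural_frequencies()))),
    fs = 1000, model = m), class = "simulation_result")
  lfp <- layer_lfp(fake, m)
  expect_identical(colnames(lfp), c("L2/3", "L4", "L5", "L6"))
  expect_equal(lfp[, "L4"], fake$x[, "L4RS"])
  expect_equal(lfp[, "L2/3"], fake$x[, "L2RS"] + fake$x[, "L2IB"])
  fake0 <- fake
  fake0$x[] <- 0
  expect_true(all(layer_lfp(fake0, m) == 0))
})

test_that("decomposition export writes CSV plus JSON sidecar", {
  set.seed(4)
  x <- matrix(rnorm(2 * 3000), ncol = 2)
  dec <- decompose_bands(x, list(alpha = band_definition("alpha", 8, 12)),
                         fs = fs)
  dir <- tempfile()
  write_decomposition_csv(dec, dir)
  expect_true(file.exists(file.path(dir, "amplitude.csv")))
  expect_true(file.exists(file.path(dir, "phase.csv")))
  meta <- jsonlite::read_json(file.path(dir, "decomposition.json"))
  expect_equal(meta$fs, dec$fs)
  amp <- read.csv(file.path(dir, "amplitude.csv"), check.names = FALSE)
  expect_equal(nrow(amp), dim(dec$amplitude)[1])
  unlink(dir, recursive = TRUE)
})
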