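test_that("modulation index matches closed forms and a brute-force oracle", {
  n <- 1000
  phi <- 2 * pi * (0:(n - 1)) / n - pi  # exact full cycles
  expect_lt(modulation_index(phi, rep(1, n)), 1e-8)
  expect_equal(modulation_index(phi, cos(phi)), n / 2, tolerance = 1e-6)
  set.seed(1)
  a <- rnorm(200); ph <- runif(200, -pi, pi)
  oracle <- sqrt(sum(a * cos(ph))^2 + sum(a * sin(ph))^2)
  expect_equal(modulation_index(ph, a), oracle, tolerance = 1e-12)
  expect_equal(modulation_index(ph, a, normalize = TRUE), oracle / 200)
  expect_error(modulation_index(ph, a[1:10]), "length")
})

test_that("envelope-to-signal correlation hits the corners and stays small under independence", {
  n <- 5000
  phi <- runif(n, -pi, pi)
  expect_equal(esc(phi, cos(phi)), 1)
  expect_equal(esc(phi, -cos(phi)), -1)
  expect_error(esc(rep(0.5, 10), rep(1, 10)), "zero-variance")
  set.seed(2)
  # independence: |ESC| below the 99% permutation-style bound ~ 2.6/sqrt(n)
  n2 <- 1e4
  expect_lt(abs(esc(runif(n2, -pi, pi), rnorm(n2))), 0.05)
})

test_that("discretization is equiprobable for amplitudes and uniform for phases", {
  set.seed(3)
  x <- rexp(1000)  # heavy-tailed
  cd <- discretize_series(x, discretization_scheme(8))
  expect_true(all(table(cd) == 125))
  ph <- c(-pi, -pi / 2, 0, pi / 2, pi - 1e-9)
  cp <- discretize_series(ph, discretization_scheme(4), circular = TRUE)
  expect_identical(as.integer(cp), c(1L, 2L, 3L, 4L, 4L))
  expect_error(discretization_scheme(1))
})

test_that("plug-in cMI matches brute-force summation over exact joint tables", {
  # arbitrary 3-variable joint on small alphabets, sampled exactly
  set.seed(4)
  tab <- array(runif(3 * 2 * 4), c(3, 2, 4))
  tab <- round(tab * 40) / sum(round(tab * 40))
  fx <- generate_fixture("markov_discrete",
                         params = list(table = tab, n = sum(round(tab * 40) *
                                                              1)),
                         seed = 9)
  # regenerate with a sample size that reproduces the table exactly
  counts <- round(tab * 1000)
  tab2 <- counts / sum(counts)
  fx <- generate_fixture("markov_discrete",
                         params = list(table = tab2, n = sum(counts)),
                         seed = 9)
  d <- fx$data
  est <- conditional_mutual_information(d[, 1], d[, 2], list(d[, 3]))
  expect_equal(est, oracle_cmi(tab2), tolerance = 1e-9)
  # chain-rule and direct-definition estimates agree on the same samples
  direct <- oracle_cmi_series(d[, 1], d[, 2], d[, 3])
  expect_equal(est, direct, tolerance = 1e-9)
})

test_that("XOR gives zero pairwise MI but one bit conditionally", {
  fx <- generate_fixture("markov_discrete", params = list(n = 4096), seed = 5)
  d <- fx$data  # v1 = X, v2 = Y = xor(X, Z), v3 = Z
  expect_equal(conditional_mutual_information(d[, 1], d[, 2]), 0,
               tolerance = 1e-9)
  expect_equal(conditional_mutual_information(d[, 1], d[, 2], list(d[, 3])),
               1, tolerance = 1e-9)
})

test_that("chain-rule cMI equals the direct definition on random discrete data", {
  set.seed(6)
  for (rep in 1:10) {
    x <- sample(1:3, 500, replace = TRUE)
    y <- sample(1:4, 500, replace = TRUE)
    z <- sample(1:2, 500, replace = TRUE)
    # induce some dependence
    y[z == 1] <- pmin(4, x[z == 1])
    est <- conditional_mutual_information(x, y, list(z))
    expect_equal(est, oracle_cmi_series(x, y, z), tolerance = 1e-9)
  }
})

test_that("conditioning on an independent series barely changes the cMI", {
  set.seed(7)
  x <- sample(1:4, 6000, replace = TRUE)
  y <- ((x + sample(0:1, 6000, replace = TRUE)) %% 4) + 1
  z <- sample(1:4, 6000, replace = TRUE)
  plain <- conditional_mutual_information(x, y)
  cond <- conditional_mutual_information(x, y, list(z))
  expect_lt(abs(plain - cond), 0.01)
})

test_that("transfer entropy of a binary copy chain is 0.5 bits at two lags", {
  # X a balanced random permutation (exact fair marginal), Y_{t+1} = X_t:
  # delta = 1 carries exactly 1 bit, delta = 2 nothing
  set.seed(8)
  n <- 4096
  x <- sample(rep(0:1, n / 2))
  y <- c(0, x[-n])
  est <- conditional_transfer_entropy(x, y, n_lags = 2, target_past = FALSE)
  expect_equal(est, 0.5, tolerance = 0.02)
  # directionality: nothing flows back from the copy to the iid source
  back <- conditional_transfer_entropy(y, x, n_lags = 2, target_past = FALSE)
  expect_lt(back, 0.01)
  # and independent series carry nothing either way
  ind <- conditional_transfer_entropy(x, sample(rep(0:1, n / 2)), n_lags = 2,
                                      target_past = FALSE)
  expect_lt(ind, 0.01)
})

test_that("conditional TE matches an exact enumeration oracle on a Markov chain", {
  # Y_{t+1} = X_t with probability q, else stays at Y_t; X iid Bernoulli(.5).
  # The analytic I(X_t; Y_{t+1} | Y_t) follows from the stationary joint.
  q <- 0.7
  set.seed(9)
  n <- 2e5
  x <- sample(0:1, n, replace = TRUE)
  y <- integer(n)
  for (t in 1:(n - 1)) {
    y[t + 1] <- if (runif(1) < q) x[t] else y[t]
  }
  est <- conditional_transfer_entropy(x, y, n_lags = 1, target_past = TRUE)
  # oracle: P(Y'|X, Y) = q * [Y' = X] + (1-q) * [Y' = Y]; X fair and
  # independent of the current Y, so within each Y-stratum the X -> Y'
  # channel is binary with known transition probabilities:
  # I(X; Y' | Y) = sum_y P(y) [H(Y'|y) - H(Y'|X, y)]
  p_y1_given_xy <- function(x_, y_) q * (x_ == 1) + (1 - q) * (y_ == 1)
  Hb <- function(p) {
    if (p <= 0 || p >= 1) return(0)
    -p * log2(p) - (1 - p) * log2(1 - p)
  }
  cmi <- 0
  for (y_ in 0:1) {
    p1 <- p_y1_given_xy(1, y_); p0 <- p_y1_given_xy(0, y_)
    pm <- (p1 + p0) / 2
    cmi <- cmi + 0.5 * (Hb(pm) - 0.5 * Hb(p1) - 0.5 * Hb(p0))
  }
  expect_equal(est, cmi, tolerance = 0.01)
})

test_that("coupling specs validate band/feature combinations", {
  sp <- coupling_spec("PAC", "theta", "gamma")
  expect_identical(sp$source_feature, "phase")
  expect_identical(sp$target_feature, "amplitude")
  expect_error(coupling_spec("SFC-amp", "theta", "gamma"), "same band")
  sp2 <- coupling_spec("APC", "gamma", "alpha")
  expect_identical(sp2$source_feature, "amplitude")
})

test_that("planted phase-amplitude coupling is detected and the reverse direction is not", {
  dec <- planted_pac_decomposition(m_depth = 0.8, seed = 1)
  scheme <- discretization_scheme(8)
  pac <- estimate_cfc(dec, coupling_spec("PAC", "theta", "gamma",
                                         n_lags = 10, lag_stride = 40),
                      scheme, conditioning = "target_past",
                      surrogates = surrogate_config(200, seed = 7))
  expect_true(pac$mask["slow", "fast"])
  expect_gt(pac$z["slow", "fast"], 3)
  apc <- estimate_cfc(dec, coupling_spec("APC", "gamma", "theta",
                                         n_lags = 10, lag_stride = 40),
                      scheme, conditioning = "target_past",
                      surrogates = surrogate_config(200, seed = 8))
  expect_false(apc$mask["fast", "slow"])

  # PAC band-order validation
  expect_error(estimate_cfc(dec, coupling_spec("PAC", "gamma", "theta")),
               "source band below")
})

test_that("no modulation means no detection", {
  dec <- planted_pac_decomposition(m_depth = 0, seed = 1)
  pac <- estimate_cfc(dec, coupling_spec("PAC", "theta", "gamma",
                                         n_lags = 10, lag_stride = 40),
                      discretization_scheme(8),
                      conditioning = "target_past",
                      surrogates = surrogate_config(200, seed = 7))
  expect_false(pac$mask["slow", "fast"])
})

test_that("a duplicated channel predicts itself (same-frequency coupling)", {
  set.seed(10)
  n <- 6000
  raw <- rnorm(n + 3000)
  x <- bandpass(raw, band_definition("gamma", 30, 60), 1000)[1501:(1500 + n)]
  d <- cbind(a = as.numeric(x), b = as.numeric(x))
  dec <- decompose_bands(d, list(gamma = band_definition("gamma", 30, 120)),
                         fs = 1000)
  sfc <- estimate_cfc(dec, coupling_spec("SFC-amp", "gamma", "gamma",
                                         n_lags = 5, lag_stride = 20),
                      discretization_scheme(6),
                      conditioning = "none",
                      surrogates = surrogate_config(200, seed = 3))
  expect_true(sfc$mask["a", "b"])
  expect_gt(sfc$values["a", "b"], 0)
})

test_that("nearest-neighbour cMI approximates known Gaussian information", {
  set.seed(11)
  n <- 1200
  rho <- 0.6
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  truth <- -0.5 * log2(1 - rho^2)
  expect_equal(knn_cmi(x, y, k = 5), truth, tolerance = 0.08)
  # conditional: X -> Z -> Y, so I(X;Y|Z) ~ 0
  z <- 0.9 * x + sqrt(1 - 0.81) * rnorm(n)
  y2 <- 0.9 * z + sqrt(1 - 0.81) * rnorm(n)
  expect_lt(abs(knn_cmi(x, y2, list(z), k = 5)), 0.06)
})

test_that("coupling matrices serialize to CSV with a JSON sidecar", {
  dec <- planted_pac_decomposition(m_depth = 0.8, seed = 2, duration = 6)
  res <- estimate_cfc(dec, coupling_spec("PAC", "theta", "gamma",
                                         n_lags = 5, lag_stride = 20),
                      discretization_scheme(4),
                      surrogates = surrogate_config(100, seed = 1))
  dir <- tempfile()
  path <- write_cfc_csv(res, dir)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("\\.csv$", ".json", path)))
  back <- as.matrix(read.csv(path, row.names = 1))
  expect_equal(unname(back),
               unname(res$values * ifelse(is.na(res$mask), 1, res$mask)),
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
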