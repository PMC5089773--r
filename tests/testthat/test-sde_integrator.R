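test_that("uncoupled noise-free trajectories settle at the fixed point", {
  pops <- list(population_spec("L4RS", G = 3.25, g = 100, b = 1,
                               p_mean = 120))
  m <- column_model(pops, matrix(0, 1, 1))
  r <- simulate_column(m, simulation_config(dt = 1e-4, duration = 1,
                                            burn_in = 0.9),
                       init = model_state(0, 0))
  expect_equal(unname(tail(r$x[, 1], 1)), 3.9, tolerance = 1e-6)
})

test_that("local linearization is exact on a linear system", {
  g <- 2 * pi * 10; b <- 0.2; dt <- 0.01
  pops <- list(population_spec("L4RS", G = 3.25, g = g, b = b))
  m <- column_model(pops, matrix(0, 1, 1))
  st <- model_state(1, 0)
  s1 <- step_local_linearization(st, m, dt)
  A <- matrix(c(0, 1, -g^2, -2 * g * b), 2, 2, byrow = TRUE)
  ev <- eigen(A)
  E <- Re(ev$vectors %*% diag(exp(ev$values * dt)) %*% solve(ev$vectors))
  ex <- E %*% c(1, 0)
  expect_equal(s1$x, ex[1], tolerance = 1e-10)
  expect_equal(s1$y, ex[2], tolerance = 1e-10)

  # multi-step propagation of the full linear system matches the closed form
  r <- simulate_column(m, simulation_config(dt = 1e-3, duration = 0.5,
                                            burn_in = 0),
                       init = st, linear_sigmoid = TRUE)
  Efull <- Re(ev$vectors %*% diag(exp(ev$values * 0.25)) %*% solve(ev$vectors))
  expect_equal(unname(r$x[250, 1]), (Efull %*% c(1, 0))[1], tolerance = 1e-8)
})

test_that("zero drift leaves the state unchanged; scalar decay matches exp", {
  pops <- list(population_spec("L4RS", G = 3.25, g = 100, b = 1,
                               p_mean = 120))
  m <- column_model(pops, matrix(0, 1, 1))
  st <- model_state(3.9, 0)  # fixed point
  s1 <- step_local_linearization(st, m, 0.05)
  expect_equal(s1$x, 3.9, tolerance = 1e-12)
  expect_equal(s1$y, 0, tolerance = 1e-10)
})

test_that("trajectories are bit-identical under a fixed seed", {
  m <- chain3_model(p_sigma = 5)
  cfg <- simulation_config(dt = 1e-3, duration = 1, burn_in = 0.5, seed = 11)
  r1 <- simulate_column(m, cfg)
  r2 <- simulate_column(m, cfg)
  expect_identical(r1$x, r2$x)
  r3 <- simulate_column(m, simulation_config(dt = 1e-3, duration = 1,
                                             burn_in = 0.5, seed = 12))
  expect_false(identical(r1$x, r3$x))
})

test_that("self-convergence under step halving is consistent with the scheme orders", {
  # deterministic nonlinear run: error vs a fine reference should shrink by
  # ~4x per halving for the locally linearized scheme (order 2) and ~2x for
  # the explicit Euler scheme (order 1)
  pops <- list(population_spec("L4RS", G = 3.25, g = 20, b = 0.3,
                               p_mean = 15),
               population_spec("L4FS", G = 8, g = 35, b = 0.4))
  gam <- matrix(c(10, 18, -18, 0), 2, 2, byrow = TRUE)
  m <- column_model(pops, gam)
  run_last <- function(dt, method) {
    r <- simulate_column(m, simulation_config(dt = dt, duration = 0.4,
                                              burn_in = 0, method = method),
                         init = model_state(c(4, 5), c(0, 0)))
    r$x[nrow(r$x), ]
  }
  for (method in c("local_linearization", "euler_maruyama")) {
    ref <- run_last(2.5e-5, method)
    e1 <- max(abs(run_last(4e-4, method) - ref))
    e2 <- max(abs(run_last(2e-4, method) - ref))
    ratio <- e1 / e2
    if (method == "local_linearization") {
      expect_gt(ratio, 2.5)
    } else {
      expect_gt(ratio, 1.6)
      expect_lt(ratio, 3.5)
    }
  }
})

test_that("the two schemes agree at small steps on a stochastic run", {
  m <- chain3_model(p_sigma = 5)
  r_ll <- simulate_column(m, simulation_config(dt = 1e-4, duration = 1.2,
                                               burn_in = 0.2, seed = 3))
  r_em <- simulate_column(m, simulation_config(dt = 1e-4, duration = 1.2,
                                               burn_in = 0.2, seed = 3,
                                               method = "euler_maruyama"))
  expect_gt(cor(r_ll$x[, 2], r_em$x[, 2]), 0.999)
})

test_that("divergence aborts with a diagnostic", {
  # strong positive linear self-feedback is unstable
  pops <- list(population_spec("L4RS", G = 3.25, g = 100, b = 0.1,
                               p_mean = 0))
  m <- column_model(pops, matrix(500, 1, 1))
  expect_error(
    simulate_column(m, simulation_config(dt = 1e-3, duration = 5,
                                         burn_in = 0, diverge_bound = 1e3),
                    init = model_state(1, 0), linear_sigmoid = TRUE),
    "diverged")
})

test_that("simulated output length and sampling follow the configuration", {
  m <- chain3_model(p_sigma = 2)
  r <- simulate_column(m, simulation_config(dt = 1e-3, duration = 2,
                                            burn_in = 0.5, seed = 1))
  expect_equal(nrow(r$x), (2 - 0.5) / 1e-3)
  expect_equal(r$fs, 1000)
  expect_false(any(!is.finite(r$x)))
})

test_that("chain simulations show amplitude-modulated (waxing and waning) rhythms", {
  m <- chain3_model(p_sigma = 10)
  r <- simulate_column(m, simulation_config(dt = 1e-4, duration = 6,
                                            burn_in = 2, seed = 4))
  dec <- decompose_bands(r, list(gamma = band_definition("gamma", 30, 120)),
                         downsample_to = 1000, normalize = FALSE)
  for (k in 1:3) {
    a <- dec$amplitude[, 1, k]
    expect_gt(sd(a) / mean(a), 0.1)
  }
})

test_that("simulation CSV round-trips at double precision", {
  m <- chain3_model(p_sigma = 2)
  r <- simulate_column(m, simulation_config(dt = 1e-3, duration = 1,
                                            burn_in = 0.5, seed = 2))
  path <- tempfile(fileext = ".csv")
  write_simulation_csv(r, path)
  back <- read_simulation_csv(path)
  expect_equal(back$x, r$x, tolerance = 1e-15)
  expect_equal(back$t, r$t, tolerance = 1e-12)
  expect_equal(back$fs, r$fs, tolerance = 1e-6)
  unlink(path)
})
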