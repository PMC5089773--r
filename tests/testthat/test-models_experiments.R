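test_that("the default column hits the published natural frequencies with the right ordering", {
  m <- default_column_model()
  fnat <- default_natural_frequencies()
  for (p in m$populations) {
    expect_equal(natural_frequency(p), unname(fnat[p$name]),
                 tolerance = 1e-10)
  }
  # FS fastest, then IB, RS, LTS (reciprocal time constants)
  g_of <- function(cls) {
    mean(vapply(Filter(function(p) p$cell_class == cls, m$populations),
                `[[`, numeric(1), "g"))
  }
  expect_true(g_of("FS") > g_of("IB"))
  expect_true(g_of("IB") > g_of("RS"))
  expect_true(g_of("RS") > g_of("LTS"))
  # external input only reaches layer-4 RS and FS
  driven <- vapply(m$populations, function(p) p$p_mean != 0 | p$p_sigma > 0,
                   logical(1))
  expect_identical(vapply(m$populations, `[[`, character(1),
                          "name")[driven], c("L4RS", "L4FS"))
})

test_that("eta scales the connectivity globally", {
  m1 <- default_column_model(eta = 1)
  m2 <- default_column_model(eta = 0.5)
  expect_equal(m2$gamma, m1$gamma * 0.5)
})

test_that("chain3 has the control architecture (2 drives 1 and 3, no 1-3 link)", {
  m <- chain3_model()
  g <- unname(m$gamma)
  expect_gt(g[2, 1], 0)
  expect_gt(g[2, 3], 0)
  expect_equal(g[1, 3], 0)
  expect_equal(g[3, 1], 0)
  expect_equal(g[1, 2], 0)
  expect_equal(g[3, 2], 0)
})

test_that("model files round-trip through JSON, YAML and gamma CSV", {
  m <- chain3_model()
  p1 <- tempfile(fileext = ".json")
  write_model_file(m, p1)
  m1 <- read_model_file(p1)
  expect_equal(m1$gamma, m$gamma, tolerance = 1e-12)
  expect_equal(m1$populations[[2]]$g, m$populations[[2]]$g)

  p2 <- tempfile(fileext = ".json")
  write_model_file(m, p2, gamma_csv = "gamma.csv")
  m2 <- read_model_file(p2)
  expect_equal(unname(m2$gamma), unname(m$gamma), tolerance = 1e-10)

  p3 <- tempfile(fileext = ".yaml")
  write_model_file(m, p3)
  m3 <- read_model_file(p3)
  expect_equal(m3$populations[[1]]$p_mean, m$populations[[1]]$p_mean)
  unlink(c(p1, p2, p3))
})

test_that("fixtures are reproducible and carry their ground truth", {
  f1 <- generate_fixture("am_coupled", params = list(duration = 2), seed = 9)
  f2 <- generate_fixture("am_coupled", params = list(duration = 2), seed = 9)
  expect_identical(f1$data, f2$data)
  expect_equal(f1$truth$m, 0.8)
  f3 <- generate_fixture("am_coupled", params = list(duration = 2), seed = 10)
  expect_false(identical(f1$data, f3$data))
  expect_error(generate_fixture("bogus"), "arg")

  dir <- tempfile()
  generate_fixture("null_noise", params = list(duration = 1), seed = 1,
                   dir = dir)
  expect_true(file.exists(file.path(dir, "data.csv")))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(truth$coupling, "none")
  unlink(dir, recursive = TRUE)
})

test_that("exact discrete fixtures reproduce their joint table", {
  fx <- generate_fixture("markov_discrete", params = list(n = 4096), seed = 2)
  d <- fx$data
  emp <- table(d[, 1], d[, 2], d[, 3]) / nrow(d)
  expect_equal(as.numeric(emp), as.numeric(fx$truth$table),
               tolerance = 1e-12)
})

test_that("grid strings parse and reject malformed input", {
  expect_equal(parse_grid("0.03:0.03:0.09"), c(0.03, 0.06, 0.09))
  expect_equal(length(parse_grid("5:5:500")), 100)
  expect_error(parse_grid("1:0:5"), "positive step")
  expect_error(parse_grid("1-5"), "grid")
})

test_that("a scaled-down sweep runs end to end and emits the summary schema", {
  out <- run_sweep(param = "eta", grid = c(0.8, 1.2, 1.6, 2.0),
                   combos = "theta-gamma", seed = 2, scale = "smoke",
                   out_dir = tempfile())
  expect_true(all(c("param", "value", "combo", "strongest",
                    "n_significant", "n_direct", "n_indirect") %in%
                    names(out$table)))
  expect_true(all(out$table$strongest >= 0))
  expect_true(is.list(out$correlations))
  expect_true("theta-gamma" %in% names(out$correlations))
})

test_that("the sweep rejects unknown parameters and empty grids", {
  expect_error(run_sweep(param = "nope", grid = 1), "unknown sweep")
  expect_error(run_sweep(grid = numeric(0)), "empty")
})

test_that("the cascade driver produces R-squared profiles for all ten models", {
  out <- run_cascade("I", grid12 = c(120, 240, 360),
                     grid23 = c(120, 240, 360), seed = 3, scale = "smoke")
  expect_equal(sort(unique(out$r2$model)), sort(names(cascade_models("I"))))
  expect_equal(nrow(out$r2), 10 * 3)
  ok <- is.finite(out$r2$R2)
  expect_true(all(out$r2$R2[ok] >= -1e-9 & out$r2$R2[ok] <= 1 + 1e-9))
  expect_length(out$predictors, 16)
})

test_that("the full-column experiment reports spectra, LFP power and coupling roles", {
  out <- run_full_column(combos = "theta-gamma", seed = 2, scale = "smoke")
  expect_length(out$spectra, 14)
  expect_equal(dim(out$lfp_power), c(5, 4))  # five bands x four layers
  expect_true(all(is.finite(out$lfp_power)))
  expect_s3_class(out$pac[["theta-gamma"]], "cfc_result")
  expect_equal(dim(out$pac[["theta-gamma"]]$values), c(14, 14))
  expect_true(all(c("clustering", "efficiency", "betweenness") %in%
                    names(out$topology)))
  if (nrow(out$roles$entries) > 0) {
    expect_true(all(out$roles$entries$role %in% c("direct", "indirect")))
  }
})

test_that("the command-line entry point runs and writes outputs", {
  cli <- system.file("cli", "laminarpac.R", package = "laminarpac")
  expect_true(nzchar(cli))
  out <- tempfile()
  res <- system2("Rscript", c(cli, "topology", "--out", out),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "topology.csv")))
  tm <- read.csv(file.path(out, "topology.csv"))
  expect_equal(nrow(tm), 14)
  unlink(out, recursive = TRUE)
})
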