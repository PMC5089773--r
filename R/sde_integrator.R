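#' Simulation configuration
#'
#' Fixed-step integration settings for the column model's random differential
#' system. External input noise is realized as a normal draw held constant
#' within each step (random-differential-equation convention, not an Ito
#' SDE), so trajectories are differentiable between steps.
#'
#' @param dt integration step, s.
#' @param duration total simulated time, s.
#' @param burn_in initial span discarded from the returned trajectories, s.
#' @param seed integer RNG seed (`NULL` leaves the RNG state alone).
#' @param method `"local_linearization"` (default; exact on linear drift) or
#'   `"euler_maruyama"` (first-order cross-check scheme).
#' @param diverge_bound simulation aborts with a diagnostic when any |PSP|
#'   exceeds this bound, mV.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 1e-4, duration = 12, burn_in = 2,
                              seed = NULL,
                              method = c("local_linearization", "euler_maruyama"),
                              diverge_bound = 1e4) {
  method <- match.arg(method)
  stopifnot(dt > 0, duration > 0, burn_in >= 0, burn_in < duration,
            diverge_bound > 0)
  structure(list(dt = dt, duration = duration, burn_in = burn_in,
                 seed = seed, method = method, diverge_bound = diverge_bound),
            class = "simulation_config")
}

#' Simulate the column model
#'
#' Integrates the 2P-equation first-order system with per-step constant
#' noise. Initial conditions default to the noise-free uncoupled fixed point
#' with zero derivatives; the burn-in span is discarded so the returned
#' trajectories are free of the initial transient.
#'
#' @param model a [column_model()].
#' @param config a [simulation_config()].
#' @param init optional [model_state()] initial condition.
#' @param linear_sigmoid if `TRUE` the sigmoid is replaced by the identity,
#'   making the system linear (control analysis for the origin of
#'   cross-frequency coupling).
#' @return An object of class `simulation_result`: `t` (time grid, s),
#'   `x` (time-by-population PSP matrix, mV), `fs` (sampling rate, Hz),
#'   plus the config and model.
#' @export
simulate_column <- function(model, config = simulation_config(), init = NULL,
                            linear_sigmoid = FALSE) {
  stopifnot(inherits(model, "column_model"),
            inherits(config, "simulation_config"))
  pv <- model_par_vectors(model)
  P <- length(pv$G)
  nsteps <- round(config$duration / config$dt)
  nburn <- round(config$burn_in / config$dt)
  if (!is.null(config$seed)) set.seed(config$seed)
  noise <- matrix(0, nsteps, P)
  active <- which(pv$p_sigma > 0)
  if (length(active)) {
    noise[, active] <- rnorm(nsteps * length(active))
  }
  if (is.null(init)) {
    init <- model_state(uncoupled_fixed_point(model), rep(0, P))
  }
  stopifnot(inherits(init, "model_state"), length(init$x) == P)
  res <- nmm_integrate_cpp(init$x, init$y, pv$G, pv$g, pv$b, model$gamma,
                           pv$e0, pv$v0, pv$r, pv$p_mean, pv$p_sigma, noise,
                           config$dt, linear_sigmoid,
                           if (config$method == "local_linearization") 0L else 1L,
                           config$diverge_bound)
  if (res$n_fallback > 0) {
    warning(res$n_fallback,
            " local-linearization steps fell back to an Euler update",
            " (ill-conditioned linearization)")
  }
  keep <- (nburn + 1):nsteps + 1L  # row 1 is t = 0
  x <- res$x[keep, , drop = FALSE]
  colnames(x) <- pv$names
  structure(list(
    t = (nburn + 1):nsteps * config$dt,
    x = x,
    fs = 1 / config$dt,
    config = config,
    model = model,
    final_state = model_state(res$x[nsteps + 1, ], res$y[nsteps + 1, ])
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("simulation_result:", ncol(x$x), "populations,", nrow(x$x),
      "samples at", x$fs, "Hz (", x$config$method, ")\n")
  invisible(x)
}

#' Single local-linearization step
#'
#' Advances the state one step of length `dt` holding the external input at
#' `p_mean + p_sigma * noise_draw`. Reduces to exact matrix-exponential
#' propagation when the drift is linear; an ill-conditioned linearization
#' falls back to an Euler update with a warning.
#'
#' @param state a [model_state()].
#' @param model a [column_model()].
#' @param dt step, s.
#' @param noise_draw standard-normal draws, one per population (recycled).
#' @param linear_sigmoid see [simulate_column()].
#' @return The advanced `model_state`.
#' @export
step_local_linearization <- function(state, model, dt, noise_draw = 0,
                                     linear_sigmoid = FALSE) {
  stopifnot(inherits(state, "model_state"), inherits(model, "column_model"),
            dt > 0)
  pv <- model_par_vectors(model)
  P <- length(pv$G)
  noise_draw <- rep_len(noise_draw, P)
  p <- pv$p_mean + pv$p_sigma * noise_draw
  out <- nmm_step_cpp(state$x, state$y, pv$G, pv$g, pv$b, model$gamma,
                      pv$e0, pv$v0, pv$r, p, dt, linear_sigmoid, 0L)
  if (!out$ll_ok) {
    warning("ill-conditioned linearization; fell back to an Euler update")
  }
  model_state(as.numeric(out$x), as.numeric(out$y))
}

#' Write / read simulated trajectories as CSV
#'
#' The CSV holds the time grid in column `t` and one column per population;
#' values round-trip at full double precision.
#'
#' @param result a [simulate_column()] result.
#' @param path output file.
#' @return `write_simulation_csv` returns `path` invisibly;
#'   `read_simulation_csv` returns a list with `t`, `x` and `fs`.
#' @export
write_simulation_csv <- function(result, path) {
  df <- data.frame(t = result$t, result$x, check.names = FALSE)
  write.csv(format(df, digits = 17, trim = TRUE), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_simulation_csv
#' @export
read_simulation_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  t <- df$t
  x <- as.matrix(df[, setdiff(names(df), "t"), drop = FALSE])
  fs <- if (length(t) > 1) 1 / stats::median(diff(t)) else NA_real_
  list(t = t, x = x, fs = fs)
}
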