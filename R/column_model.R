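#' Sigmoid (potential-to-rate) parameters
#'
#' Parameters of the sigmoid converting a population's mean postsynaptic
#' potential (PSP) into a mean firing rate: `e0` is the maximal rate (1/s),
#' `v0` the PSP at half-maximal rate (mV) and `r` the steepness (1/mV).
#' The defaults are the values in standard use for neural mass models of
#' EEG rhythms.
#'
#' @param e0 maximal firing rate, 1/s. Must be positive.
#' @param v0 PSP of half-maximal firing, mV.
#' @param r steepness, 1/mV. Must be positive.
#' @return An object of class `sigmoid_params`.
#' @export
sigmoid_params <- function(e0 = 5, v0 = 6, r = 0.56) {
  stopifnot(is.numeric(e0), length(e0) == 1, e0 > 0,
            is.numeric(v0), length(v0) == 1,
            is.numeric(r), length(r) == 1, r > 0)
  structure(list(e0 = e0, v0 = v0, r = r), class = "sigmoid_params")
}

#' Sigmoid potential-to-rate conversion
#'
#' `S(x) = e0 / (1 + exp(r (v0 - x)))`. Strictly increasing, bounded in
#' `(0, e0)`, with `S(v0) = e0/2`.
#'
#' @param x PSP values, mV.
#' @param params a [sigmoid_params()] object.
#' @return Firing rates, 1/s.
#' @export
sigmoid <- function(x, params = sigmoid_params()) {
  stopifnot(inherits(params, "sigmoid_params"))
  params$e0 / (1 + exp(params$r * (params$v0 - x)))
}

#' Synaptic impulse response
#'
#' The PSP kernel `h(t) = G g t exp(-g t)` for `t >= 0` converting a firing
#' rate input into a PSP: `G` scales the maximum PSP amplitude and `g` is the
#' reciprocal of the lumped synaptic/dendritic time constant. The kernel peaks
#' at `t = 1/g` with value `G/e` and integrates to `G/g`.
#'
#' @param t time, s (non-negative).
#' @param G gain, mV.
#' @param g reciprocal time constant, 1/s.
#' @return Kernel values.
#' @export
impulse_response <- function(t, G, g) {
  if (any(t < 0)) stop("impulse_response is defined for t >= 0")
  G * g * t * exp(-g * t)
}

valid_population_names <- c("L2RS", "L2IB", "L2LTS", "L2FS",
                            "L4RS", "L4LTS", "L4FS",
                            "L5RS", "L5IB", "L5LTS", "L5FS",
                            "L6RS", "L6LTS", "L6FS")

#' One neuronal population's physiological parameters
#'
#' @param name population label, e.g. `"L4RS"`; layer and cell class are
#'   parsed from it (layer L2 stands for layer 2/3).
#' @param G PSP gain, mV (positive).
#' @param g reciprocal time constant, 1/s (positive).
#' @param b dimensionless damping; `b < 1` lets the isolated population ring
#'   at its natural frequency, `b = 1` is the critically damped
#'   (Jansen-Rit) regime.
#' @param p_mean mean external input rate, 1/s.
#' @param p_sigma external input noise SD, 1/s (non-negative).
#' @param sigmoid a [sigmoid_params()] object.
#' @return An object of class `population_spec` with fields `layer`,
#'   `cell_class` and `excitatory` derived from `name`.
#' @export
population_spec <- function(name, G, g, b = 1, p_mean = 0, p_sigma = 0,
                            sigmoid = sigmoid_params()) {
  stopifnot(is.character(name), length(name) == 1)
  m <- regmatches(name, regexec("^(L[2456])(RS|IB|LTS|FS)$", name))[[1]]
  if (length(m) != 3) {
    stop("population name must be layer (L2/L4/L5/L6) + class (RS/IB/LTS/FS): ",
         name)
  }
  stopifnot(G > 0, g > 0, b >= 0, p_sigma >= 0,
            inherits(sigmoid, "sigmoid_params"))
  cls <- m[3]
  G <- unname(G); g <- unname(g); b <- unname(b)
  p_mean <- unname(p_mean); p_sigma <- unname(p_sigma)
  structure(list(
    name = name,
    layer = if (m[2] == "L2") "L2/3" else m[2],
    cell_class = cls,
    excitatory = cls %in% c("RS", "IB"),
    G = G, g = g, b = b, p_mean = p_mean, p_sigma = p_sigma,
    sigmoid = sigmoid
  ), class = "population_spec")
}

#' Natural frequency of an isolated population
#'
#' For an uncoupled, noise-free population the homogeneous dynamics are a
#' damped harmonic oscillator: underdamped populations (`b < 1`) ring at
#' `g sqrt(1 - b^2) / (2 pi)` Hz; for `b >= 1` there is no oscillation and
#' `NA` is returned.
#'
#' @param pop a [population_spec()] object.
#' @return Frequency in Hz, or `NA` if critically/over-damped.
#' @export
natural_frequency <- function(pop) {
  stopifnot(inherits(pop, "population_spec"))
  if (pop$b >= 1) return(NA_real_)
  pop$g * sqrt(1 - pop$b^2) / (2 * pi)
}

#' Assemble a column model
#'
#' A column model is an ordered list of populations plus the signed effective
#' connectivity matrix `gamma` with `gamma[n, m]` the weight of the connection
#' from source population `n` to target population `m`. Connections from
#' inhibitory populations (LTS/FS) must be non-positive and from excitatory
#' populations (RS/IB) non-negative; self-connections are allowed.
#'
#' @param populations list of [population_spec()] objects.
#' @param gamma square numeric matrix, one row/column per population
#'   (source in rows, target in columns).
#' @return An object of class `column_model`.
#' @export
column_model <- function(populations, gamma) {
  stopifnot(is.list(populations), length(populations) >= 1,
            all(vapply(populations, inherits, logical(1), "population_spec")))
  P <- length(populations)
  gamma <- as.matrix(gamma)
  if (nrow(gamma) != P || ncol(gamma) != P) {
    stop("gamma must be a ", P, "x", P, " matrix matching the population count")
  }
  nm <- vapply(populations, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicated population names")
  for (n in seq_len(P)) {
    out_n <- gamma[n, ]
    if (populations[[n]]$excitatory && any(out_n < 0)) {
      stop("excitatory source ", nm[n], " has negative outgoing weights")
    }
    if (!populations[[n]]$excitatory && any(out_n > 0)) {
      stop("inhibitory source ", nm[n], " has positive outgoing weights")
    }
  }
  dimnames(gamma) <- list(nm, nm)
  structure(list(populations = populations, gamma = gamma),
            class = "column_model")
}

#' @export
print.column_model <- function(x, ...) {
  P <- length(x$populations)
  cat("column_model:", P, "populations,", 2 * P, "first-order state equations\n")
  df <- model_parameter_table(x)
  print(df, row.names = FALSE)
  cat("connections (nonzero gamma entries):", sum(x$gamma != 0), "\n")
  invisible(x)
}

#' Tabulate model parameters
#'
#' @param model a [column_model()].
#' @return A data frame, one row per population.
#' @export
model_parameter_table <- function(model) {
  stopifnot(inherits(model, "column_model"))
  do.call(rbind, lapply(model$populations, function(p) {
    data.frame(name = p$name, layer = p$layer, class = p$cell_class,
               excitatory = p$excitatory, G = p$G, g = p$g, b = p$b,
               p_mean = p$p_mean, p_sigma = p$p_sigma,
               f_nat = if (p$b < 1) p$g * sqrt(1 - p$b^2) / (2 * pi) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

# parameter vectors in matrix form for the C++ integrator
model_par_vectors <- function(model) {
  pops <- model$populations
  list(G = vapply(pops, `[[`, numeric(1), "G"),
       g = vapply(pops, `[[`, numeric(1), "g"),
       b = vapply(pops, `[[`, numeric(1), "b"),
       p_mean = vapply(pops, `[[`, numeric(1), "p_mean"),
       p_sigma = vapply(pops, `[[`, numeric(1), "p_sigma"),
       e0 = vapply(pops, function(p) p$sigmoid$e0, numeric(1)),
       v0 = vapply(pops, function(p) p$sigmoid$v0, numeric(1)),
       r = vapply(pops, function(p) p$sigmoid$r, numeric(1)),
       names = vapply(pops, `[[`, character(1), "name"))
}

#' Model state
#'
#' @param x PSP vector, mV.
#' @param y PSP derivative vector, mV/s.
#' @return An object of class `model_state`.
#' @export
model_state <- function(x, y = rep(0, length(x))) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  structure(list(x = as.numeric(x), y = as.numeric(y)), class = "model_state")
}

#' Deterministic right-hand side of the column dynamics
#'
#' The 2P-equation first-order form: `dx/dt = y` and
#' `dy/dt = -2 g b y - g^2 x + G g (p + t(gamma) S(x))`, evaluated at a given
#' state and instantaneous external input.
#'
#' @param state a [model_state()].
#' @param model a [column_model()].
#' @param p instantaneous external input rates, 1/s (recycled if scalar).
#' @param linear_sigmoid replace `S(x)` with the identity (used to verify that
#'   cross-frequency coupling requires the sigmoid nonlinearity).
#' @return A `model_state` holding the time derivatives (`x` slot = dx/dt,
#'   `y` slot = dy/dt).
#' @export
column_rhs <- function(state, model, p = NULL, linear_sigmoid = FALSE) {
  stopifnot(inherits(state, "model_state"), inherits(model, "column_model"))
  pv <- model_par_vectors(model)
  P <- length(pv$G)
  if (length(state$x) != P) stop("state dimension does not match model")
  if (is.null(p)) p <- pv$p_mean
  if (length(p) == 1) p <- rep(p, P)
  if (length(p) != P) stop("input vector p has wrong length")
  sx <- if (linear_sigmoid) state$x else {
    vapply(seq_len(P), function(i) {
      model$populations[[i]]$sigmoid$e0 /
        (1 + exp(model$populations[[i]]$sigmoid$r *
                   (model$populations[[i]]$sigmoid$v0 - state$x[i])))
    }, numeric(1))
  }
  dx <- state$y
  dy <- -2 * pv$g * pv$b * state$y - pv$g^2 * state$x +
    pv$G * pv$g * (p + as.numeric(t(model$gamma) %*% sx))
  structure(list(x = dx, y = dy), class = "model_state")
}

#' Noise-free uncoupled fixed point
#'
#' With all inter-population connections ignored and no noise, each
#' population settles (or rings down) to `x* = G (p_mean + gamma_mm S(x*)) / g`;
#' solved by fixed-point iteration including the self-connection.
#'
#' @param model a [column_model()].
#' @param max_iter,tol iteration controls.
#' @return PSP vector at the fixed point, mV.
#' @export
uncoupled_fixed_point <- function(model, max_iter = 500, tol = 1e-12) {
  pv <- model_par_vectors(model)
  P <- length(pv$G)
  x <- pv$G * pv$p_mean / pv$g
  for (it in seq_len(max_iter)) {
    sx <- vapply(seq_len(P), function(i) {
      s <- model$populations[[i]]$sigmoid
      s$e0 / (1 + exp(s$r * (s$v0 - x[i])))
    }, numeric(1))
    x_new <- pv$G * (pv$p_mean + diag(model$gamma) * sx) / pv$g
    if (max(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  x
}
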