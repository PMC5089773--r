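#' Synthetic test fixtures with known ground truth
#'
#' Reproducible generators for the signal classes used throughout testing:
#' \describe{
#'   \item{`am_coupled`}{two channels: a stochastic narrowband slow signal
#'     (band-limited noise, so its phase has finite coherence time) and a
#'     fast carrier whose amplitude is modulated by the slow channel's
#'     (optionally delayed) phase, `x(t) = (1 + m cos(phi_slow(t - lag)))
#'     cos(2 pi f_fast t) + noise`. Planted phase-amplitude coupling of
#'     known depth `m`.}
#'   \item{`chain3`}{a simulation of the three-population chain
#'     ([chain3_model()]): population 2 drives 1 and 3, no 1-3 connection.}
#'   \item{`markov_discrete`}{iid samples from a stored joint probability
#'     table over small alphabets; with `exact = TRUE` the empirical
#'     frequencies equal the table exactly, enabling closed-form
#'     information-theoretic oracles.}
#'   \item{`null_noise`}{independent white-noise channels (no coupling).}
#' }
#'
#' @param kind fixture kind.
#' @param params named list of parameters overriding the kind's defaults
#'   (see Details in the source; e.g. `m`, `f_slow`, `f_fast`, `fs`,
#'   `duration`, `noise_sd`, `lag_s` for `am_coupled`; `table` (array of
#'   probabilities), `n` for `markov_discrete`; `n_channels`, `fs`,
#'   `duration` for `null_noise`; any [chain3_model()] /
#'   [simulation_config()] argument for `chain3`).
#' @param seed integer RNG seed.
#' @param dir if non-`NULL`, data are written as CSV and the ground truth as
#'   a JSON sidecar (`truth.json`) in this directory.
#' @return List with `data` (matrix or data frame), `truth` (ground-truth
#'   description) and `fs` where applicable.
#' @export
generate_fixture <- function(kind = c("am_coupled", "chain3",
                                      "markov_discrete", "null_noise"),
                             params = list(), seed = 1, dir = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  out <- switch(kind,
    am_coupled = {
      p <- modifyList(list(m = 0.8, f_slow = 5, f_fast = 50, fs = 1000,
                           duration = 10, noise_sd = 0.3, slow_bw = 1,
                           lag_s = 0.04), params)
      n <- round(p$duration * p$fs)
      lagn <- round(p$lag_s * p$fs)
      pad <- 4 * p$fs
      raw <- rnorm(n + pad + lagn)
      band <- band_definition("slow", p$f_slow - p$slow_bw,
                              p$f_slow + p$slow_bw)
      slow <- bandpass(raw, band, p$fs)[(pad / 2 + 1):(pad / 2 + n + lagn)]
      slow <- slow / sd(slow)
      phs <- analytic_decompose(slow)$phase
      carrier <- cos(2 * pi * p$f_fast * (1:n) / p$fs + runif(1) * 2 * pi)
      fast <- (1 + p$m * cos(phs[1:n])) * carrier + p$noise_sd * rnorm(n)
      slow_now <- slow[(lagn + 1):(lagn + n)] + p$noise_sd * rnorm(n)
      list(data = cbind(slow = slow_now, fast = fast), fs = p$fs,
           truth = list(kind = kind, coupling = "slow phase -> fast amplitude",
                        m = p$m, f_slow = p$f_slow, f_fast = p$f_fast,
                        lag_s = p$lag_s, seed = seed))
    },
    chain3 = {
      model_args <- params[names(params) %in% names(formals(chain3_model))]
      sim_args <- params[names(params) %in% names(formals(simulation_config))]
      model <- do.call(chain3_model, model_args)
      cfg <- do.call(simulation_config, c(sim_args, list(seed = seed)))
      r <- simulate_column(model, cfg)
      list(data = r$x, fs = r$fs, model = model, result = r,
           truth = list(kind = kind,
                        connections = c("2->1", "2->3"),
                        absent = c("1->3", "3->1"), seed = seed))
    },
    markov_discrete = {
      p <- modifyList(list(table = NULL, n = 4096, exact = TRUE), params)
      if (is.null(p$table)) {
        # default: XOR triple, X and Z iid fair bits, Y = xor(X, Z)
        tab <- array(0, c(2, 2, 2))
        for (x in 0:1) for (z in 0:1) tab[x + 1, (bitwXor(x, z)) + 1, z + 1] <- 0.25
        p$table <- tab
      }
      tab <- p$table / sum(p$table)
      cells <- which(tab > 0, arr.ind = TRUE)
      probs <- tab[tab > 0]
      if (p$exact) {
        counts <- round(probs * p$n)
        idx <- rep(seq_len(nrow(cells)), counts)
        idx <- sample(idx)  # shuffle order; joint counts stay exact
      } else {
        idx <- sample(seq_len(nrow(cells)), p$n, replace = TRUE, prob = probs)
      }
      d <- cells[idx, , drop = FALSE]
      colnames(d) <- paste0("v", seq_len(ncol(d)))
      list(data = d, truth = list(kind = kind, table = tab,
                                  exact = p$exact, seed = seed))
    },
    null_noise = {
      p <- modifyList(list(n_channels = 3, fs = 1000, duration = 10), params)
      n <- round(p$duration * p$fs)
      d <- matrix(rnorm(n * p$n_channels), n, p$n_channels,
                  dimnames = list(NULL, paste0("ch", seq_len(p$n_channels))))
      list(data = d, fs = p$fs,
           truth = list(kind = kind, coupling = "none", seed = seed))
    })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(as.data.frame(out$data), file.path(dir, "data.csv"),
              row.names = FALSE)
    jsonlite::write_json(out$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
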