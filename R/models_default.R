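# Shipped default parameter sets. The canonical parameter tables for the
# full column are not part of the distributed text, so these defaults are
# approximate reconstructions: reciprocal time constants are chosen so every
# isolated population rings at its published natural frequency (FS fastest,
# then IB, RS, LTS), sigmoid parameters are the standard neural-mass values,
# and the connectivity follows the canonical laminar microcircuit motifs.
# Exact values can always be supplied through the model-file interface.

#' Natural frequencies of the default 14-population column
#'
#' @return Named vector, Hz.
#' @export
default_natural_frequencies <- function() {
  c(L2RS = 8.25, L2IB = 10.48, L2LTS = 5.40, L2FS = 55.87,
    L4RS = 8.25, L4LTS = 5.40, L4FS = 46.35,
    L5RS = 7.30, L5IB = 9.52, L5LTS = 5.40, L5FS = 46.35,
    L6RS = 6.98, L6LTS = 5.40, L6FS = 44.76)
}

# g giving natural frequency f at damping b: f = g sqrt(1-b^2) / (2 pi)
g_for_frequency <- function(f, b) 2 * pi * f / sqrt(1 - b^2)

#' Default 14-population column model
#'
#' Approximate canonical parameter set: damping `b` (shared), gains per
#' excitatory/inhibitory class, external input only to the layer-4 RS and FS
#' populations, and a signed laminar connectivity built from standard
#' microcircuit motifs (within-layer excitatory-inhibitory loops, L4 -> L2/3
#' -> L5 -> L6 feedforward chain, L6 -> L4 feedback). Excitatory sources
#' have non-negative, inhibitory sources non-positive outgoing weights.
#'
#' @param b damping, shared by all populations (`b < 1`: every population
#'   can ring at its own natural frequency).
#' @param G_E,G_I PSP gains of excitatory / inhibitory populations, mV.
#' @param p_L4RS,p_L4FS mean external input to L4RS / L4FS, 1/s.
#' @param p_sigma input noise SD for the two driven populations, 1/s.
#' @param w_scale global scale of the connectivity table; the default puts
#'   the column just above its oscillation threshold, where network rhythms
#'   are sustained but PSP excursions stay in the sigmoid's sensitive range.
#' @param eta additional multiplier on the connectivity matrix (the swept
#'   parameter of the sensitivity analysis).
#' @param k_scale named multipliers of the reciprocal time constants per
#'   cell class, e.g. `c(RS = 1.2)`.
#' @return A [column_model()].
#' @export
default_column_model <- function(b = 0.2, G_E = 3.25, G_I = 15,
                                 p_L4RS = 60, p_L4FS = 80, p_sigma = 10,
                                 w_scale = 0.3, eta = 1, k_scale = NULL) {
  fnat <- default_natural_frequencies()
  sig <- sigmoid_params()
  nm_all <- names(fnat)
  cls_of <- function(nm) sub("^L[2456]", "", nm)
  G <- ifelse(cls_of(nm_all) %in% c("RS", "IB"), G_E, G_I)
  g <- vapply(nm_all, function(nm) {
    gg <- g_for_frequency(fnat[[nm]], b)
    cls <- cls_of(nm)
    if (!is.null(k_scale) && cls %in% names(k_scale)) gg <- gg * k_scale[[cls]]
    gg
  }, numeric(1))
  p_mean <- ifelse(nm_all == "L4RS", p_L4RS,
                   ifelse(nm_all == "L4FS", p_L4FS, 0))
  gamma <- default_column_gamma() * w_scale * eta
  pops <- lapply(seq_along(nm_all), function(i) {
    population_spec(nm_all[i], G = G[i], g = g[i], b = b,
                    p_mean = p_mean[i],
                    p_sigma = if (nm_all[i] %in% c("L4RS", "L4FS"))
                      p_sigma else 0,
                    sigmoid = sig)
  })
  column_model(pops, gamma)
}

#' Default signed connectivity of the 14-population column
#'
#' Rows are sources, columns targets; negative entries are inhibitory
#' (LTS/FS sources), units of firing-rate weight.
#'
#' @return 14 x 14 named matrix.
#' @export
default_column_gamma <- function() {
  nm <- names(default_natural_frequencies())
  G <- matrix(0, 14, 14, dimnames = list(nm, nm))
  set_conn <- function(from, to, w) G[from, to] <<- w
  # within-layer excitatory-inhibitory loops (per layer where present)
  for (L in c("L2", "L4", "L5", "L6")) {
    rs <- paste0(L, "RS")
    fs <- paste0(L, "FS")
    lts <- paste0(L, "LTS")
    set_conn(rs, fs, 60)
    set_conn(rs, lts, 40)
    set_conn(fs, rs, -55)
    set_conn(lts, rs, -40)
    set_conn(lts, fs, -15)
    set_conn(rs, rs, 45)
  }
  # IB populations in L2/3 and L5 participate in their layer's loop
  for (L in c("L2", "L5")) {
    ib <- paste0(L, "IB")
    set_conn(paste0(L, "RS"), ib, 30)
    set_conn(ib, paste0(L, "FS"), 35)
    set_conn(ib, paste0(L, "LTS"), 20)
    set_conn(paste0(L, "FS"), ib, -35)
    set_conn(paste0(L, "LTS"), ib, -25)
    set_conn(ib, ib, 25)
  }
  # only the L4 FS population has an anatomical self-connection
  set_conn("L4FS", "L4FS", -10)
  # canonical interlaminar chain: L4 -> L2/3 -> L5 -> L6 -> L4
  set_conn("L4RS", "L2RS", 50)
  set_conn("L4RS", "L2FS", 25)
  set_conn("L4RS", "L2IB", 20)
  set_conn("L2RS", "L5RS", 40)
  set_conn("L2RS", "L5IB", 25)
  set_conn("L2IB", "L5RS", 20)
  set_conn("L2RS", "L5FS", 15)
  set_conn("L5RS", "L6RS", 35)
  set_conn("L5IB", "L6RS", 20)
  set_conn("L5RS", "L6FS", 15)
  set_conn("L6RS", "L4RS", 30)
  set_conn("L6RS", "L4FS", 15)
  # deep-layer slow inhibition reaching across layers
  set_conn("L5LTS", "L2RS", -15)
  set_conn("L6LTS", "L4RS", -15)
  G
}

# Design helper for the small chain models. For each population the
# external input p is solved so that the prescribed operating point x_op is
# an exact fixed point of the full coupled system given the mean drive
# t(gamma) %*% S(x_op). Populations flagged `compensate` additionally get
# their reciprocal time constant solved so the *linearized* resonance,
# softened by the positive self-feedback (omega0^2 = g^2 - G g w_self
# S'(x_op)), lands on the target frequency; for the strongly nonlinear fast
# populations the raw g = 2 pi f is used and the softening is left to pull
# the effective peak into the target band.
design_chain <- function(freqs, x_op, b, gamma, G, p_sigma,
                         compensate = rep(TRUE, length(freqs)),
                         names = c("L2RS", "L4RS", "L5RS"),
                         sig = sigmoid_params()) {
  P <- length(freqs)
  S <- sig$e0 / (1 + exp(sig$r * (sig$v0 - x_op)))
  Sp <- sig$r * S * (1 - S / sig$e0)
  g <- numeric(P)
  for (i in seq_len(P)) {
    w0 <- 2 * pi * freqs[i]
    if (compensate[i]) {
      cc <- G[i] * gamma[i, i] * Sp[i]
      g[i] <- (cc + sqrt(cc^2 + 4 * w0^2)) / 2
    } else {
      g[i] <- w0
    }
  }
  drive <- as.numeric(t(gamma) %*% S)
  p_mean <- g * x_op / G - drive
  pops <- lapply(seq_len(P), function(i) {
    population_spec(names[i], G = G[i], g = g[i], b = b[i],
                    p_mean = p_mean[i], p_sigma = p_sigma[i], sigmoid = sig)
  })
  column_model(pops, gamma)
}

#' Three-population chain model (control analysis)
#'
#' Populations 1 and 3 ring in the gamma band and are both driven by
#' population 2, which oscillates in the theta band (near 4.4 Hz); there is
#' no connection between populations 1 and 3. The slow population's rhythm
#' is a noise-driven resonance amplified by compensated positive
#' self-feedback; the fast populations sit below the sigmoid inflection so
#' the strong slow drive sweeps their operating point through the curved
#' region, which modulates their effective gain and thereby the amplitude of
#' their gamma-band ringing (phase-amplitude coupling). External inputs are
#' solved so each population's prescribed operating point is a fixed point.
#'
#' @param p_sigma input noise SD, 1/s, applied to all three populations
#'   (the elevated-noise control uses 10, the destructive level is ~100 for
#'   this parameter set).
#' @param b damping vector (populations 1..3); the fast populations'
#'   damping keeps their envelope able to track the theta drive.
#' @param w21,w23 drive strengths from population 2.
#' @param w_self self-connection strength of the fast populations 1 and 3.
#' @param w_self2 self-connection strength of the slow population
#'   (compensated, i.e. its design frequency accounts for the softening).
#' @param freqs design frequencies, Hz: raw natural frequencies of the fast
#'   populations (the self-feedback softening pulls the effective peaks
#'   down into 45-65 Hz) and the linearized target of the slow population
#'   (its effective peak sits near 4.4 Hz).
#' @param x_op operating points, mV.
#' @return A [column_model()] with populations labelled L2RS, L4RS, L5RS
#'   standing in for the generic excitatory populations 1, 2, 3.
#' @export
chain3_model <- function(p_sigma = 5, b = c(0.03, 0.02, 0.03), w21 = 480,
                         w23 = 480, w_self = 120, w_self2 = 80,
                         freqs = c(75, 3, 81), x_op = c(3.5, 6, 3.5)) {
  gamma <- matrix(0, 3, 3)
  gamma[1, 1] <- w_self
  gamma[3, 3] <- w_self
  gamma[2, 2] <- w_self2
  gamma[2, 1] <- w21
  gamma[2, 3] <- w23
  design_chain(freqs, x_op, b, gamma, G = rep(3.25, 3),
               p_sigma = rep(p_sigma, 3),
               compensate = c(FALSE, TRUE, FALSE))
}

#' Three-population cascade model (indirect-coupling study)
#'
#' Chain 1 -> 2 -> 3: population 1 oscillates in the theta band, population
#' 3 in the gamma band, and the relay population 2 in the delta band
#' (case I) or beta band (case II). The two connection strengths are the
#' swept parameters of the cascade analysis.
#'
#' @param case `"I"` or `"II"`.
#' @param gamma12,gamma23 connection strengths 1 -> 2 and 2 -> 3.
#' @param p_sigma input noise SD, 1/s.
#' @param b damping vector.
#' @param w_self1,w_self2,w_self3 self-connection strengths: the two slow
#'   oscillators (populations 1 and 2 in case I) use compensated
#'   self-feedback amplification; the fast population uses raw feedback
#'   with its design frequency above the band.
#' @param x_op operating points, mV.
#' @return A [column_model()].
#' @export
cascade3_model <- function(case = c("I", "II"), gamma12 = 200, gamma23 = 200,
                           p_sigma = 5, b = c(0.02, 0.02, 0.03),
                           w_self1 = 80, w_self2 = 80, w_self3 = 120,
                           x_op = c(6, 6, 3.5)) {
  case <- match.arg(case)
  f2 <- if (case == "I") 1.8 else 16
  freqs <- c(4, f2, 75)
  gamma <- matrix(0, 3, 3)
  gamma[1, 1] <- w_self1
  gamma[2, 2] <- w_self2
  gamma[3, 3] <- w_self3
  gamma[1, 2] <- gamma12
  gamma[2, 3] <- gamma23
  design_chain(freqs, x_op, b, gamma, G = rep(3.25, 3),
               p_sigma = rep(p_sigma, 3),
               compensate = c(TRUE, TRUE, FALSE))
}
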