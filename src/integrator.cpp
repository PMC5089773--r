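// Fixed-step integrators for the column model's random differential system.
//
// State per population m: PSP x_m (mV) and its derivative y_m (mV/s),
//   dx_m/dt = y_m
//   dy_m/dt = -2 g_m b_m y_m - g_m^2 x_m + G_m g_m (p_m + sum_n Gamma_nm S(x_n))
// External input p_m is held piecewise constant over each step (random-DE
// convention): p_m = p_mean_m + p_sigma_m * xi, xi ~ N(0,1) drawn per step.
//
// The local linearization (LL) step propagates the drift linearized at the
// current state exactly over one step via the exponential of the augmented
// matrix [[J, f], [0, 0]]; it is exact whenever the drift is linear.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline vec sig_vec(const vec& x, const vec& e0, const vec& v0,
                          const vec& r, bool linear) {
  if (linear) return x;
  return e0 / (1.0 + exp(r % (v0 - x)));
}

// S'(x) = r S (1 - S/e0)
static inline vec dsig_vec(const vec& x, const vec& e0, const vec& v0,
                           const vec& r, bool linear) {
  if (linear) return ones<vec>(x.n_elem);
  vec s = sig_vec(x, e0, v0, r, false);
  return r % s % (1.0 - s / e0);
}

struct ModelPars {
  vec G, g, b, e0, v0, r;
  mat GammaT;     // GammaT(m, n) = Gamma(n, m): input to m from source n
  bool linear;
};

static void drift(const vec& x, const vec& y, const vec& p,
                  const ModelPars& mp, vec& fx, vec& fy) {
  fx = y;
  fy = -2.0 * (mp.g % mp.b) % y - square(mp.g) % x +
       (mp.G % mp.g) % (p + mp.GammaT * sig_vec(x, mp.e0, mp.v0, mp.r, mp.linear));
}

// One LL step; falls back to Euler if the augmented exponential is not finite.
static bool ll_step(vec& x, vec& y, const vec& p, const ModelPars& mp, double dt) {
  const uword P = x.n_elem;
  vec fx, fy;
  drift(x, y, p, mp, fx, fy);
  mat M(2 * P + 1, 2 * P + 1, fill::zeros);
  // Jacobian: [[0, I], [A, D]]
  M.submat(0, P, P - 1, 2 * P - 1) = eye<mat>(P, P);
  mat A = -diagmat(square(mp.g)) +
          diagmat(mp.G % mp.g) * mp.GammaT *
          diagmat(dsig_vec(x, mp.e0, mp.v0, mp.r, mp.linear));
  M.submat(P, 0, 2 * P - 1, P - 1) = A;
  M.submat(P, P, 2 * P - 1, 2 * P - 1) = -diagmat(2.0 * (mp.g % mp.b));
  M.submat(0, 2 * P, P - 1, 2 * P) = fx;
  M.submat(P, 2 * P, 2 * P - 1, 2 * P) = fy;
  mat E;
  bool ok = expmat(E, M * dt);
  if (!ok || !E.is_finite()) {
    // ill-conditioned linearization: plain Euler fallback
    x += dt * fx;
    y += dt * fy;
    return false;
  }
  x += E.submat(0, 2 * P, P - 1, 2 * P);
  y += E.submat(P, 2 * P, 2 * P - 1, 2 * P);
  return true;
}

static void euler_step(vec& x, vec& y, const vec& p, const ModelPars& mp, double dt) {
  vec fx, fy;
  drift(x, y, p, mp, fx, fy);
  x += dt * fx;
  y += dt * fy;
}

// [[Rcpp::export]]
Rcpp::List nmm_integrate_cpp(const arma::vec& x0, const arma::vec& y0,
                             const arma::vec& G, const arma::vec& g,
                             const arma::vec& b, const arma::mat& Gamma,
                             const arma::vec& e0, const arma::vec& v0,
                             const arma::vec& r, const arma::vec& p_mean,
                             const arma::vec& p_sigma, const arma::mat& noise,
                             double dt, bool linear_sigmoid, int method,
                             double diverge_bound) {
  const uword P = x0.n_elem;
  const uword nsteps = noise.n_rows;
  ModelPars mp{G, g, b, e0, v0, r, Gamma.t(), linear_sigmoid};
  mat xs(nsteps + 1, P), ys(nsteps + 1, P);
  vec x = x0, y = y0;
  xs.row(0) = x.t();
  ys.row(0) = y.t();
  int n_fallback = 0;
  for (uword i = 0; i < nsteps; ++i) {
    vec p = p_mean + p_sigma % noise.row(i).t();
    if (method == 0) {
      if (!ll_step(x, y, p, mp, dt)) ++n_fallback;
    } else {
      euler_step(x, y, p, mp, dt);
    }
    if (!x.is_finite() || !y.is_finite() || abs(x).max() > diverge_bound) {
      Rcpp::stop("simulation diverged at step %d (t = %g s): |x| exceeded %g",
                 (int)(i + 1), (double)(i + 1) * dt, diverge_bound);
    }
    xs.row(i + 1) = x.t();
    ys.row(i + 1) = y.t();
  }
  return Rcpp::List::create(Rcpp::Named("x") = xs, Rcpp::Named("y") = ys,
                            Rcpp::Named("n_fallback") = n_fallback);
}

// [[Rcpp::export]]
Rcpp::List nmm_step_cpp(const arma::vec& x0, const arma::vec& y0,
                        const arma::vec& G, const arma::vec& g,
                        const arma::vec& b, const arma::mat& Gamma,
                        const arma::vec& e0, const arma::vec& v0,
                        const arma::vec& r, const arma::vec& p,
                        double dt, bool linear_sigmoid, int method) {
  ModelPars mp{G, g, b, e0, v0, r, Gamma.t(), linear_sigmoid};
  vec x = x0, y = y0;
  bool ll_ok = true;
  if (method == 0) {
    ll_ok = ll_step(x, y, p, mp, dt);
  } else {
    euler_step(x, y, p, mp, dt);
  }
  return Rcpp::List::create(Rcpp::Named("x") = x, Rcpp::Named("y") = y,
                            Rcpp::Named("ll_ok") = ll_ok);
}
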