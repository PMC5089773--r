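// Plug-in (histogram) estimators of mutual information, conditional mutual
// information and conditional transfer entropy on integer-coded series.
//
// Conventions: codes are 0-based, alphabet sizes passed explicitly.
// cMI uses the mutual-information chain rule, I(x;y|m) = I(x;(y,m)) - I(x;m),
// so that identities between sums of MI terms hold exactly for the plug-in
// estimates. cTE(src -> tgt | m) averages cMI(src_t; tgt_{t+delta} | m_t)
// over delta = 1..N, with m_t the (optional) target past at time t combined
// with any exogenous conditioning series; for each delta all series are
// truncated to the common sample range.
//
// Surrogates circularly shift the *target* series (future and past
// together) while the source and exogenous conditioning stay aligned: this
// destroys the source-target coupling under test but preserves both the
// source-conditioning dependence and the target's own autostructure, so the
// surrogate distribution shares the estimator's finite-sample bias.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double LOG2 = std::log(2.0);

// MI (bits) between paired code vectors over indices [0, n)
static double mi_pairs(const int* x, const int* z, int n, int nx, int nz,
                       std::vector<double>& joint, std::vector<double>& mx,
                       std::vector<double>& mz) {
  std::fill(joint.begin(), joint.begin() + (size_t)nx * nz, 0.0);
  std::fill(mx.begin(), mx.begin() + nx, 0.0);
  std::fill(mz.begin(), mz.begin() + nz, 0.0);
  for (int i = 0; i < n; ++i) {
    joint[(size_t)x[i] + (size_t)nx * z[i]] += 1.0;
    mx[x[i]] += 1.0;
    mz[z[i]] += 1.0;
  }
  double mi = 0.0, N = (double)n;
  for (int b = 0; b < nz; ++b) {
    if (mz[b] == 0.0) continue;
    for (int a = 0; a < nx; ++a) {
      double c = joint[(size_t)a + (size_t)nx * b];
      if (c > 0.0) mi += (c / N) * std::log(c * N / (mx[a] * mz[b]));
    }
  }
  return mi / LOG2;
}

struct MIWork {
  std::vector<double> joint, mx, mz;
  std::vector<int> zbuf, mbuf;
  MIWork(int nx, size_t nzmax, int n) {
    if ((size_t)nx * nzmax > (size_t)2e8) stop("joint alphabet too large");
    joint.resize((size_t)nx * nzmax);
    mx.resize(nx);
    mz.resize(nzmax);
    zbuf.resize(n);
    mbuf.resize(n);
  }
};

// [[Rcpp::export]]
double mi_disc_cpp(const IntegerVector& x, const IntegerVector& z,
                   int nx, int nz) {
  int n = x.size();
  if (z.size() != n) stop("length mismatch");
  MIWork w(nx, nz, n);
  return mi_pairs(&x[0], &z[0], n, nx, nz, w.joint, w.mx, w.mz);
}

// chain-rule cMI at a fixed alignment
// [[Rcpp::export]]
double cmi_chain_cpp(const IntegerVector& x, const IntegerVector& y,
                     const IntegerVector& m, int nx, int ny, int nm) {
  int n = x.size();
  if (y.size() != n || m.size() != n) stop("length mismatch");
  size_t nym = (size_t)ny * nm;
  MIWork w(nx, nym, n);
  for (int i = 0; i < n; ++i) w.zbuf[i] = y[i] + ny * m[i];
  double i_xym = mi_pairs(&x[0], w.zbuf.data(), n, nx, (int)nym, w.joint, w.mx, w.mz);
  double i_xm = mi_pairs(&x[0], &m[0], n, nx, nm, w.joint, w.mx, w.mz);
  return i_xym - i_xm;
}

// cTE core: src/cond stay aligned; tgt may be circularly shifted by tau.
// conditioning code at time i: cond[i] (+ target past tgt[(i+tau)%n] when
// with_past). future target at i+delta: tgt[(i+delta+tau)%n] -- but only
// indices with i+delta < n are used for the unshifted case, and for
// surrogates the wrap acts on the whole target stream, mimicking an offset
// recording of the target.
static double cte_core(const int* s, const int* t, const int* c, int n,
                       int ns, int nt, int nc, int N, int stride,
                       bool with_past, int tau, MIWork& w) {
  double acc = 0.0;
  int nm = with_past ? nc * nt : nc;
  size_t ntm = (size_t)nt * nm;
  for (int j = 1; j <= N; ++j) {
    int d = j * stride;
    int len = n - d;
    for (int i = 0; i < len; ++i) {
      int tp = t[(i + tau) % n];
      int tf = t[(i + d + tau) % n];
      int m = with_past ? (c[i] + nc * tp) : c[i];
      w.mbuf[i] = m;
      w.zbuf[i] = tf + nt * m;
    }
    double i_sym = mi_pairs(s, w.zbuf.data(), len, ns, (int)ntm,
                            w.joint, w.mx, w.mz);
    double i_sm = mi_pairs(s, w.mbuf.data(), len, ns, nm, w.joint, w.mx, w.mz);
    acc += i_sym - i_sm;
  }
  return acc / (double)N;
}

// [[Rcpp::export]]
double cte_disc_cpp(const IntegerVector& src, const IntegerVector& tgt,
                    const IntegerVector& cond, int ns, int nt, int nc,
                    int N, int stride, bool target_past) {
  int n = src.size();
  if (tgt.size() != n || cond.size() != n) stop("length mismatch");
  if (stride < 1) stop("lag stride must be >= 1");
  if (N * stride >= n) stop("lag horizon must be smaller than the series length");
  int nm = target_past ? nc * nt : nc;
  MIWork w(ns, (size_t)nt * nm, n);
  return cte_core(&src[0], &tgt[0], &cond[0], n, ns, nt, nc, N, stride,
                  target_past, 0, w);
}

// cTE recomputed for each circular shift of the target series
// [[Rcpp::export]]
NumericVector cte_surrogates_cpp(const IntegerVector& src,
                                 const IntegerVector& tgt,
                                 const IntegerVector& cond, int ns, int nt,
                                 int nc, int N, int stride, bool target_past,
                                 const IntegerVector& shifts) {
  int n = src.size();
  if (tgt.size() != n || cond.size() != n) stop("length mismatch");
  if (stride < 1) stop("lag stride must be >= 1");
  if (N * stride >= n) stop("lag horizon must be smaller than the series length");
  int nm = target_past ? nc * nt : nc;
  MIWork w(ns, (size_t)nt * nm, n);
  NumericVector out(shifts.size());
  for (int k = 0; k < shifts.size(); ++k) {
    int tau = ((shifts[k] % n) + n) % n;
    out[k] = cte_core(&src[0], &tgt[0], &cond[0], n, ns, nt, nc, N, stride,
                      target_past, tau, w);
  }
  return out;
}

// contemporaneous cMI recomputed for each circular shift of the target
// [[Rcpp::export]]
NumericVector cmi_surrogates_cpp(const IntegerVector& src,
                                 const IntegerVector& tgt,
                                 const IntegerVector& cond, int ns, int nt,
                                 int nc, const IntegerVector& shifts) {
  int n = src.size();
  if (tgt.size() != n || cond.size() != n) stop("length mismatch");
  size_t ntm = (size_t)nt * nc;
  MIWork w(ns, ntm, n);
  NumericVector out(shifts.size());
  for (int k = 0; k < shifts.size(); ++k) {
    int tau = ((shifts[k] % n) + n) % n;
    for (int i = 0; i < n; ++i) {
      int tf = tgt[(i + tau) % n];
      w.mbuf[i] = cond[i];
      w.zbuf[i] = tf + nt * cond[i];
    }
    double i_sym = mi_pairs(&src[0], w.zbuf.data(), n, ns, (int)ntm,
                            w.joint, w.mx, w.mz);
    double i_sm = mi_pairs(&src[0], w.mbuf.data(), n, ns, nc,
                           w.joint, w.mx, w.mz);
    out[k] = i_sym - i_sm;
  }
  return out;
}
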