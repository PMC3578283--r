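#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// One synchronous step of the macroscopic sublattice map.
// sig_k = 2 m X U / Use - 1; h_i = sum_k D(i,k) p_k sig_k; m <- g(h),
// X <- X + (1-X)/tauR - m X U; U <- U + (Use-U)/tauF + Use (1-U) m.
static inline void macro_step(std::vector<double> &m, std::vector<double> &X,
                              std::vector<double> &U,
                              const NumericMatrix &D,
                              const NumericVector &psz,
                              double Use, double tauR, double tauF,
                              double T,
                              std::vector<double> &sig,
                              std::vector<double> &mn) {
  const int n = (int)m.size();
  for (int k = 0; k < n; ++k)
    sig[k] = psz[k] * (2.0 * m[k] * X[k] * U[k] / Use - 1.0);
  for (int i = 0; i < n; ++i) {
    double h = 0.0;
    for (int k = 0; k < n; ++k) h += D(i, k) * sig[k];
    mn[i] = 0.5 * (1.0 + std::tanh(h / T));
  }
  for (int k = 0; k < n; ++k) {
    X[k] = X[k] + (1.0 - X[k]) / tauR - m[k] * X[k] * U[k];
    U[k] = U[k] + (Use - U[k]) / tauF + Use * (1.0 - U[k]) * m[k];
    m[k] = mn[k];
  }
}

static inline void overlaps(const std::vector<double> &m,
                            const NumericMatrix &eta,
                            const NumericVector &psz,
                            double *M) {
  const int n = (int)m.size(), p = eta.ncol();
  for (int mu = 0; mu < p; ++mu) {
    double acc = 0.0;
    for (int k = 0; k < n; ++k)
      acc += psz[k] * eta(k, mu) * (2.0 * m[k] - 1.0);
    M[mu] = acc;
  }
}

// [[Rcpp::export]]
List macro_traj_cpp(NumericVector m0, NumericVector X0, NumericVector U0,
                    NumericMatrix D, NumericVector psz, NumericMatrix eta,
                    double Use, double tauR, double tauF, double T,
                    int n_steps, bool record) {
  const int n = m0.size(), p = eta.ncol();
  std::vector<double> m(m0.begin(), m0.end()), X(X0.begin(), X0.end()),
      U(U0.begin(), U0.end()), sig(n), mn(n);
  std::vector<double> M(p);
  if (record) {
    NumericMatrix Mt(n_steps + 1, p), mt(n_steps + 1, n),
        Xt(n_steps + 1, n), Ut(n_steps + 1, n);
    overlaps(m, eta, psz, M.data());
    for (int mu = 0; mu < p; ++mu) Mt(0, mu) = M[mu];
    for (int k = 0; k < n; ++k) { mt(0,k)=m[k]; Xt(0,k)=X[k]; Ut(0,k)=U[k]; }
    for (int t = 1; t <= n_steps; ++t) {
      macro_step(m, X, U, D, psz, Use, tauR, tauF, T, sig, mn);
      overlaps(m, eta, psz, M.data());
      for (int mu = 0; mu < p; ++mu) Mt(t, mu) = M[mu];
      for (int k = 0; k < n; ++k) { mt(t,k)=m[k]; Xt(t,k)=X[k]; Ut(t,k)=U[k]; }
    }
    return List::create(_["M"] = Mt, _["m"] = mt, _["X"] = Xt, _["U"] = Ut,
                        _["m_final"] = NumericVector(m.begin(), m.end()),
                        _["X_final"] = NumericVector(X.begin(), X.end()),
                        _["U_final"] = NumericVector(U.begin(), U.end()));
  } else {
    std::vector<double> Mmin(p, R_PosInf), Mmax(p, R_NegInf);
    for (int t = 1; t <= n_steps; ++t) {
      macro_step(m, X, U, D, psz, Use, tauR, tauF, T, sig, mn);
      overlaps(m, eta, psz, M.data());
      for (int mu = 0; mu < p; ++mu) {
        if (M[mu] < Mmin[mu]) Mmin[mu] = M[mu];
        if (M[mu] > Mmax[mu]) Mmax[mu] = M[mu];
      }
    }
    return List::create(_["M_min"] = NumericVector(Mmin.begin(), Mmin.end()),
                        _["M_max"] = NumericVector(Mmax.begin(), Mmax.end()),
                        _["m_final"] = NumericVector(m.begin(), m.end()),
                        _["X_final"] = NumericVector(X.begin(), X.end()),
                        _["U_final"] = NumericVector(U.begin(), U.end()));
  }
}

// Brute-force attractor sweep over a grid of noise intensities with orbit
// inheritance: the post-window state at one T seeds the next T. For each T,
// run `transient` steps, then a `window` over which overlap extrema and the
// mean effective dimension (pairwise-distinct overlap count at tolerance
// eps, p = 3 only) are accumulated.
// [[Rcpp::export]]
List macro_sweep_cpp(NumericVector m0, NumericVector X0, NumericVector U0,
                     NumericMatrix D, NumericVector psz, NumericMatrix eta,
                     double Use, double tauR, double tauF,
                     NumericVector Tgrid, int transient, int window,
                     double eps) {
  const int n = m0.size(), p = eta.ncol(), nT = Tgrid.size();
  std::vector<double> m(m0.begin(), m0.end()), X(X0.begin(), X0.end()),
      U(U0.begin(), U0.end()), sig(n), mn(n), M(p);
  NumericMatrix Mmin(nT, p), Mmax(nT, p), states(nT, 3 * n);
  NumericVector med(nT), amp(nT);
  for (int it = 0; it < nT; ++it) {
    const double T = Tgrid[it];
    for (int t = 0; t < transient; ++t)
      macro_step(m, X, U, D, psz, Use, tauR, tauF, T, sig, mn);
    std::vector<double> lo(p, R_PosInf), hi(p, R_NegInf);
    double ed_sum = 0.0;
    for (int t = 0; t < window; ++t) {
      macro_step(m, X, U, D, psz, Use, tauR, tauF, T, sig, mn);
      overlaps(m, eta, psz, M.data());
      for (int mu = 0; mu < p; ++mu) {
        if (M[mu] < lo[mu]) lo[mu] = M[mu];
        if (M[mu] > hi[mu]) hi[mu] = M[mu];
      }
      if (p == 3) {
        double d12 = std::fabs(M[0] - M[1]), d23 = std::fabs(M[1] - M[2]),
               d31 = std::fabs(M[2] - M[0]);
        int ed;
        if (d12 < eps && d23 < eps && d31 < eps) ed = 1;
        else if (d12 > eps && d23 > eps && d31 > eps) ed = 3;
        else ed = 2;
        ed_sum += ed;
      }
    }
    double a = 0.0;
    for (int mu = 0; mu < p; ++mu) {
      Mmin(it, mu) = lo[mu];
      Mmax(it, mu) = hi[mu];
      if (hi[mu] - lo[mu] > a) a = hi[mu] - lo[mu];
    }
    amp[it] = a;
    med[it] = (p == 3) ? ed_sum / window : NA_REAL;
    for (int k = 0; k < n; ++k) {
      states(it, k) = m[k];
      states(it, n + k) = X[k];
      states(it, 2 * n + k) = U[k];
    }
  }
  return List::create(_["T"] = Tgrid, _["amplitude"] = amp, _["med"] = med,
                      _["M_min"] = Mmin, _["M_max"] = Mmax,
                      _["states"] = states);
}
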