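// Shared infrastructure for the Gaussian integral engines: shell
// parsing, Cartesian component enumeration, Hermite (McMurchie-Davidson)
// expansion coefficients, the Boys function and Hermite Coulomb integrals.
//
// Conventions: a shell holds primitives of one angular momentum l with
// final contraction coefficients (primitive norms already folded in by the
// R side).  Cartesian components are ordered lexicographically with lx
// descending, then ly descending (CCA ordering).  All quantities in
// atomic units.
#pragma once
#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>

namespace qc {

constexpr int LMAX = 5;           // highest l after one derivative lift (g + 1)
constexpr int EI = LMAX + 2;      // E-table extents
constexpr int ET = 2 * LMAX + 5;

struct Shell {
  int l;
  double A[3];
  std::vector<double> alpha, coef;
  int atom;   // 0-based
  int off;    // AO offset
  int nbf;
};

inline int ncart(int l) { return (l + 1) * (l + 2) / 2; }

inline std::vector<std::array<int, 3>> cart_comps(int l) {
  std::vector<std::array<int, 3>> v;
  v.reserve(ncart(l));
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly) v.push_back({lx, ly, l - lx - ly});
  return v;
}

inline std::vector<Shell> parse_shells(const Rcpp::List& shells) {
  std::vector<Shell> out;
  int off = 0;
  for (R_xlen_t i = 0; i < shells.size(); ++i) {
    Rcpp::List s = shells[i];
    Shell sh;
    sh.l = Rcpp::as<int>(s["l"]);
    if (sh.l > LMAX - 1) Rcpp::stop("angular momentum beyond supported maximum (g)");
    Rcpp::NumericVector A = s["center"];
    sh.A[0] = A[0]; sh.A[1] = A[1]; sh.A[2] = A[2];
    sh.alpha = Rcpp::as<std::vector<double>>(s["exp"]);
    sh.coef = Rcpp::as<std::vector<double>>(s["coef"]);
    sh.atom = Rcpp::as<int>(s["atom"]) - 1;
    sh.off = off;
    sh.nbf = ncart(sh.l);
    off += sh.nbf;
    out.push_back(sh);
  }
  return out;
}

inline int nbf_total(const std::vector<Shell>& sh) {
  int n = 0;
  for (auto& s : sh) n += s.nbf;
  return n;
}

// Hermite expansion coefficients E_t^{ij} for a 1-d primitive pair:
// exp(-a (x-A)^2) exp(-b (x-B)^2) = sum_t E_t^{ij} Lambda_t(x; p, P).
struct ETab {
  double e[EI][EI][ET];
  void fill(int imax, int jmax, double a, double b, double AB) {
    const double p = a + b, q = a * b / p;
    const double XPA = -b * AB / p, XPB = a * AB / p;
    const double o2p = 0.5 / p;
    // zero only the region the recursions and consumers touch
    for (int i = 0; i <= imax; ++i)
      for (int j = 0; j <= jmax; ++j)
        for (int t = 0; t <= imax + jmax + 2; ++t) e[i][j][t] = 0.0;
    e[0][0][0] = std::exp(-q * AB * AB);
    for (int i = 0; i < imax; ++i)
      for (int t = 0; t <= i + 1; ++t) {
        double v = XPA * e[i][0][t];
        if (t > 0) v += o2p * e[i][0][t - 1];
        if (t + 1 <= i) v += (t + 1) * e[i][0][t + 1];
        e[i + 1][0][t] = v;
      }
    for (int j = 0; j < jmax; ++j)
      for (int i = 0; i <= imax; ++i)
        for (int t = 0; t <= i + j + 1; ++t) {
          double v = XPB * e[i][j][t];
          if (t > 0) v += o2p * e[i][j][t - 1];
          if (t + 1 <= i + j) v += (t + 1) * e[i][j][t + 1];
          e[i][j + 1][t] = v;
        }
  }
};

// Boys function F_m(T), filled for m = 0..mmax.  Series with downward
// recursion for moderate T, asymptotic with upward recursion for large T.
inline void boys(int mmax, double T, double* F) {
  if (T < 1e-14) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (T > 40.0) {
    F[0] = 0.5 * std::sqrt(M_PI / T);
    const double eT = std::exp(-T);
    for (int m = 0; m < mmax; ++m) F[m + 1] = ((2 * m + 1) * F[m] - eT) / (2.0 * T);
    return;
  }
  const double eT = std::exp(-T);
  double term = 1.0 / (2.0 * mmax + 1.0), sum = term;
  for (int i = 1; i < 300; ++i) {
    term *= 2.0 * T / (2.0 * mmax + 2.0 * i + 1.0);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[mmax] = eT * sum;
  for (int m = mmax; m > 0; --m) F[m - 1] = (2.0 * T * F[m] + eT) / (2.0 * m - 1.0);
}

// Hermite Coulomb integrals R^0_{tuv}(p, X) into R[t][u][v] (flattened).
struct RTab {
  int nt, nu, nv;
  std::vector<double> r;
  std::vector<double> work;  // scratch, reused across fills
  double& at(int t, int u, int v) { return r[(t * nu + u) * nv + v]; }
  void fill(int tmax, int umax, int vmax, double p, double X, double Y, double Z) {
    nt = tmax + 1; nu = umax + 1; nv = vmax + 1;
    const int N = tmax + umax + vmax;
    const double T = p * (X * X + Y * Y + Z * Z);
    double F[64];
    boys(N, T, F);
    // work[n][t][u][v]
    work.assign((size_t)(N + 1) * nt * nu * nv, 0.0);
    auto W = [&](int n, int t, int u, int v) -> double& {
      return work[((n * nt + t) * nu + u) * nv + v];
    };
    double mp = 1.0;
    for (int n = 0; n <= N; ++n) { W(n, 0, 0, 0) = mp * F[n]; mp *= -2.0 * p; }
    for (int n = N - 1; n >= 0; --n) {
      int avail = N - n;  // how far t+u+v may reach at this n
      for (int t = 0; t <= std::min(tmax, avail); ++t)
        for (int u = 0; u <= std::min(umax, avail - t); ++u)
          for (int v = 0; v <= std::min(vmax, avail - t - u); ++v) {
            if (t + u + v == 0) continue;
            double val;
            if (t > 0) {
              val = X * W(n + 1, t - 1, u, v);
              if (t > 1) val += (t - 1) * W(n + 1, t - 2, u, v);
            } else if (u > 0) {
              val = Y * W(n + 1, t, u - 1, v);
              if (u > 1) val += (u - 1) * W(n + 1, t, u - 2, v);
            } else {
              val = Z * W(n + 1, t, u, v - 1);
              if (v > 1) val += (v - 1) * W(n + 1, t, u, v - 2);
            }
            W(n, t, u, v) = val;
          }
    }
    r.assign(nt * nu * nv, 0.0);
    for (int t = 0; t <= tmax; ++t)
      for (int u = 0; u <= umax; ++u)
        for (int v = 0; v <= vmax; ++v) at(t, u, v) = W(0, t, u, v);
  }
};

}  // namespace qc
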