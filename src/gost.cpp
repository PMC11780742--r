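// Three-center overlap integrals between basis-function pairs and
// normalized s-type tessera Gaussians, their normal-derivative (f),
// exponent-derivative and center-derivative variants, and the
// integral-direct contractions used inside the SCF and gradient code.
//
// Per dimension, the basis pair is expanded in Hermite Gaussians
// Lambda_t(x; p, P); the overlap of Lambda_t with exp(-w (x-C)^2) has the
// closed form S_t = sqrt(pi/(p+w)) f^(t)(X) with f(X) = exp(-mu X^2),
// mu = p*w/(p+w), X = P - C, and f^(t) generated by the derivative
// recursion f^(t+1) = -2 mu (X f^(t) + t f^(t-1)).  Exponent derivatives
// (at fixed normalization) follow analytically from d mu/d w and
// d/d w of the prefactor.
#include "qc.h"
#include <map>
#include <string>
#include <algorithm>
using namespace Rcpp;
using namespace qc;

namespace {

constexpr int NT = 2 * LMAX + 6;

inline double pp_amax(const Shell& s) {
  double m = s.alpha[0];
  for (double a : s.alpha) m = std::max(m, a);
  return m;
}

// S_t and (optionally) dS_t/dw for t = 0..tmax
inline void stab(int tmax, double p, double P, double w, double C, double* S, double* Sd) {
  const double s = p + w, mu = p * w / s, X = P - C;
  const double c0 = std::sqrt(M_PI / s);
  double f[NT + 2];
  f[0] = std::exp(-mu * X * X);
  for (int t = 0; t < tmax + 1; ++t)
    f[t + 1] = -2.0 * mu * (X * f[t] + (t > 0 ? t * f[t - 1] : 0.0));
  for (int t = 0; t <= tmax; ++t) S[t] = c0 * f[t];
  if (Sd) {
    const double dmu = (p / s) * (p / s);
    for (int t = 0; t <= tmax; ++t) {
      double dfdmu = -(X * X * f[t]);
      if (t >= 1) dfdmu -= 2.0 * t * X * f[t - 1];
      if (t >= 2) dfdmu -= t * (t - 1.0) * f[t - 2];
      Sd[t] = -0.5 / s * S[t] + c0 * dmu * dfdmu;
    }
  }
}

// Per-dimension contraction tables for one primitive pair and tessera.
struct DimTab {
  double U[EI][EI], V[EI][EI], V2[EI][EI], Ud[EI][EI], Vd[EI][EI];
};

// Fill tables for dimension with E-tab E (filled to imax,jmax), Hermite
// exponent p, center P, tessera exponent w, center C.
inline void dimtab(DimTab& T, const ETab& E, int imax, int jmax, double p, double P, double w,
                   double C, bool with_wderiv) {
  const int tmax = imax + jmax + 2;
  double S[NT + 2], Sd[NT + 2];
  stab(tmax, p, P, w, C, S, with_wderiv ? Sd : nullptr);
  for (int i = 0; i <= imax; ++i)
    for (int j = 0; j <= jmax; ++j) {
      double u = 0, v = 0, v2 = 0, ud = 0, vd = 0;
      for (int t = 0; t <= i + j; ++t) {
        const double e = E.e[i][j][t];
        u += e * S[t];
        v -= e * S[t + 1];
        v2 += e * S[t + 2];
        if (with_wderiv) {
          ud += e * Sd[t];
          vd -= e * Sd[t + 1];
        }
      }
      T.U[i][j] = u; T.V[i][j] = v; T.V2[i][j] = v2; T.Ud[i][j] = ud; T.Vd[i][j] = vd;
    }
}

struct PairPrim {
  double a, b, cc, p, P[3];
  ETab E[3];
};

// Precompute primitive-pair data (independent of tesserae).
inline std::vector<PairPrim> pair_prims(const Shell& A, const Shell& B, int ilift, int jlift) {
  std::vector<PairPrim> out;
  out.reserve(A.alpha.size() * B.alpha.size());
  for (size_t pa = 0; pa < A.alpha.size(); ++pa)
    for (size_t pb = 0; pb < B.alpha.size(); ++pb) {
      PairPrim pp;
      pp.a = A.alpha[pa]; pp.b = B.alpha[pb];
      pp.cc = A.coef[pa] * B.coef[pb];
      pp.p = pp.a + pp.b;
      for (int d = 0; d < 3; ++d) {
        pp.P[d] = (pp.a * A.A[d] + pp.b * B.A[d]) / pp.p;
        pp.E[d].fill(A.l + ilift, B.l + jlift, pp.a, pp.b, A.A[d] - B.A[d]);
      }
      out.push_back(pp);
    }
  return out;
}

// Conservative screening envelope per shell: |phi(r)| <= C exp(-aenv |r-A|^2)
struct Envelope { double C, aenv; };

inline Envelope envelope(const Shell& s) {
  Envelope e;
  e.C = 0.0;
  double amin = s.alpha[0];
  for (size_t k = 0; k < s.alpha.size(); ++k) {
    double M = 1.0;
    if (s.l > 0) M = std::pow(s.l / (s.alpha[k] * M_E), 0.5 * s.l);
    e.C += std::fabs(s.coef[k]) * M;
    amin = std::min(amin, s.alpha[k]);
  }
  e.aenv = 0.5 * amin;
  return e;
}

inline double ov3(double al, double be, double w, const double* A, const double* B,
                  const double* C) {
  const double s = al + be + w;
  double ab = 0, ac = 0, bc = 0;
  for (int d = 0; d < 3; ++d) {
    ab += (A[d] - B[d]) * (A[d] - B[d]);
    ac += (A[d] - C[d]) * (A[d] - C[d]);
    bc += (B[d] - C[d]) * (B[d] - C[d]);
  }
  return std::pow(M_PI / s, 1.5) * std::exp(-(al * be * ab + al * w * ac + be * w * bc) / s);
}

// factor inflating the g-bound so it also covers f-, dw- and f-dw-type
// integrands (maxima of u^k exp(-w u^2 / 2) prefactors)
inline double boundfactor(double w) {
  const double f_f = std::sqrt(2.0 * w / M_E);
  const double f_gw = 2.0 / (w * M_E);
  const double f_fw = 2.0 * std::exp(-0.5) / std::sqrt(w) +
                      2.0 * std::pow(3.0, 1.5) * std::exp(-1.5) / std::sqrt(w);
  return std::max({1.0, f_f, f_gw, f_fw});
}

struct TessData {
  NumericMatrix r, nrm;
  NumericVector w, N;
  int n;
  TessData(const NumericMatrix& r_, const NumericVector& w_, const NumericVector& N_,
           const NumericMatrix& n_)
      : r(r_), nrm(n_), w(w_), N(N_), n(r_.nrow()) {}
};

}  // namespace

// Raw integral blocks for tests and oracles.  Returns, for every requested
// kind, an array [nbf, nbf, ntess] ("g","f","gw","fw") or
// [nbf, nbf, ntess, 3] ("dgdA","dgdB","dgdC","dfdA","dfdB","dfdC" --
// derivatives with respect to bra center, ket center, tessera center).
// [[Rcpp::export]]
List gost_blocks_cpp(List shells_r, NumericMatrix tr, NumericVector tw, NumericVector tN,
                     NumericMatrix tn, CharacterVector what) {
  std::vector<Shell> sh = parse_shells(shells_r);
  const int n = nbf_total(sh);
  TessData td(tr, tw, tN, tn);
  std::vector<std::string> kinds = as<std::vector<std::string>>(what);
  auto want = [&](const std::string& k) {
    return std::find(kinds.begin(), kinds.end(), k) != kinds.end();
  };
  bool need_w = want("gw") || want("fw");
  List out;
  std::map<std::string, NumericVector> arr;
  for (auto& k : kinds) {
    bool isder = k.substr(0, 2) == "dg" || k.substr(0, 2) == "df";
    NumericVector a(isder ? (R_xlen_t)n * n * td.n * 3 : (R_xlen_t)n * n * td.n);
    if (isder)
      a.attr("dim") = IntegerVector::create(n, n, td.n, 3);
    else
      a.attr("dim") = IntegerVector::create(n, n, td.n);
    arr[k] = a;
  }
  auto set = [&](const std::string& k, int mu, int nu, int j, int d, double v) {
    NumericVector& a = arr[k];
    R_xlen_t idx = (R_xlen_t)mu + n * ((R_xlen_t)nu + n * ((R_xlen_t)j + (R_xlen_t)td.n * d));
    a[idx] += v;
  };
  for (size_t is = 0; is < sh.size(); ++is)
    for (size_t js = 0; js < sh.size(); ++js) {
      const Shell &A = sh[is], &B = sh[js];
      auto ca = cart_comps(A.l), cb = cart_comps(B.l);
      auto prims = pair_prims(A, B, 1, 1);
      for (int j = 0; j < td.n; ++j) {
        const double w = td.w[j], Nj = td.N[j];
        const double C[3] = {td.r(j, 0), td.r(j, 1), td.r(j, 2)};
        const double nn[3] = {td.nrm(j, 0), td.nrm(j, 1), td.nrm(j, 2)};
        for (auto& pp : prims) {
          DimTab T[3];
          for (int d = 0; d < 3; ++d)
            dimtab(T[d], pp.E[d], A.l + 1, B.l + 1, pp.p, pp.P[d], w, C[d], need_w);
          for (int ia = 0; ia < A.nbf; ++ia)
            for (int ib = 0; ib < B.nbf; ++ib) {
              const int mu = A.off + ia, nu = B.off + ib;
              const int ax[3] = {ca[ia][0], ca[ia][1], ca[ia][2]};
              const int bx[3] = {cb[ib][0], cb[ib][1], cb[ib][2]};
              const double cN = pp.cc * Nj;
              double U[3], V[3], V2[3], Ud[3], Vd[3];
              for (int d = 0; d < 3; ++d) {
                U[d] = T[d].U[ax[d]][bx[d]];
                V[d] = T[d].V[ax[d]][bx[d]];
                V2[d] = T[d].V2[ax[d]][bx[d]];
                Ud[d] = T[d].Ud[ax[d]][bx[d]];
                Vd[d] = T[d].Vd[ax[d]][bx[d]];
              }
              auto oth = [&](int d, int& o1, int& o2) { o1 = (d + 1) % 3; o2 = (d + 2) % 3; };
              if (want("g")) set("g", mu, nu, j, 0, cN * U[0] * U[1] * U[2]);
              if (want("f")) {
                double f = 0;
                for (int d = 0; d < 3; ++d) {
                  int o1, o2; oth(d, o1, o2);
                  f += nn[d] * V[d] * U[o1] * U[o2];
                }
                set("f", mu, nu, j, 0, cN * f);
              }
              if (want("gw")) {
                double gw = 0;
                for (int d = 0; d < 3; ++d) {
                  int o1, o2; oth(d, o1, o2);
                  gw += Ud[d] * U[o1] * U[o2];
                }
                set("gw", mu, nu, j, 0, cN * gw);
              }
              if (want("fw")) {
                double fw = 0;
                for (int d = 0; d < 3; ++d) {
                  int o1, o2; oth(d, o1, o2);
                  fw += nn[d] * (Vd[d] * U[o1] * U[o2] + V[d] * Ud[o1] * U[o2] +
                                 V[d] * U[o1] * Ud[o2]);
                }
                set("fw", mu, nu, j, 0, cN * fw);
              }
              // center derivatives
              for (int d = 0; d < 3; ++d) {
                int o1, o2; oth(d, o1, o2);
                const double DUa = 2.0 * pp.a * T[d].U[ax[d] + 1][bx[d]] -
                                   (ax[d] > 0 ? ax[d] * T[d].U[ax[d] - 1][bx[d]] : 0.0);
                const double DVa = 2.0 * pp.a * T[d].V[ax[d] + 1][bx[d]] -
                                   (ax[d] > 0 ? ax[d] * T[d].V[ax[d] - 1][bx[d]] : 0.0);
                const double DUb = 2.0 * pp.b * T[d].U[ax[d]][bx[d] + 1] -
                                   (bx[d] > 0 ? bx[d] * T[d].U[ax[d]][bx[d] - 1] : 0.0);
                const double DVb = 2.0 * pp.b * T[d].V[ax[d]][bx[d] + 1] -
                                   (bx[d] > 0 ? bx[d] * T[d].V[ax[d]][bx[d] - 1] : 0.0);
                if (want("dgdA")) set("dgdA", mu, nu, j, d, cN * DUa * U[o1] * U[o2]);
                if (want("dgdB")) set("dgdB", mu, nu, j, d, cN * DUb * U[o1] * U[o2]);
                if (want("dgdC")) set("dgdC", mu, nu, j, d, cN * V[d] * U[o1] * U[o2]);
                if (want("dfdA"))
                  set("dfdA", mu, nu, j, d,
                      cN * (nn[d] * DVa * U[o1] * U[o2] + nn[o1] * DUa * V[o1] * U[o2] +
                            nn[o2] * DUa * U[o1] * V[o2]));
                if (want("dfdB"))
                  set("dfdB", mu, nu, j, d,
                      cN * (nn[d] * DVb * U[o1] * U[o2] + nn[o1] * DUb * V[o1] * U[o2] +
                            nn[o2] * DUb * U[o1] * V[o2]));
                if (want("dfdC"))
                  set("dfdC", mu, nu, j, d,
                      cN * (nn[d] * V2[d] * U[o1] * U[o2] + nn[o1] * V[d] * V[o1] * U[o2] +
                            nn[o2] * V[d] * U[o1] * V[o2]));
              }
            }
        }
      }
    }
  for (auto& k : kinds) out[k] = arr[k];
  return out;
}

// Conservative upper bounds on |g| and |f| per (shell, shell, tessera).
// [[Rcpp::export]]
List gost_bound_cpp(List shells_r, NumericMatrix tr, NumericVector tw, NumericVector tN,
                    NumericMatrix tn) {
  std::vector<Shell> sh = parse_shells(shells_r);
  const int ns = sh.size();
  TessData td(tr, tw, tN, tn);
  NumericVector bg((R_xlen_t)ns * ns * td.n), bf((R_xlen_t)ns * ns * td.n);
  bg.attr("dim") = IntegerVector::create(ns, ns, td.n);
  bf.attr("dim") = IntegerVector::create(ns, ns, td.n);
  std::vector<Envelope> env;
  for (auto& s : sh) env.push_back(envelope(s));
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < ns; ++j)
      for (int t = 0; t < td.n; ++t) {
        const double C[3] = {td.r(t, 0), td.r(t, 1), td.r(t, 2)};
        const double base = env[i].C * env[j].C * td.N[t] *
                            ov3(env[i].aenv, env[j].aenv, 0.5 * td.w[t], sh[i].A, sh[j].A, C);
        R_xlen_t id = (R_xlen_t)i + ns * ((R_xlen_t)j + (R_xlen_t)ns * t);
        bg[id] = base;
        bf[id] = base * std::sqrt(2.0 * td.w[t] / M_E);
      }
  return List::create(Named("g") = bg, Named("f") = bf);
}

// Auxiliary vectors: gt_j = sum_{mu,nu} D g, ft_j analogous with f, and
// (optionally) the exponent-derivative contractions gw_j, fw_j.
// Integral-direct: nothing of size nbf^2 x ntess is formed.
// [[Rcpp::export]]
List gost_aux_cpp(List shells_r, NumericMatrix D, NumericMatrix tr, NumericVector tw,
                  NumericVector tN, NumericMatrix tn, double thresh, bool with_wderiv) {
  std::vector<Shell> sh = parse_shells(shells_r);
  TessData td(tr, tw, tN, tn);
  NumericVector gt(td.n), ft(td.n), gw(td.n), fw(td.n);
  std::vector<Envelope> env;
  for (auto& s : sh) env.push_back(envelope(s));
  long skipped = 0, total = 0;
  for (size_t is = 0; is < sh.size(); ++is)
    for (size_t js = is; js < sh.size(); ++js) {
      const Shell &A = sh[is], &B = sh[js];
      const double wpair = (is == js) ? 1.0 : 2.0;
      auto ca = cart_comps(A.l), cb = cart_comps(B.l);
      auto prims = pair_prims(A, B, 0, 0);
      const double Cab = env[is].C * env[js].C;
      for (int j = 0; j < td.n; ++j) {
        ++total;
        const double w = td.w[j], Nj = td.N[j];
        const double C[3] = {td.r(j, 0), td.r(j, 1), td.r(j, 2)};
        if (thresh > 0) {
          const double bound = Cab * Nj * ov3(env[is].aenv, env[js].aenv, 0.5 * w, A.A, B.A, C) *
                               boundfactor(w);
          if (bound < thresh) { ++skipped; continue; }
        }
        const double nn[3] = {td.nrm(j, 0), td.nrm(j, 1), td.nrm(j, 2)};
        double agt = 0, aft = 0, agw = 0, afw = 0;
        for (auto& pp : prims) {
          DimTab T[3];
          for (int d = 0; d < 3; ++d)
            dimtab(T[d], pp.E[d], A.l, B.l, pp.p, pp.P[d], w, C[d], with_wderiv);
          for (int ia = 0; ia < A.nbf; ++ia)
            for (int ib = 0; ib < B.nbf; ++ib) {
              const double dme = D(A.off + ia, B.off + ib) * pp.cc;
              if (dme == 0.0) continue;
              const int ax[3] = {ca[ia][0], ca[ia][1], ca[ia][2]};
              const int bx[3] = {cb[ib][0], cb[ib][1], cb[ib][2]};
              double U[3], V[3], Ud[3], Vd[3];
              for (int d = 0; d < 3; ++d) {
                U[d] = T[d].U[ax[d]][bx[d]];
                V[d] = T[d].V[ax[d]][bx[d]];
                Ud[d] = T[d].Ud[ax[d]][bx[d]];
                Vd[d] = T[d].Vd[ax[d]][bx[d]];
              }
              agt += dme * U[0] * U[1] * U[2];
              aft += dme * (nn[0] * V[0] * U[1] * U[2] + nn[1] * U[0] * V[1] * U[2] +
                            nn[2] * U[0] * U[1] * V[2]);
              if (with_wderiv) {
                agw += dme * (Ud[0] * U[1] * U[2] + U[0] * Ud[1] * U[2] + U[0] * U[1] * Ud[2]);
                afw += dme * (nn[0] * (Vd[0] * U[1] * U[2] + V[0] * Ud[1] * U[2] +
                                       V[0] * U[1] * Ud[2]) +
                              nn[1] * (Ud[0] * V[1] * U[2] + U[0] * Vd[1] * U[2] +
                                       U[0] * V[1] * Ud[2]) +
                              nn[2] * (Ud[0] * U[1] * V[2] + U[0] * Ud[1] * V[2] +
                                       U[0] * U[1] * Vd[2]));
              }
            }
        }
        gt[j] += wpair * Nj * agt;
        ft[j] += wpair * Nj * aft;
        if (with_wderiv) {
          gw[j] += wpair * Nj * agw;
          fw[j] += wpair * Nj * afw;
        }
      }
    }
  return List::create(Named("gt") = gt, Named("ft") = ft, Named("gw") = gw, Named("fw") = fw,
                      Named("skipped") = (double)skipped, Named("total") = (double)total);
}

// Fock-matrix contribution F_{mu,nu} = sum_j [cg_j g_{mu nu j} + cf_j f_{mu nu j}],
// accumulated tessera-by-tessera (second integral pass).
// [[Rcpp::export]]
NumericMatrix gost_fock_cpp(List shells_r, NumericMatrix tr, NumericVector tw, NumericVector tN,
                            NumericMatrix tn, NumericVector cg, NumericVector cf,
                            double thresh) {
  std::vector<Shell> sh = parse_shells(shells_r);
  const int n = nbf_total(sh);
  TessData td(tr, tw, tN, tn);
  NumericMatrix F(n, n);
  std::vector<Envelope> env;
  for (auto& s : sh) env.push_back(envelope(s));
  for (size_t is = 0; is < sh.size(); ++is)
    for (size_t js = is; js < sh.size(); ++js) {
      const Shell &A = sh[is], &B = sh[js];
      auto ca = cart_comps(A.l), cb = cart_comps(B.l);
      auto prims = pair_prims(A, B, 0, 0);
      const double Cab = env[is].C * env[js].C;
      for (int j = 0; j < td.n; ++j) {
        const double w = td.w[j], Nj = td.N[j];
        const double C[3] = {td.r(j, 0), td.r(j, 1), td.r(j, 2)};
        if (thresh > 0) {
          const double bound = Cab * Nj * ov3(env[is].aenv, env[js].aenv, 0.5 * w, A.A, B.A, C) *
                               boundfactor(w);
          if (bound < thresh) continue;
        }
        const double nn[3] = {td.nrm(j, 0), td.nrm(j, 1), td.nrm(j, 2)};
        const double cgj = cg[j] * Nj, cfj = cf[j] * Nj;
        for (auto& pp : prims) {
          DimTab T[3];
          for (int d = 0; d < 3; ++d)
            dimtab(T[d], pp.E[d], A.l, B.l, pp.p, pp.P[d], w, C[d], false);
          for (int ia = 0; ia < A.nbf; ++ia)
            for (int ib = 0; ib < B.nbf; ++ib) {
              const int ax[3] = {ca[ia][0], ca[ia][1], ca[ia][2]};
              const int bx[3] = {cb[ib][0], cb[ib][1], cb[ib][2]};
              double U[3], V[3];
              for (int d = 0; d < 3; ++d) {
                U[d] = T[d].U[ax[d]][bx[d]];
                V[d] = T[d].V[ax[d]][bx[d]];
              }
              const double g = U[0] * U[1] * U[2];
              const double f = nn[0] * V[0] * U[1] * U[2] + nn[1] * U[0] * V[1] * U[2] +
                               nn[2] * U[0] * U[1] * V[2];
              F(A.off + ia, B.off + ib) += pp.cc * (cgj * g + cfj * f);
            }
        }
      }
    }
  // symmetrize (blocks computed for is <= js only)
  for (size_t is = 0; is < sh.size(); ++is)
    for (size_t js = is; js < sh.size(); ++js) {
      const Shell &A = sh[is], &B = sh[js];
      if (is == js) continue;
      for (int ia = 0; ia < A.nbf; ++ia)
        for (int ib = 0; ib < B.nbf; ++ib)
          F(B.off + ib, A.off + ia) = F(A.off + ia, B.off + ib);
    }
  // diagonal-shell blocks: enforce exact symmetry
  for (size_t is = 0; is < sh.size(); ++is) {
    const Shell& A = sh[is];
    for (int ia = 0; ia < A.nbf; ++ia)
      for (int ib = ia + 1; ib < A.nbf; ++ib) {
        double v = F(A.off + ia, A.off + ib);
        F(A.off + ib, A.off + ia) = v;
      }
  }
  return F;
}

// Center-derivative gradient contraction: accumulates per atom
//   sum_j sum_{mu,nu} D_{mu,nu} [cg_j dg/dR + cf_j df/dR]
// where bra derivatives attach to the bra shell's atom, ket derivatives to
// the ket shell's atom, and the tessera-center derivative (obtained from
// translational invariance as minus their sum) to the tessera's parent atom.
// [[Rcpp::export]]
NumericMatrix gost_grad_cpp(List shells_r, NumericMatrix D, NumericMatrix tr, NumericVector tw,
                            NumericVector tN, NumericMatrix tn, NumericVector cg,
                            NumericVector cf, IntegerVector parent, int natom, double thresh) {
  std::vector<Shell> sh = parse_shells(shells_r);
  TessData td(tr, tw, tN, tn);
  NumericMatrix g(natom, 3);
  std::vector<Envelope> env;
  for (auto& s : sh) env.push_back(envelope(s));
  for (size_t is = 0; is < sh.size(); ++is)
    for (size_t js = is; js < sh.size(); ++js) {
      const Shell &A = sh[is], &B = sh[js];
      const double wpair = (is == js) ? 1.0 : 2.0;
      auto ca = cart_comps(A.l), cb = cart_comps(B.l);
      auto prims = pair_prims(A, B, 1, 1);
      const double Cab = env[is].C * env[js].C;
      for (int j = 0; j < td.n; ++j) {
        const double w = td.w[j], Nj = td.N[j];
        const double C[3] = {td.r(j, 0), td.r(j, 1), td.r(j, 2)};
        if (thresh > 0) {
          const double bound = Cab * Nj * ov3(env[is].aenv, env[js].aenv, 0.5 * w, A.A, B.A, C) *
                               boundfactor(w) * (2.0 * (pp_amax(A) + pp_amax(B)) + A.l + B.l + 2.0);
          if (bound < thresh) continue;
        }
        const double nn[3] = {td.nrm(j, 0), td.nrm(j, 1), td.nrm(j, 2)};
        const double cgj = cg[j] * Nj, cfj = cf[j] * Nj;
        double accA[3] = {0, 0, 0}, accB[3] = {0, 0, 0};
        for (auto& pp : prims) {
          DimTab T[3];
          for (int d = 0; d < 3; ++d)
            dimtab(T[d], pp.E[d], A.l + 1, B.l + 1, pp.p, pp.P[d], w, C[d], false);
          for (int ia = 0; ia < A.nbf; ++ia)
            for (int ib = 0; ib < B.nbf; ++ib) {
              const double dme = D(A.off + ia, B.off + ib) * pp.cc;
              if (dme == 0.0) continue;
              const int ax[3] = {ca[ia][0], ca[ia][1], ca[ia][2]};
              const int bx[3] = {cb[ib][0], cb[ib][1], cb[ib][2]};
              double U[3], V[3];
              for (int d = 0; d < 3; ++d) {
                U[d] = T[d].U[ax[d]][bx[d]];
                V[d] = T[d].V[ax[d]][bx[d]];
              }
              for (int d = 0; d < 3; ++d) {
                const int o1 = (d + 1) % 3, o2 = (d + 2) % 3;
                const double DUa = 2.0 * pp.a * T[d].U[ax[d] + 1][bx[d]] -
                                   (ax[d] > 0 ? ax[d] * T[d].U[ax[d] - 1][bx[d]] : 0.0);
                const double DVa = 2.0 * pp.a * T[d].V[ax[d] + 1][bx[d]] -
                                   (ax[d] > 0 ? ax[d] * T[d].V[ax[d] - 1][bx[d]] : 0.0);
                const double DUb = 2.0 * pp.b * T[d].U[ax[d]][bx[d] + 1] -
                                   (bx[d] > 0 ? bx[d] * T[d].U[ax[d]][bx[d] - 1] : 0.0);
                const double DVb = 2.0 * pp.b * T[d].V[ax[d]][bx[d] + 1] -
                                   (bx[d] > 0 ? bx[d] * T[d].V[ax[d]][bx[d] - 1] : 0.0);
                const double dgA = DUa * U[o1] * U[o2];
                const double dgB = DUb * U[o1] * U[o2];
                const double dfA = nn[d] * DVa * U[o1] * U[o2] + nn[o1] * DUa * V[o1] * U[o2] +
                                   nn[o2] * DUa * U[o1] * V[o2];
                const double dfB = nn[d] * DVb * U[o1] * U[o2] + nn[o1] * DUb * V[o1] * U[o2] +
                                   nn[o2] * DUb * U[o1] * V[o2];
                accA[d] += dme * (cgj * dgA + cfj * dfA);
                accB[d] += dme * (cgj * dgB + cfj * dfB);
              }
            }
        }
        for (int d = 0; d < 3; ++d) {
          g(A.atom, d) += wpair * accA[d];
          g(B.atom, d) += wpair * accB[d];
          g(parent[j] - 1, d) -= wpair * (accA[d] + accB[d]);
        }
      }
    }
  return g;
}
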