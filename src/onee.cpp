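// One-electron integrals (overlap, kinetic, nuclear attraction) and their
// nuclear-derivative contractions for the restricted Hartree-Fock engine.
#include "qc.h"
using namespace Rcpp;
using namespace qc;

namespace {

// 1-d overlap S_ij = E_0^{ij} sqrt(pi/p); kinetic uses lifted/lowered j.
inline double s1d(const ETab& E, int i, int j, double pref) { return E.e[i][j][0] * pref; }

inline double k1d(const ETab& E, int i, int j, double b, double pref) {
  double v = -2.0 * b * b * s1d(E, i, j + 2, pref) + b * (2.0 * j + 1.0) * s1d(E, i, j, pref);
  if (j >= 2) v -= 0.5 * j * (j - 1.0) * s1d(E, i, j - 2, pref);
  return v;
}

}  // namespace

// [[Rcpp::export]]
List one_electron_cpp(List shells_r, NumericMatrix coords, NumericVector Z) {
  std::vector<Shell> sh = parse_shells(shells_r);
  const int n = nbf_total(sh), natom = coords.nrow();
  NumericMatrix S(n, n), T(n, n), V(n, n);
  for (size_t is = 0; is < sh.size(); ++is)
    for (size_t js = is; js < sh.size(); ++js) {
      const Shell &sa = sh[is], &sb = sh[js];
      auto ca = cart_comps(sa.l), cb = cart_comps(sb.l);
      std::vector<double> bS(sa.nbf * sb.nbf, 0.0), bT(sa.nbf * sb.nbf, 0.0),
          bV(sa.nbf * sb.nbf, 0.0);
      for (size_t pa = 0; pa < sa.alpha.size(); ++pa)
        for (size_t pb = 0; pb < sb.alpha.size(); ++pb) {
          const double a = sa.alpha[pa], b = sb.alpha[pb], cc = sa.coef[pa] * sb.coef[pb];
          const double p = a + b, pref = std::sqrt(M_PI / p);
          ETab Ex, Ey, Ez;
          Ex.fill(sa.l, sb.l + 2, a, b, sa.A[0] - sb.A[0]);
          Ey.fill(sa.l, sb.l + 2, a, b, sa.A[1] - sb.A[1]);
          Ez.fill(sa.l, sb.l + 2, a, b, sa.A[2] - sb.A[2]);
          double P[3];
          for (int d = 0; d < 3; ++d) P[d] = (a * sa.A[d] + b * sb.A[d]) / p;
          // nuclear attraction Hermite tables per nucleus
          const int tmax = sa.l + sb.l;
          std::vector<RTab> rt(natom);
          for (int c = 0; c < natom; ++c)
            rt[c].fill(tmax, tmax, tmax, p, P[0] - coords(c, 0), P[1] - coords(c, 1),
                       P[2] - coords(c, 2));
          const double vpref = 2.0 * M_PI / p;
          for (int ia = 0; ia < sa.nbf; ++ia)
            for (int ib = 0; ib < sb.nbf; ++ib) {
              const int ax = ca[ia][0], ay = ca[ia][1], az = ca[ia][2];
              const int bx = cb[ib][0], by = cb[ib][1], bz = cb[ib][2];
              const double sx = s1d(Ex, ax, bx, pref), sy = s1d(Ey, ay, by, pref),
                           sz = s1d(Ez, az, bz, pref);
              bS[ia * sb.nbf + ib] += cc * sx * sy * sz;
              bT[ia * sb.nbf + ib] +=
                  cc * (k1d(Ex, ax, bx, b, pref) * sy * sz + sx * k1d(Ey, ay, by, b, pref) * sz +
                        sx * sy * k1d(Ez, az, bz, b, pref));
              double vsum = 0.0;
              for (int c = 0; c < natom; ++c) {
                if (Z[c] == 0.0) continue;
                double acc = 0.0;
                for (int t = 0; t <= ax + bx; ++t)
                  for (int u = 0; u <= ay + by; ++u)
                    for (int v = 0; v <= az + bz; ++v)
                      acc += Ex.e[ax][bx][t] * Ey.e[ay][by][u] * Ez.e[az][bz][v] *
                             rt[c].at(t, u, v);
                vsum -= Z[c] * acc;
              }
              bV[ia * sb.nbf + ib] += cc * vpref * vsum;
            }
        }
      for (int ia = 0; ia < sa.nbf; ++ia)
        for (int ib = 0; ib < sb.nbf; ++ib) {
          const int mu = sa.off + ia, nu = sb.off + ib;
          S(mu, nu) = S(nu, mu) = bS[ia * sb.nbf + ib];
          T(mu, nu) = T(nu, mu) = bT[ia * sb.nbf + ib];
          V(mu, nu) = V(nu, mu) = bV[ia * sb.nbf + ib];
        }
    }
  return List::create(Named("S") = S, Named("T") = T, Named("V") = V);
}

// Gradient contractions: sum_{mu,nu} D_{mu,nu} d(T+V)_{mu,nu}/dR and
// sum_{mu,nu} W_{mu,nu} dS_{mu,nu}/dR, accumulated per atom.  Bra-side
// derivatives are formed by angular-momentum shifts with the 2*alpha
// factor inside the primitive contraction; ket (S, T) and operator-center
// (V) derivatives follow from translational invariance.
// [[Rcpp::export]]
List hf_grad_onee_cpp(List shells_r, NumericMatrix coords, NumericVector Z, NumericMatrix D,
                      NumericMatrix W) {
  std::vector<Shell> sh = parse_shells(shells_r);
  const int natom = coords.nrow();
  NumericMatrix gH(natom, 3), gS(natom, 3);
  for (size_t is = 0; is < sh.size(); ++is)
    for (size_t js = 0; js < sh.size(); ++js) {
      const Shell &sa = sh[is], &sb = sh[js];
      auto ca = cart_comps(sa.l), cb = cart_comps(sb.l);
      for (size_t pa = 0; pa < sa.alpha.size(); ++pa)
        for (size_t pb = 0; pb < sb.alpha.size(); ++pb) {
          const double a = sa.alpha[pa], b = sb.alpha[pb], cc = sa.coef[pa] * sb.coef[pb];
          const double p = a + b, pref = std::sqrt(M_PI / p);
          ETab E[3];
          for (int d = 0; d < 3; ++d) E[d].fill(sa.l + 1, sb.l + 2, a, b, sa.A[d] - sb.A[d]);
          double P[3];
          for (int d = 0; d < 3; ++d) P[d] = (a * sa.A[d] + b * sb.A[d]) / p;
          const int tmax = sa.l + 1 + sb.l;
          std::vector<RTab> rt(natom);
          for (int c = 0; c < natom; ++c)
            rt[c].fill(tmax, tmax, tmax, p, P[0] - coords(c, 0), P[1] - coords(c, 1),
                       P[2] - coords(c, 2));
          const double vpref = 2.0 * M_PI / p;
          for (int ia = 0; ia < sa.nbf; ++ia)
            for (int ib = 0; ib < sb.nbf; ++ib) {
              const double dmn = D(sa.off + ia, sb.off + ib);
              const double wmn = W(sa.off + ia, sb.off + ib);
              int la[3] = {ca[ia][0], ca[ia][1], ca[ia][2]};
              int lb[3] = {cb[ib][0], cb[ib][1], cb[ib][2]};
              for (int d = 0; d < 3; ++d) {
                // bra-derivative 1-d factors for S and T in dimension d
                const int o1 = (d + 1) % 3, o2 = (d + 2) % 3;
                auto sd = [&](int i, int j, ETab& e) { return s1d(e, i, j, pref); };
                double dS1 = 2.0 * a * sd(la[d] + 1, lb[d], E[d]);
                double dT1 = 2.0 * a * k1d(E[d], la[d] + 1, lb[d], b, pref);
                if (la[d] > 0) {
                  dS1 -= la[d] * sd(la[d] - 1, lb[d], E[d]);
                  dT1 -= la[d] * k1d(E[d], la[d] - 1, lb[d], b, pref);
                }
                const double so1 = sd(la[o1], lb[o1], E[o1]), so2 = sd(la[o2], lb[o2], E[o2]);
                const double ko1 = k1d(E[o1], la[o1], lb[o1], b, pref),
                             ko2 = k1d(E[o2], la[o2], lb[o2], b, pref);
                const double dSd = dS1 * so1 * so2;
                const double dTd = dT1 * so1 * so2 + dS1 * (ko1 * so2 + so1 * ko2);
                // S and T depend on A and B only: dB = -dA
                gS(sa.atom, d) += wmn * cc * dSd;
                gS(sb.atom, d) -= wmn * cc * dSd;
                gH(sa.atom, d) += dmn * cc * dTd;
                gH(sb.atom, d) -= dmn * cc * dTd;
              }
              // nuclear attraction: bra derivative and operator-center
              // (Hellmann-Feynman) derivative; ket from invariance
              for (int c = 0; c < natom; ++c) {
                if (Z[c] == 0.0) continue;
                for (int d = 0; d < 3; ++d) {
                  int lap[3] = {la[0], la[1], la[2]};
                  lap[d] += 1;
                  auto vterm = [&](const int* A3, int extra_t_dim, int shift) {
                    double acc = 0.0;
                    for (int t = 0; t <= A3[0] + lb[0]; ++t)
                      for (int u = 0; u <= A3[1] + lb[1]; ++u)
                        for (int v = 0; v <= A3[2] + lb[2]; ++v) {
                          int tt = t + (extra_t_dim == 0 ? shift : 0);
                          int uu = u + (extra_t_dim == 1 ? shift : 0);
                          int vv = v + (extra_t_dim == 2 ? shift : 0);
                          acc += E[0].e[A3[0]][lb[0]][t] * E[1].e[A3[1]][lb[1]][u] *
                                 E[2].e[A3[2]][lb[2]][v] * rt[c].at(tt, uu, vv);
                        }
                    return acc;
                  };
                  double dA = 2.0 * a * vterm(lap, -1, 0);
                  if (la[d] > 0) {
                    int lam[3] = {la[0], la[1], la[2]};
                    lam[d] -= 1;
                    dA -= la[d] * vterm(lam, -1, 0);
                  }
                  // d/dC_d: R_tuv argument is (P - C) so one extra Hermite index
                  double dC = -vterm(la, d, 1);
                  dA *= -Z[c] * cc * vpref * dmn;
                  dC *= -Z[c] * cc * vpref * dmn;
                  gH(sa.atom, d) += dA;
                  gH(c, d) += dC;
                  gH(sb.atom, d) -= dA + dC;
                }
              }
            }
        }
    }
  return List::create(Named("hcore") = gH, Named("overlap") = gS);
}
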