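// Two-electron repulsion integrals over contracted Cartesian Gaussian
// shells (McMurchie-Davidson with Hermite Coulomb integrals) and the
// derivative contraction entering the Hartree-Fock nuclear gradient.
#include "qc.h"
using namespace Rcpp;
using namespace qc;

namespace {

// Contracted ERI block for four shells with explicit angular momenta.
// Coefficients are taken from the shells; lifted-l derivative variants
// pass scaled coefficients (2*alpha folded in) through `ascale` flags.
struct Quartet {
  const Shell *a, *b, *c, *d;
  int la, lb, lc, ld;
  bool scale_a = false, scale_b = false, scale_c = false;
};

struct EriPrim {
  double c, p, P[3];
  ETab E[3];
};

void eri_prims(const Shell& A, const Shell& B, int la, int lb, bool scale_a, bool scale_b,
               std::vector<EriPrim>& out) {
  out.clear();
  for (size_t pa = 0; pa < A.alpha.size(); ++pa)
    for (size_t pb = 0; pb < B.alpha.size(); ++pb) {
      EriPrim pp;
      const double a = A.alpha[pa], b = B.alpha[pb];
      pp.p = a + b;
      pp.c = A.coef[pa] * B.coef[pb];
      if (scale_a) pp.c *= 2.0 * a;
      if (scale_b) pp.c *= 2.0 * b;
      for (int d = 0; d < 3; ++d) {
        pp.P[d] = (a * A.A[d] + b * B.A[d]) / pp.p;
        pp.E[d].fill(la, lb, a, b, A.A[d] - B.A[d]);
      }
      out.push_back(pp);
    }
}

void eri_block(const Quartet& qt, std::vector<double>& out) {
  const Shell &A = *qt.a, &B = *qt.b, &C = *qt.c, &D = *qt.d;
  const int la = qt.la, lb = qt.lb, lc = qt.lc, ld = qt.ld;
  auto ca = cart_comps(la), cb = cart_comps(lb), cc2 = cart_comps(lc), cd = cart_comps(ld);
  const int na = ncart(la), nb = ncart(lb), nc = ncart(lc), nd = ncart(ld);
  out.assign((size_t)na * nb * nc * nd, 0.0);
  const int nbra = la + lb + 1;
  const int cube = nbra * nbra * nbra;
  static std::vector<double> Rket;
  Rket.assign((size_t)nc * nd * cube, 0.0);
  static std::vector<EriPrim> bra, ket;
  static RTab R;
  eri_prims(A, B, la, lb, qt.scale_a, qt.scale_b, bra);
  eri_prims(C, D, lc, ld, qt.scale_c, false, ket);
  for (auto& bp : bra) {
    const double p = bp.p, cab = bp.c;
    const double* P = bp.P;
    const ETab* E1 = bp.E;
    const double kab = E1[0].e[0][0][0] * E1[1].e[0][0][0] * E1[2].e[0][0][0];
    for (auto& kp : ket) {
          const double q = kp.p, ccd = kp.c;
          const double* Q = kp.P;
          const ETab* E2 = kp.E;
          const double alpha = p * q / (p + q);
          const double pref =
              2.0 * std::pow(M_PI, 2.5) / (p * q * std::sqrt(p + q)) * cab * ccd;
          const double kcd = E2[0].e[0][0][0] * E2[1].e[0][0][0] * E2[2].e[0][0][0];
          if (std::fabs(pref) * kab * kcd < 1e-18) continue;
          R.fill(la + lb + lc + ld, la + lb + lc + ld, la + lb + lc + ld, alpha,
                 P[0] - Q[0], P[1] - Q[1], P[2] - Q[2]);
          // ket Hermite distributions contracted with R over the bra cube
          for (int ic = 0; ic < nc; ++ic)
            for (int id = 0; id < nd; ++id) {
              double* rk = &Rket[((size_t)ic * nd + id) * cube];
              const int cx = cc2[ic][0], cy = cc2[ic][1], cz = cc2[ic][2];
              const int dx = cd[id][0], dy = cd[id][1], dz = cd[id][2];
              for (int t = 0; t < nbra; ++t)
                for (int u = 0; u < nbra; ++u)
                  for (int v = 0; v < nbra; ++v) {
                    double acc = 0.0;
                    for (int tt = 0; tt <= cx + dx; ++tt)
                      for (int uu = 0; uu <= cy + dy; ++uu)
                        for (int vv = 0; vv <= cz + dz; ++vv) {
                          const double sgn = ((tt + uu + vv) & 1) ? -1.0 : 1.0;
                          acc += sgn * E2[0].e[cx][dx][tt] * E2[1].e[cy][dy][uu] *
                                 E2[2].e[cz][dz][vv] * R.at(t + tt, u + uu, v + vv);
                        }
                    rk[(t * nbra + u) * nbra + v] = acc;
                  }
            }
          for (int ia = 0; ia < na; ++ia)
            for (int ib = 0; ib < nb; ++ib) {
              const int axv = ca[ia][0], ayv = ca[ia][1], azv = ca[ia][2];
              const int bxv = cb[ib][0], byv = cb[ib][1], bzv = cb[ib][2];
              for (int ic = 0; ic < nc; ++ic)
                for (int id = 0; id < nd; ++id) {
                  const double* rk = &Rket[((size_t)ic * nd + id) * cube];
                  double acc = 0.0;
                  for (int t = 0; t <= axv + bxv; ++t)
                    for (int u = 0; u <= ayv + byv; ++u)
                      for (int v = 0; v <= azv + bzv; ++v)
                        acc += E1[0].e[axv][bxv][t] * E1[1].e[ayv][byv][u] *
                               E1[2].e[azv][bzv][v] * rk[(t * nbra + u) * nbra + v];
                  out[(((size_t)ia * nb + ib) * nc + ic) * nd + id] += pref * acc;
                }
            }
        }
    }
}

}  // namespace

// Full ERI tensor [n,n,n,n] with Schwarz screening of shell quartets.
// [[Rcpp::export]]
NumericVector eri_cpp(List shells_r, double schwarz_thresh = 1e-14) {
  std::vector<Shell> sh = parse_shells(shells_r);
  const int ns = sh.size(), n = nbf_total(sh);
  NumericVector out((R_xlen_t)n * n * n * n);
  out.attr("dim") = IntegerVector::create(n, n, n, n);
  double* o = out.begin();
  // Schwarz factors sqrt(max |(ab|ab)|) per shell pair
  std::vector<std::vector<double>> K(ns, std::vector<double>(ns));
  std::vector<double> blk;
  for (int i = 0; i < ns; ++i)
    for (int j = i; j < ns; ++j) {
      Quartet qt{&sh[i], &sh[j], &sh[i], &sh[j], sh[i].l, sh[j].l, sh[i].l, sh[j].l};
      eri_block(qt, blk);
      double m = 0.0;
      for (int ia = 0; ia < sh[i].nbf; ++ia)
        for (int ib = 0; ib < sh[j].nbf; ++ib) {
          double v = blk[(((size_t)ia * sh[j].nbf + ib) * sh[i].nbf + ia) * sh[j].nbf + ib];
          m = std::max(m, std::fabs(v));
        }
      K[i][j] = K[j][i] = std::sqrt(m);
    }
  auto idx = [n](int a, int b, int c, int d) {
    return (R_xlen_t)a + n * ((R_xlen_t)b + n * ((R_xlen_t)c + n * (R_xlen_t)d));
  };
  for (int i = 0; i < ns; ++i)
    for (int j = i; j < ns; ++j)
      for (int k = i; k < ns; ++k)
        for (int l = (k == i ? j : k); l < ns; ++l) {
          if (K[i][j] * K[k][l] < schwarz_thresh) continue;
          Quartet qt{&sh[i], &sh[j], &sh[k], &sh[l], sh[i].l, sh[j].l, sh[k].l, sh[l].l};
          eri_block(qt, blk);
          for (int ia = 0; ia < sh[i].nbf; ++ia)
            for (int ib = 0; ib < sh[j].nbf; ++ib)
              for (int ic = 0; ic < sh[k].nbf; ++ic)
                for (int id = 0; id < sh[l].nbf; ++id) {
                  const double v =
                      blk[(((size_t)ia * sh[j].nbf + ib) * sh[k].nbf + ic) * sh[l].nbf + id];
                  const int mu = sh[i].off + ia, nu = sh[j].off + ib, la = sh[k].off + ic,
                            si = sh[l].off + id;
                  o[idx(mu, nu, la, si)] = v;
                  o[idx(nu, mu, la, si)] = v;
                  o[idx(mu, nu, si, la)] = v;
                  o[idx(nu, mu, si, la)] = v;
                  o[idx(la, si, mu, nu)] = v;
                  o[idx(si, la, mu, nu)] = v;
                  o[idx(la, si, nu, mu)] = v;
                  o[idx(si, la, nu, mu)] = v;
                }
        }
  return out;
}

// Two-electron gradient contraction: dE2/dR_I = 1/2 sum_{abcd} Gamma_abcd
// d(ab|cd)/dR_I with Gamma_abcd = D_ab D_cd - 1/2 D_ac D_bd (closed-shell
// RHF).  Derivatives with respect to three centers are computed by
// angular-momentum shifts; the fourth follows from translational
// invariance.
// [[Rcpp::export]]
NumericMatrix hf_grad_eri_cpp(List shells_r, NumericMatrix D, int natom) {
  std::vector<Shell> sh = parse_shells(shells_r);
  const int ns = sh.size();
  NumericMatrix g(natom, 3);
  std::vector<double> bp, bm, tmp;
  const int ex[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  auto comp_index = [](const std::array<int, 3>& c) {
    // index of component (lx,ly,lz) within its shell's ordering
    const int l = c[0] + c[1] + c[2];
    int k = 0;
    for (int lx = l; lx >= 0; --lx)
      for (int ly = l - lx; ly >= 0; --ly) {
        if (lx == c[0] && ly == c[1]) return k;
        ++k;
      }
    return -1;
  };
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j < ns; ++j)
      for (int k = 0; k < ns; ++k)
        for (int l = 0; l < ns; ++l) {
          const Shell &A = sh[i], &B = sh[j], &C = sh[k], &Ds = sh[l];
          auto ca = cart_comps(A.l), cb = cart_comps(B.l), cc = cart_comps(C.l),
               cd = cart_comps(Ds.l);
          // Gamma for this block
          std::vector<double> G((size_t)A.nbf * B.nbf * C.nbf * Ds.nbf);
          double gmax = 0.0;
          for (int ia = 0; ia < A.nbf; ++ia)
            for (int ib = 0; ib < B.nbf; ++ib)
              for (int ic = 0; ic < C.nbf; ++ic)
                for (int id = 0; id < Ds.nbf; ++id) {
                  const int mu = A.off + ia, nu = B.off + ib, lam = C.off + ic,
                            sg = Ds.off + id;
                  double v = D(mu, nu) * D(lam, sg) - 0.5 * D(mu, lam) * D(nu, sg);
                  G[(((size_t)ia * B.nbf + ib) * C.nbf + ic) * Ds.nbf + id] = v;
                  gmax = std::max(gmax, std::fabs(v));
                }
          if (gmax < 1e-14) continue;
          // derivative for centers A, B, C; D via invariance
          double dAcc[3][3] = {{0}};  // [which center][dim]
          for (int w = 0; w < 3; ++w) {  // 0:A 1:B 2:C
            const Shell* tgt = (w == 0) ? &A : (w == 1) ? &B : &C;
            Quartet qp{&A, &B, &C, &Ds, A.l, B.l, C.l, Ds.l};
            if (w == 0) { qp.la += 1; qp.scale_a = true; }
            if (w == 1) { qp.lb += 1; qp.scale_b = true; }
            if (w == 2) { qp.lc += 1; qp.scale_c = true; }
            eri_block(qp, bp);
            bool have_m = tgt->l > 0;
            if (have_m) {
              Quartet qm{&A, &B, &C, &Ds, A.l, B.l, C.l, Ds.l};
              if (w == 0) qm.la -= 1;
              if (w == 1) qm.lb -= 1;
              if (w == 2) qm.lc -= 1;
              eri_block(qm, bm);
            }
            const int nbp[4] = {w == 0 ? ncart(A.l + 1) : A.nbf,
                                w == 1 ? ncart(B.l + 1) : B.nbf,
                                w == 2 ? ncart(C.l + 1) : C.nbf, Ds.nbf};
            const int nbm[4] = {w == 0 ? ncart(A.l - 1) : A.nbf,
                                w == 1 ? ncart(B.l - 1) : B.nbf,
                                w == 2 ? ncart(C.l - 1) : C.nbf, Ds.nbf};
            for (int ia = 0; ia < A.nbf; ++ia)
              for (int ib = 0; ib < B.nbf; ++ib)
                for (int ic = 0; ic < C.nbf; ++ic)
                  for (int id = 0; id < Ds.nbf; ++id) {
                    const double gcoef =
                        G[(((size_t)ia * B.nbf + ib) * C.nbf + ic) * Ds.nbf + id];
                    if (std::fabs(gcoef) < 1e-16) continue;
                    const std::array<int, 3>& tc =
                        (w == 0) ? ca[ia] : (w == 1) ? cb[ib] : cc[ic];
                    for (int d = 0; d < 3; ++d) {
                      std::array<int, 3> up = tc, dn = tc;
                      up[d] += 1;
                      dn[d] -= 1;
                      int iup = comp_index(up);
                      int i4[4] = {ia, ib, ic, id};
                      i4[w] = iup;
                      double val =
                          bp[(((size_t)i4[0] * nbp[1] + i4[1]) * nbp[2] + i4[2]) * nbp[3] +
                             i4[3]];
                      if (tc[d] > 0) {
                        int idn = comp_index(dn);
                        int i4m[4] = {ia, ib, ic, id};
                        i4m[w] = idn;
                        val -= tc[d] *
                               bm[(((size_t)i4m[0] * nbm[1] + i4m[1]) * nbm[2] + i4m[2]) *
                                      nbm[3] +
                                  i4m[3]];
                      }
                      dAcc[w][d] += gcoef * val;
                    }
                  }
          }
          for (int d = 0; d < 3; ++d) {
            g(A.atom, d) += 0.5 * dAcc[0][d];
            g(B.atom, d) += 0.5 * dAcc[1][d];
            g(C.atom, d) += 0.5 * dAcc[2][d];
            g(Ds.atom, d) -= 0.5 * (dAcc[0][d] + dAcc[1][d] + dAcc[2][d]);
          }
        }
  return g;
}
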