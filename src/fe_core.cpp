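// Core finite-element kernels: transversely isotropic hyperelastic point
// stress and hexahedral residual/tangent assembly with mean-dilatation
// treatment of the volumetric term (guards against locking near
// incompressibility with trilinear elements). The element tangent is built
// by central finite differences on the element dofs; reference-configuration
// quantities (shape gradients, Jacobians) are precomputed once per element
// so each perturbed residual costs only the constitutive update.
//
// Units package-wide: mm, N, MPa.

#include <RcppArmadillo.h>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

// Local node coordinates of the 8-node hex, VTK ordering; zeta is axial.
static const double XI[8][3] = {
  {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
  {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1}
};

static inline double det3(const double F[9]) {
  return F[0] * (F[4] * F[8] - F[5] * F[7]) -
         F[3] * (F[1] * F[8] - F[2] * F[7]) +
         F[6] * (F[1] * F[5] - F[2] * F[4]);
}

// column-major 3x3 inverse
static inline void inv3(const double F[9], double Fi[9]) {
  const double d = det3(F);
  const double id = 1.0 / d;
  Fi[0] = (F[4] * F[8] - F[5] * F[7]) * id;
  Fi[1] = (F[2] * F[7] - F[1] * F[8]) * id;
  Fi[2] = (F[1] * F[5] - F[2] * F[4]) * id;
  Fi[3] = (F[5] * F[6] - F[3] * F[8]) * id;
  Fi[4] = (F[0] * F[8] - F[2] * F[6]) * id;
  Fi[5] = (F[2] * F[3] - F[0] * F[5]) * id;
  Fi[6] = (F[3] * F[7] - F[4] * F[6]) * id;
  Fi[7] = (F[1] * F[6] - F[0] * F[7]) * id;
  Fi[8] = (F[0] * F[4] - F[1] * F[3]) * id;
}

// Piecewise fiber stress law lambda * dF2/dlambda.
static inline double fiber_stress_c(double lam, const double *pp) {
  if (lam <= 1.0) return 0.0;
  if (lam <= pp[5]) return pp[1] * (std::exp(pp[2] * (lam - 1.0)) - 1.0);
  return pp[3] * lam + pp[4];
}

// Isochoric Cauchy stress (column-major sig[9]), given F (column-major) and
// its determinant; pp = (c1, c3, c4, c5, c6, lambda_star, kappa).
static inline void cauchy_iso_fast(const double F[9], double J,
                                   const double a0[3], const double *pp,
                                   double sig[9]) {
  const double Jm23 = std::pow(J, -2.0 / 3.0);
  double b[9]; // F F^T
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      double s = 0;
      for (int k = 0; k < 3; ++k) s += F[i + 3 * k] * F[j + 3 * k];
      b[i + 3 * j] = s;
    }
  const double cb = pp[0] * Jm23 / J;
  const double tr3 = (b[0] + b[4] + b[8]) / 3.0;
  for (int c = 0; c < 9; ++c) sig[c] = cb * b[c];
  sig[0] -= cb * tr3; sig[4] -= cb * tr3; sig[8] -= cb * tr3;
  double m[3];
  for (int i = 0; i < 3; ++i)
    m[i] = F[i] * a0[0] + F[i + 3] * a0[1] + F[i + 6] * a0[2];
  const double mn2 = m[0] * m[0] + m[1] * m[1] + m[2] * m[2];
  const double lambar = std::sqrt(Jm23 * mn2);
  const double f = fiber_stress_c(lambar, pp);
  if (f != 0.0) {
    const double cf = f / (J * mn2);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) sig[i + 3 * j] += cf * m[i] * m[j];
    const double f3 = f / (3.0 * J);
    sig[0] -= f3; sig[4] -= f3; sig[8] -= f3;
  }
}

// Full point Cauchy stress with local volumetric pressure kappa*lnJ/J.
// params: c1 c3 c4 c5 c6 lambda_star kappa
// [[Rcpp::export(name = ".tt_cauchy_point")]]
Rcpp::NumericMatrix tt_cauchy_point(Rcpp::NumericMatrix Fin,
                                    Rcpp::NumericVector a0in,
                                    Rcpp::NumericVector params) {
  double F[9], a0[3], sig[9];
  for (int c = 0; c < 9; ++c) F[c] = Fin[c];
  for (int i = 0; i < 3; ++i) a0[i] = a0in[i];
  const double J = det3(F);
  if (J <= 0) Rcpp::stop("det(F) must be positive");
  cauchy_iso_fast(F, J, a0, params.begin(), sig);
  const double p = params[6] * std::log(J) / J;
  sig[0] += p; sig[4] += p; sig[8] += p;
  Rcpp::NumericMatrix out(3, 3);
  for (int c = 0; c < 9; ++c) out[c] = sig[c];
  return out;
}

// Precomputed per-element reference data: for each of the 8 Gauss points the
// material shape gradients dN/dX (8 nodes x 3) and the reference Jacobian.
struct ElemRef {
  double dNdX[8][8][3];
  double detJx[8];
  double vol0;
};

struct GaussBasis {
  double dNl[8][8][3]; // gp, node, comp
  GaussBasis() {
    const double g = 1.0 / std::sqrt(3.0);
    int q = 0;
    for (int k = 0; k < 2; ++k)
      for (int j = 0; j < 2; ++j)
        for (int i = 0; i < 2; ++i, ++q) {
          const double xi = (2 * i - 1) * g, eta = (2 * j - 1) * g,
                       zeta = (2 * k - 1) * g;
          for (int a = 0; a < 8; ++a) {
            dNl[q][a][0] = 0.125 * XI[a][0] * (1 + XI[a][1] * eta) * (1 + XI[a][2] * zeta);
            dNl[q][a][1] = 0.125 * (1 + XI[a][0] * xi) * XI[a][1] * (1 + XI[a][2] * zeta);
            dNl[q][a][2] = 0.125 * (1 + XI[a][0] * xi) * (1 + XI[a][1] * eta) * XI[a][2];
          }
        }
  }
};
static const GaussBasis GB;

// Build reference data; returns false on non-positive reference Jacobian.
static bool elem_ref(const double Xe[8][3], ElemRef &er) {
  er.vol0 = 0;
  for (int q = 0; q < 8; ++q) {
    double Jx[9]; // column-major: Jx(i,j) = sum_a Xe[a][i] * dNl[q][a][j]
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) {
        double s = 0;
        for (int a = 0; a < 8; ++a) s += Xe[a][i] * GB.dNl[q][a][j];
        Jx[i + 3 * j] = s;
      }
    const double d = det3(Jx);
    if (d <= 0) return false;
    er.detJx[q] = d;
    er.vol0 += d;
    double Ji[9];
    inv3(Jx, Ji);
    for (int a = 0; a < 8; ++a)
      for (int j = 0; j < 3; ++j)
        er.dNdX[q][a][j] = GB.dNl[q][a][0] * Ji[0 + 3 * j] +
                           GB.dNl[q][a][1] * Ji[1 + 3 * j] +
                           GB.dNl[q][a][2] * Ji[2 + 3 * j];
  }
  return true;
}

// Element internal force with mean-dilatation volumetric pressure.
// Optionally writes per-gp stress (column-major rows) and current-volume
// weights. Returns false on element inversion.
static bool elem_residual(const ElemRef &er, const double ue[8][3],
                          const double fib[8][3], const double *pp,
                          double r[24], double (*gp_sig)[9], double *gp_w,
                          double *theta_out) {
  double F[8][9], Jg[8];
  double volc = 0;
  for (int q = 0; q < 8; ++q) {
    double *Fq = F[q];
    Fq[0] = Fq[4] = Fq[8] = 1.0;
    Fq[1] = Fq[2] = Fq[3] = Fq[5] = Fq[6] = Fq[7] = 0.0;
    for (int a = 0; a < 8; ++a) {
      const double *da = er.dNdX[q][a];
      for (int j = 0; j < 3; ++j) {
        Fq[0 + 3 * j] += ue[a][0] * da[j];
        Fq[1 + 3 * j] += ue[a][1] * da[j];
        Fq[2 + 3 * j] += ue[a][2] * da[j];
      }
    }
    Jg[q] = det3(Fq);
    if (Jg[q] <= 0) return false;
    volc += er.detJx[q] * Jg[q];
  }
  const double theta = volc / er.vol0;
  const double p = pp[6] * std::log(theta) / theta;
  if (theta_out) *theta_out = theta;
  for (int d = 0; d < 24; ++d) r[d] = 0;
  for (int q = 0; q < 8; ++q) {
    double sig[9];
    cauchy_iso_fast(F[q], Jg[q], fib[q], pp, sig);
    sig[0] += p; sig[4] += p; sig[8] += p;
    if (gp_sig) for (int c = 0; c < 9; ++c) gp_sig[q][c] = sig[c];
    if (gp_w) gp_w[q] = er.detJx[q] * Jg[q];
    double Fi[9];
    inv3(F[q], Fi);
    const double w = er.detJx[q] * Jg[q];
    for (int a = 0; a < 8; ++a) {
      // spatial gradient dN/dx = dN/dX * F^{-1}
      double g[3];
      const double *da = er.dNdX[q][a];
      for (int j = 0; j < 3; ++j)
        g[j] = da[0] * Fi[0 + 3 * j] + da[1] * Fi[1 + 3 * j] +
               da[2] * Fi[2 + 3 * j];
      for (int i = 0; i < 3; ++i)
        r[3 * a + i] += w * (sig[i + 0] * g[0] + sig[i + 3] * g[1] +
                             sig[i + 6] * g[2]);
    }
  }
  return true;
}

// Assemble global internal force, per-gp stress/von Mises/weights and
// (optionally) the tangent stiffness. conn is 1-based (from R); fib is
// (nelem*8) x 3 with gp index fastest within each element.
// [[Rcpp::export(name = ".tt_assemble")]]
Rcpp::List tt_assemble(Rcpp::NumericMatrix Xin, Rcpp::NumericMatrix Uin,
                       Rcpp::IntegerMatrix conn, Rcpp::NumericMatrix fibin,
                       Rcpp::NumericVector params, bool want_tangent,
                       bool want_stress) {
  const int nn = Xin.nrow(), ne = conn.nrow();
  const double *pp = params.begin();

  Rcpp::NumericVector R(3 * nn);
  Rcpp::NumericMatrix gps;
  Rcpp::NumericVector gvm, gw;
  if (want_stress) {
    gps = Rcpp::NumericMatrix(ne * 8, 9);
    gvm = Rcpp::NumericVector(ne * 8);
    gw = Rcpp::NumericVector(ne * 8);
  }
  Rcpp::NumericVector thetas(ne);

  std::vector<int> ti, tj;
  std::vector<double> tv;
  if (want_tangent) {
    ti.reserve((size_t)ne * 576);
    tj.reserve((size_t)ne * 576);
    tv.reserve((size_t)ne * 576);
  }

  const double h = 1e-6;
  double Xe[8][3], ue[8][3], fib[8][3];
  double r0[24], rp[24], rm[24];
  double gp_sig[8][9], gp_w[8];
  ElemRef er;

  for (int e = 0; e < ne; ++e) {
    int idx[8];
    for (int a = 0; a < 8; ++a) {
      const int n = conn(e, a) - 1;
      idx[a] = n;
      for (int i = 0; i < 3; ++i) {
        Xe[a][i] = Xin(n, i);
        ue[a][i] = Uin(n, i);
        fib[a][i] = fibin(8 * e + a, i);
      }
    }
    if (!elem_ref(Xe, er) ||
        !elem_residual(er, ue, fib, pp, r0, want_stress ? gp_sig : nullptr,
                       want_stress ? gp_w : nullptr, &thetas[e]))
      return Rcpp::List::create(Rcpp::Named("ok") = false,
                                Rcpp::Named("bad_element") = e + 1);
    if (want_stress) {
      for (int q = 0; q < 8; ++q) {
        for (int c = 0; c < 9; ++c) gps(8 * e + q, c) = gp_sig[q][c];
        gw[8 * e + q] = gp_w[q];
        const double *s = gp_sig[q];
        const double tr3 = (s[0] + s[4] + s[8]) / 3.0;
        double acc = 0;
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) {
            const double d = s[i + 3 * j] - (i == j ? tr3 : 0.0);
            acc += d * d;
          }
        gvm[8 * e + q] = std::sqrt(1.5 * acc);
      }
    }
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) R[3 * idx[a] + i] += r0[3 * a + i];

    if (want_tangent) {
      double Ke[24][24];
      for (int d = 0; d < 24; ++d) {
        const int a = d / 3, i = d % 3;
        const double keep = ue[a][i];
        ue[a][i] = keep + h;
        bool ok1 = elem_residual(er, ue, fib, pp, rp, nullptr, nullptr, nullptr);
        ue[a][i] = keep - h;
        bool ok2 = elem_residual(er, ue, fib, pp, rm, nullptr, nullptr, nullptr);
        ue[a][i] = keep;
        if (!ok1 || !ok2)
          return Rcpp::List::create(Rcpp::Named("ok") = false,
                                    Rcpp::Named("bad_element") = e + 1);
        for (int d1 = 0; d1 < 24; ++d1) Ke[d1][d] = (rp[d1] - rm[d1]) / (2 * h);
      }
      for (int d2 = 0; d2 < 24; ++d2)
        for (int d1 = 0; d1 < 24; ++d1) {
          ti.push_back(3 * idx[d1 / 3] + d1 % 3 + 1);
          tj.push_back(3 * idx[d2 / 3] + d2 % 3 + 1);
          tv.push_back(Ke[d1][d2]);
        }
    }
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("ok") = true, Rcpp::Named("resid") = R,
      Rcpp::Named("theta") = thetas);
  if (want_stress) {
    out["gp_stress"] = gps;
    out["gp_vm"] = gvm;
    out["gp_w"] = gw;
  }
  if (want_tangent) {
    out["ti"] = Rcpp::IntegerVector(ti.begin(), ti.end());
    out["tj"] = Rcpp::IntegerVector(tj.begin(), tj.end());
    out["tv"] = Rcpp::NumericVector(tv.begin(), tv.end());
  }
  return out;
}

// Reference-configuration element quality: minimum Jacobian determinant over
// the Gauss points of each element, and element volumes.
// [[Rcpp::export(name = ".tt_mesh_quality")]]
Rcpp::List tt_mesh_quality(Rcpp::NumericMatrix Xin, Rcpp::IntegerMatrix conn) {
  const int ne = conn.nrow();
  Rcpp::NumericVector minJ(ne), vol(ne);
  double Xe[8][3];
  for (int e = 0; e < ne; ++e) {
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) Xe[a][i] = Xin(conn(e, a) - 1, i);
    double mj = R_PosInf, v = 0;
    for (int q = 0; q < 8; ++q) {
      double Jx[9];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j) {
          double s = 0;
          for (int a = 0; a < 8; ++a) s += Xe[a][i] * GB.dNl[q][a][j];
          Jx[i + 3 * j] = s;
        }
      const double d = det3(Jx);
      if (d < mj) mj = d;
      v += d;
    }
    minJ[e] = mj;
    vol[e] = v;
  }
  return Rcpp::List::create(Rcpp::Named("min_jac") = minJ,
                            Rcpp::Named("volume") = vol);
}
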