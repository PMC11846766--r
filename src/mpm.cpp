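#include <Rcpp.h>
using namespace Rcpp;

// Quadratic B-spline basis on a regular grid, evaluated at r = (x - x_g)/h.
static inline double qbs(double r) {
  double a = std::fabs(r);
  if (a < 0.5) return 0.75 - a * a;
  if (a < 1.5) { double t = 1.5 - a; return 0.5 * t * t; }
  return 0.0;
}

// derivative w.r.t. r (caller divides by h for d/dx)
static inline double dqbs(double r) {
  double a = std::fabs(r);
  if (a < 0.5) return -2.0 * r;
  if (a < 1.5) { double t = 1.5 - a; return (r > 0.0) ? -t : t; }
  return 0.0;
}

struct Stencil {
  int idx[3];       // base node index per axis (first of up to 3)
  int n[3];         // number of support nodes per axis (1 for inactive axis)
  double w[3][3];   // weights per axis/node
  double dw[3][3];  // d/dx per axis/node
};

// Build the per-axis stencil for one point. Axes with a single node layer are
// inactive (weight 1, zero gradient): used by the 1-D column configurations.
static inline void stencil(const double *x, const double *origin, double h,
                           const int *dims, Stencil &S) {
  for (int a = 0; a < 3; ++a) {
    if (dims[a] == 1) {
      S.idx[a] = 0; S.n[a] = 1;
      S.w[a][0] = 1.0; S.dw[a][0] = 0.0;
      continue;
    }
    double s = (x[a] - origin[a]) / h;
    int i0 = (int)std::floor(s + 0.5) - 1;
    if (i0 < 0 || i0 + 2 >= dims[a])
      stop("point outside grid support (axis %d, coord %.3f)", a + 1, x[a]);
    S.idx[a] = i0; S.n[a] = 3;
    for (int m = 0; m < 3; ++m) {
      double r = s - (double)(i0 + m);
      S.w[a][m] = qbs(r);
      S.dw[a][m] = dqbs(r) / h;
    }
  }
}

static inline int nodeIndex(int i, int j, int k, const int *dims) {
  return i + dims[0] * (j + dims[1] * k);
}

// [[Rcpp::export]]
NumericVector cpp_field_interp(NumericMatrix X, NumericVector vals,
                               NumericVector origin, double h,
                               IntegerVector dims) {
  int N = X.nrow();
  int d[3] = {dims[0], dims[1], dims[2]};
  double o[3] = {origin[0], origin[1], origin[2]};
  NumericVector out(N);
  Stencil S;
  for (int p = 0; p < N; ++p) {
    double x[3] = {X(p, 0), X(p, 1), X(p, 2)};
    stencil(x, o, h, d, S);
    double acc = 0.0;
    for (int k = 0; k < S.n[2]; ++k)
      for (int j = 0; j < S.n[1]; ++j)
        for (int i = 0; i < S.n[0]; ++i) {
          double w = S.w[0][i] * S.w[1][j] * S.w[2][k];
          acc += w * vals[nodeIndex(S.idx[0] + i, S.idx[1] + j, S.idx[2] + k, d)];
        }
    out[p] = acc;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_field_grad(NumericMatrix X, NumericVector vals,
                             NumericVector origin, double h,
                             IntegerVector dims) {
  int N = X.nrow();
  int d[3] = {dims[0], dims[1], dims[2]};
  double o[3] = {origin[0], origin[1], origin[2]};
  NumericMatrix out(N, 3);
  Stencil S;
  for (int p = 0; p < N; ++p) {
    double x[3] = {X(p, 0), X(p, 1), X(p, 2)};
    stencil(x, o, h, d, S);
    double g[3] = {0.0, 0.0, 0.0};
    for (int k = 0; k < S.n[2]; ++k)
      for (int j = 0; j < S.n[1]; ++j)
        for (int i = 0; i < S.n[0]; ++i) {
          double v = vals[nodeIndex(S.idx[0] + i, S.idx[1] + j, S.idx[2] + k, d)];
          g[0] += v * S.dw[0][i] * S.w[1][j] * S.w[2][k];
          g[1] += v * S.w[0][i] * S.dw[1][j] * S.w[2][k];
          g[2] += v * S.w[0][i] * S.w[1][j] * S.dw[2][k];
        }
    for (int a = 0; a < 3; ++a) out(p, a) = g[a];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_scatter(NumericMatrix X, NumericVector amt,
                          NumericVector origin, double h, IntegerVector dims) {
  int N = X.nrow();
  int d[3] = {dims[0], dims[1], dims[2]};
  double o[3] = {origin[0], origin[1], origin[2]};
  NumericVector out(d[0] * d[1] * d[2]);
  Stencil S;
  for (int p = 0; p < N; ++p) {
    if (amt[p] == 0.0) continue;
    double x[3] = {X(p, 0), X(p, 1), X(p, 2)};
    stencil(x, o, h, d, S);
    for (int k = 0; k < S.n[2]; ++k)
      for (int j = 0; j < S.n[1]; ++j)
        for (int i = 0; i < S.n[0]; ++i) {
          double w = S.w[0][i] * S.w[1][j] * S.w[2][k];
          out[nodeIndex(S.idx[0] + i, S.idx[1] + j, S.idx[2] + k, d)] += w * amt[p];
        }
  }
  return out;
}

static inline double det3(const double *A) {
  return A[0] * (A[4] * A[8] - A[5] * A[7])
       - A[1] * (A[3] * A[8] - A[5] * A[6])
       + A[2] * (A[3] * A[7] - A[4] * A[6]);
}

static inline bool inv3(const double *A, double *Ainv) {
  double d = det3(A);
  if (std::fabs(d) < 1e-300) return false;
  double id = 1.0 / d;
  Ainv[0] =  (A[4] * A[8] - A[5] * A[7]) * id;
  Ainv[1] = -(A[1] * A[8] - A[2] * A[7]) * id;
  Ainv[2] =  (A[1] * A[5] - A[2] * A[4]) * id;
  Ainv[3] = -(A[3] * A[8] - A[5] * A[6]) * id;
  Ainv[4] =  (A[0] * A[8] - A[2] * A[6]) * id;
  Ainv[5] = -(A[0] * A[5] - A[2] * A[3]) * id;
  Ainv[6] =  (A[3] * A[7] - A[4] * A[6]) * id;
  Ainv[7] = -(A[0] * A[7] - A[1] * A[6]) * id;
  Ainv[8] =  (A[0] * A[4] - A[1] * A[3]) * id;
  return true;
}

// Total elastic energy  E = sum_p psi(F_trial, F^g) V0_p  and its gradient with
// respect to grid node displacements, with F_trial = (I + grad u) F_p and the
// growth-decomposed compressible neo-Hookean density
//   psi = J^g ( lambda/8 ln^2 I3 + mu/2 (I1 - 3 - ln I3) ).
// u is node-major: u[3*g + a]. An inverted trial state returns a large finite
// energy so line searches back off.
// [[Rcpp::export]]
List cpp_energy(NumericVector u, NumericMatrix X, NumericMatrix Fm,
                NumericMatrix Fgm, NumericVector V0, NumericVector lam,
                NumericVector mu, NumericVector origin, double h,
                IntegerVector dims, bool want_grad) {
  int N = X.nrow();
  int d[3] = {dims[0], dims[1], dims[2]};
  double o[3] = {origin[0], origin[1], origin[2]};
  int nn = d[0] * d[1] * d[2];
  NumericVector grad(want_grad ? 3 * nn : 0);
  double Etot = 0.0;
  bool bad = false;
  Stencil S;

  for (int p = 0; p < N && !bad; ++p) {
    double x[3] = {X(p, 0), X(p, 1), X(p, 2)};
    stencil(x, o, h, d, S);

    double gu[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0}; // grad u, row-major du_a/dx_b
    for (int k = 0; k < S.n[2]; ++k)
      for (int j = 0; j < S.n[1]; ++j)
        for (int i = 0; i < S.n[0]; ++i) {
          int g = nodeIndex(S.idx[0] + i, S.idx[1] + j, S.idx[2] + k, d);
          double dN[3] = {S.dw[0][i] * S.w[1][j] * S.w[2][k],
                          S.w[0][i] * S.dw[1][j] * S.w[2][k],
                          S.w[0][i] * S.w[1][j] * S.dw[2][k]};
          for (int a = 0; a < 3; ++a)
            for (int b = 0; b < 3; ++b)
              gu[3 * a + b] += u[3 * g + a] * dN[b];
        }

    double F[9], Fg[9], Ft[9], iFg[9], Fe[9];
    for (int m = 0; m < 9; ++m) { F[m] = Fm(p, m); Fg[m] = Fgm(p, m); }
    // F_trial = (I + gu) F
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double acc = F[3 * a + b];
        for (int c = 0; c < 3; ++c) acc += gu[3 * a + c] * F[3 * c + b];
        Ft[3 * a + b] = acc;
      }
    if (!inv3(Fg, iFg)) stop("singular growth tensor at point %d", p + 1);
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double acc = 0.0;
        for (int c = 0; c < 3; ++c) acc += Ft[3 * a + c] * iFg[3 * c + b];
        Fe[3 * a + b] = acc;
      }
    double Je = det3(Fe);
    if (Je <= 1e-8) { bad = true; break; }
    double Jg = det3(Fg);
    double I1 = 0.0;
    for (int m = 0; m < 9; ++m) I1 += Fe[m] * Fe[m];
    double lnI3 = 2.0 * std::log(Je);
    double psi = Jg * (0.125 * lam[p] * lnI3 * lnI3 +
                       0.5 * mu[p] * (I1 - 3.0 - lnI3));
    Etot += psi * V0[p];

    if (want_grad) {
      double iFe[9];
      inv3(Fe, iFe);
      // dpsi/dFe = Jg ( lam/2 lnI3 Fe^{-T} + mu (Fe - Fe^{-T}) )
      double dFe[9];
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          double feInvT = iFe[3 * b + a];
          dFe[3 * a + b] = Jg * (0.5 * lam[p] * lnI3 * feInvT +
                                 mu[p] * (Fe[3 * a + b] - feInvT));
        }
      // dpsi/dF_trial = dpsi/dFe * Fg^{-T};  dpsi/dgu = dpsi/dF_trial * F^T
      double dFt[9], dGu[9];
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          double acc = 0.0;
          for (int c = 0; c < 3; ++c) acc += dFe[3 * a + c] * iFg[3 * b + c];
          dFt[3 * a + b] = acc;
        }
      for (int a = 0; a < 3; ++a)
        for (int b = 0; b < 3; ++b) {
          double acc = 0.0;
          for (int c = 0; c < 3; ++c) acc += dFt[3 * a + c] * F[3 * b + c];
          dGu[3 * a + b] = acc;
        }
      for (int k = 0; k < S.n[2]; ++k)
        for (int j = 0; j < S.n[1]; ++j)
          for (int i = 0; i < S.n[0]; ++i) {
            int g = nodeIndex(S.idx[0] + i, S.idx[1] + j, S.idx[2] + k, d);
            double dN[3] = {S.dw[0][i] * S.w[1][j] * S.w[2][k],
                            S.w[0][i] * S.dw[1][j] * S.w[2][k],
                            S.w[0][i] * S.w[1][j] * S.dw[2][k]};
            for (int a = 0; a < 3; ++a)
              grad[3 * g + a] += V0[p] * (dGu[3 * a + 0] * dN[0] +
                                          dGu[3 * a + 1] * dN[1] +
                                          dGu[3 * a + 2] * dN[2]);
          }
    }
  }

  if (bad) {
    Etot = 1e30;
    if (want_grad) std::fill(grad.begin(), grad.end(), 0.0);
  }
  return List::create(_["E"] = Etot, _["grad"] = grad, _["inverted"] = bad);
}

// Advect points through a converged grid displacement field:
// x <- x + u(x),  F <- (I + grad u) F.
// [[Rcpp::export]]
List cpp_update_points(NumericVector u, NumericMatrix X, NumericMatrix Fm,
                       NumericVector origin, double h, IntegerVector dims) {
  int N = X.nrow();
  int d[3] = {dims[0], dims[1], dims[2]};
  double o[3] = {origin[0], origin[1], origin[2]};
  NumericMatrix X1(N, 3), F1(N, 9);
  NumericVector detF(N);
  Stencil S;
  for (int p = 0; p < N; ++p) {
    double x[3] = {X(p, 0), X(p, 1), X(p, 2)};
    stencil(x, o, h, d, S);
    double up[3] = {0, 0, 0};
    double gu[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
    for (int k = 0; k < S.n[2]; ++k)
      for (int j = 0; j < S.n[1]; ++j)
        for (int i = 0; i < S.n[0]; ++i) {
          int g = nodeIndex(S.idx[0] + i, S.idx[1] + j, S.idx[2] + k, d);
          double w = S.w[0][i] * S.w[1][j] * S.w[2][k];
          double dN[3] = {S.dw[0][i] * S.w[1][j] * S.w[2][k],
                          S.w[0][i] * S.dw[1][j] * S.w[2][k],
                          S.w[0][i] * S.w[1][j] * S.dw[2][k]};
          for (int a = 0; a < 3; ++a) {
            up[a] += w * u[3 * g + a];
            for (int b = 0; b < 3; ++b) gu[3 * a + b] += u[3 * g + a] * dN[b];
          }
        }
    double F[9], Fn[9];
    for (int m = 0; m < 9; ++m) F[m] = Fm(p, m);
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        double acc = F[3 * a + b];
        for (int c = 0; c < 3; ++c) acc += gu[3 * a + c] * F[3 * c + b];
        Fn[3 * a + b] = acc;
      }
    for (int a = 0; a < 3; ++a) X1(p, a) = x[a] + up[a];
    for (int m = 0; m < 9; ++m) F1(p, m) = Fn[m];
    detF[p] = det3(Fn);
  }
  return List::create(_["X"] = X1, _["F"] = F1, _["detF"] = detF);
}
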