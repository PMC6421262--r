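#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Signed solid angle of triangle (a,b,c) seen from p, van Oosterom-Strackee:
// Omega = 2 * atan2(det[r1 r2 r3], r1r2r3 + (r1.r2)r3 + (r1.r3)r2 + (r2.r3)r1)
// Positive for a triangle whose outward normal faces away from p when the
// surface is wound consistently outward and p is interior (total 4*pi).
static inline double tri_solid_angle(const double* a, const double* b,
                                     const double* c, const double* p) {
  double r1[3], r2[3], r3[3];
  for (int k = 0; k < 3; ++k) {
    r1[k] = a[k] - p[k];
    r2[k] = b[k] - p[k];
    r3[k] = c[k] - p[k];
  }
  double n1 = std::sqrt(r1[0]*r1[0] + r1[1]*r1[1] + r1[2]*r1[2]);
  double n2 = std::sqrt(r2[0]*r2[0] + r2[1]*r2[1] + r2[2]*r2[2]);
  double n3 = std::sqrt(r3[0]*r3[0] + r3[1]*r3[1] + r3[2]*r3[2]);
  double det = r1[0]*(r2[1]*r3[2] - r2[2]*r3[1])
             - r1[1]*(r2[0]*r3[2] - r2[2]*r3[0])
             + r1[2]*(r2[0]*r3[1] - r2[1]*r3[0]);
  double d12 = r1[0]*r2[0] + r1[1]*r2[1] + r1[2]*r2[2];
  double d13 = r1[0]*r3[0] + r1[1]*r3[1] + r1[2]*r3[2];
  double d23 = r2[0]*r3[0] + r2[1]*r3[1] + r2[2]*r3[2];
  double den = n1*n2*n3 + d12*n3 + d13*n2 + d23*n1;
  return 2.0 * std::atan2(det, den);
}

// Lumped per-vertex solid angles of a closed triangulated surface at a set
// of observation points. Returns omega (npoints x nverts, each triangle's
// angle split equally over its three vertices) and the per-point total.
// [[Rcpp::export]]
List solid_angle_lumped_cpp(NumericMatrix V, IntegerMatrix F, NumericMatrix P) {
  int np = P.nrow(), nv = V.nrow(), nf = F.nrow();
  NumericMatrix omega(np, nv);
  NumericVector total(np);
  std::vector<double> pt(3);
  for (int p = 0; p < np; ++p) {
    double pp[3] = { P(p,0), P(p,1), P(p,2) };
    for (int t = 0; t < nf; ++t) {
      int i1 = F(t,0) - 1, i2 = F(t,1) - 1, i3 = F(t,2) - 1;
      double a[3] = { V(i1,0), V(i1,1), V(i1,2) };
      double b[3] = { V(i2,0), V(i2,1), V(i2,2) };
      double c[3] = { V(i3,0), V(i3,1), V(i3,2) };
      double om = tri_solid_angle(a, b, c, pp);
      total[p] += om;
      double o3 = om / 3.0;
      omega(p, i1) += o3;
      omega(p, i2) += o3;
      omega(p, i3) += o3;
    }
  }
  return List::create(_["omega"] = omega, _["total"] = total);
}

// Lumped solid angles of a surface at its own vertices, skipping triangles
// incident to the observation vertex (their principal-value contribution at
// an in-plane point is zero); used for BEM collocation. The auto (diagonal)
// term is set afterwards in R from the 2*pi row-sum identity.
// [[Rcpp::export]]
NumericMatrix solid_angle_self_cpp(NumericMatrix V, IntegerMatrix F) {
  int nv = V.nrow(), nf = F.nrow();
  NumericMatrix omega(nv, nv);
  for (int p = 0; p < nv; ++p) {
    double pp[3] = { V(p,0), V(p,1), V(p,2) };
    for (int t = 0; t < nf; ++t) {
      int i1 = F(t,0) - 1, i2 = F(t,1) - 1, i3 = F(t,2) - 1;
      if (i1 == p || i2 == p || i3 == p) continue;
      double a[3] = { V(i1,0), V(i1,1), V(i1,2) };
      double b[3] = { V(i2,0), V(i2,1), V(i2,2) };
      double c[3] = { V(i3,0), V(i3,1), V(i3,2) };
      double om = tri_solid_angle(a, b, c, pp);
      double o3 = om / 3.0;
      omega(p, i1) += o3;
      omega(p, i2) += o3;
      omega(p, i3) += o3;
    }
  }
  return omega;
}

// Euclidean local-cost matrix between the time columns of two multichannel
// sequences X, Y (channels x samples): C[n, m] = ||X[, n] - Y[, m]||_2.
// [[Rcpp::export]]
NumericMatrix dtw_cost_matrix_cpp(NumericMatrix X, NumericMatrix Y) {
  int P = X.nrow(), Tn = X.ncol(), Tm = Y.ncol();
  NumericMatrix C(Tn, Tm);
  for (int m = 0; m < Tm; ++m) {
    for (int n = 0; n < Tn; ++n) {
      double s = 0.0;
      for (int p = 0; p < P; ++p) {
        double d = X(p, n) - Y(p, m);
        s += d * d;
      }
      C(n, m) = std::sqrt(s);
    }
  }
  return C;
}

// Accumulated-cost matrix with sentinel row/column:
// D(0,0) = 0, D(0, m>0) = D(n>0, 0) = Inf,
// D(n,m) = min{D(n-1,m-1), D(n-1,m), D(n,m-1)} + C(n,m).
// [[Rcpp::export]]
NumericMatrix dtw_accumulate_cpp(NumericMatrix C) {
  int Tn = C.nrow(), Tm = C.ncol();
  NumericMatrix D(Tn + 1, Tm + 1);
  std::fill(D.begin(), D.end(), R_PosInf);
  D(0, 0) = 0.0;
  for (int n = 1; n <= Tn; ++n) {
    for (int m = 1; m <= Tm; ++m) {
      double best = std::min(D(n - 1, m - 1), std::min(D(n - 1, m), D(n, m - 1)));
      D(n, m) = best + C(n - 1, m - 1);
    }
  }
  return D;
}

// Optimal total cost only, with a rolling pair of rows (used in the
// per-node inverse search where the path itself is not needed).
// [[Rcpp::export]]
double dtw_total_cost_cpp(NumericMatrix C) {
  int Tn = C.nrow(), Tm = C.ncol();
  std::vector<double> prev(Tm + 1, R_PosInf), cur(Tm + 1, R_PosInf);
  prev[0] = 0.0;
  for (int n = 1; n <= Tn; ++n) {
    cur[0] = R_PosInf;
    for (int m = 1; m <= Tm; ++m) {
      double best = std::min(prev[m - 1], std::min(prev[m], cur[m - 1]));
      cur[m] = best + C(n - 1, m - 1);
    }
    std::swap(prev, cur);
  }
  return prev[Tm];
}

// Cumulative sums along columns (column j gets column j-1 added), used to
// assemble Heaviside-source BSPMs from activation-ordered lead fields.
// [[Rcpp::export]]
NumericMatrix cumsum_columns_cpp(NumericMatrix M) {
  NumericMatrix out = clone(M);
  int nr = out.nrow(), nc = out.ncol();
  for (int j = 1; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) += out(i, j - 1);
  return out;
}
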