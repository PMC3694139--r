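#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// SOR solve of the nodal mass-conservation system of a vessel network.
//
// Node c (interior): sum_s g_s (P_k - P_c) - 0.5 * sum_s lambda_s *
//   ((P_c + P_k)/2 - Pe_s) = 0
// where s runs over segments incident to c, k is the far endpoint,
// g is the Poiseuille conductance, lambda = Lp * pi * D * L the wall
// conductance and Pe the effective external (interstitial + oncotic)
// pressure of the segment. Dirichlet nodes keep their imposed pressure.
//
// Adjacency is passed in CSR form: for node i, entries ptr[i]..ptr[i+1]-1
// of `nbr` (0-based far node) and `seg` (0-based segment index).
// [[Rcpp::export]]
List sor_network_cpp(IntegerVector ptr, IntegerVector nbr, IntegerVector seg,
                     NumericVector g, NumericVector lambda, NumericVector Pe,
                     NumericVector P0, LogicalVector dirichlet,
                     double omega, double tol, int max_sweeps) {
  int n = P0.size();
  NumericVector P = clone(P0);
  double delta = 0.0;
  int sweep = 0;
  for (sweep = 1; sweep <= max_sweeps; ++sweep) {
    delta = 0.0;
    double pmax = 1e-300;
    for (int i = 0; i < n; ++i) {
      if (dirichlet[i]) continue;
      double num = 0.0, den = 0.0;
      for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
        int k = nbr[e], s = seg[e];
        num += (g[s] - 0.25 * lambda[s]) * P[k] + 0.5 * lambda[s] * Pe[s];
        den += g[s] + 0.25 * lambda[s];
      }
      if (den <= 0.0) continue;  // isolated node: leave untouched
      double pnew = (1.0 - omega) * P[i] + omega * num / den;
      double d = std::fabs(pnew - P[i]);
      if (d > delta) delta = d;
      P[i] = pnew;
      double ap = std::fabs(pnew);
      if (ap > pmax) pmax = ap;
    }
    for (int i = 0; i < n; ++i) {
      double ap = std::fabs(P[i]);
      if (ap > pmax) pmax = ap;
    }
    if (delta / pmax < tol) break;
  }
  // nodal residuals at the solution
  NumericVector res(n);
  for (int i = 0; i < n; ++i) {
    double r = 0.0;
    for (int e = ptr[i]; e < ptr[i + 1]; ++e) {
      int k = nbr[e], s = seg[e];
      r += g[s] * (P[k] - P[i]) -
           0.5 * lambda[s] * (0.5 * (P[i] + P[k]) - Pe[s]);
    }
    res[i] = r;
  }
  return List::create(_["P"] = P, _["sweeps"] = sweep,
                      _["delta"] = delta, _["residual"] = res);
}

// SOR solve of the 5-point finite-difference Darcy equation with a
// linearized Starling source:
//   sum_faces T (P_nb - P) + alpha * (Pe - P) = 0
// Face transmissibilities Tx (nx+1 by ny) and Ty (nx by ny+1) carry the
// harmonically averaged K/h^2; boundary faces have T = 0 for no-flux or
// the Dirichlet half-cell transmissibility with the boundary value in
// Pbnd. alpha = A * Lp * S/V (1/(Pa s)) and Pe the effective source
// pressure, both per cell. Column-major cell index i + nx*j.
// [[Rcpp::export]]
List sor_grid_cpp(int nx, int ny, NumericVector Tx, NumericVector Ty,
                  NumericVector TxBnd, NumericVector PxBnd,
                  NumericVector alpha, NumericVector Pe,
                  NumericVector P0, double omega, double tol,
                  int max_sweeps) {
  NumericVector P = clone(P0);
  const double *tx = Tx.begin(), *ty = Ty.begin(), *al = alpha.begin(),
               *pe = Pe.begin(), *txb = TxBnd.begin(), *pxb = PxBnd.begin();
  double *p = P.begin();
  // precompute the constant diagonal and source parts per cell
  std::vector<double> den(nx * ny), src(nx * ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int c = i + nx * j;
      double d = al[c];
      double s = al[c] * pe[c];
      if (i > 0) d += tx[i + (nx + 1) * j];
      else { d += txb[j]; s += txb[j] * pxb[j]; }
      if (i < nx - 1) d += tx[(i + 1) + (nx + 1) * j];
      if (j > 0) d += ty[i + nx * j];
      if (j < ny - 1) d += ty[i + nx * (j + 1)];
      den[c] = d;
      src[c] = s;
    }
  }
  double delta = 0.0;
  int sweep = 0;
  for (sweep = 1; sweep <= max_sweeps; ++sweep) {
    delta = 0.0;
    double pmax = 1e-300;
    for (int j = 0; j < ny; ++j) {
      const double *txr = tx + (nx + 1) * j;
      const double *tys = ty + nx * j, *tyn = ty + nx * (j + 1);
      double *pr = p + nx * j;
      for (int i = 0; i < nx; ++i) {
        double num = src[i + nx * j];
        if (i > 0) num += txr[i] * pr[i - 1];
        if (i < nx - 1) num += txr[i + 1] * pr[i + 1];
        if (j > 0) num += tys[i] * pr[i - nx];
        if (j < ny - 1) num += tyn[i] * pr[i + nx];
        double dn = den[i + nx * j];
        if (dn <= 0.0) continue;
        double pnew = (1.0 - omega) * pr[i] + omega * num / dn;
        double d = std::fabs(pnew - pr[i]);
        if (d > delta) delta = d;
        pr[i] = pnew;
        double ap = std::fabs(pnew);
        if (ap > pmax) pmax = ap;
      }
    }
    if (delta / pmax < tol) break;
  }
  return List::create(_["P"] = P, _["sweeps"] = sweep, _["delta"] = delta);
}
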