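#include <Rcpp.h>
#include <map>
#include <vector>
using namespace Rcpp;

// SCAD penalty p(beta; a, lambda), piecewise in |beta|.
static double scad_pen(double b, double a, double lam) {
  b = std::fabs(b);
  if (b <= lam) return lam * b;
  if (b <= a * lam) return (2.0 * a * lam * b - b * b - lam * lam) / (2.0 * (a - 1.0));
  return lam * lam * (a + 1.0) / 2.0;
}

// Minimize h(b) = (v/2) b^2 - z b + p(b; a, lam) exactly.
// Valid for any a > 1 and v > 0 (column norms need not be 1): the minimizer is
// either 0, a stationary point of one of the three penalty branches, or a
// branch boundary, all of which are evaluated.
static double scad_min1d(double z, double v, double a, double lam) {
  if (lam <= 0.0) return z / v;
  const double s = (z >= 0.0) ? 1.0 : -1.0;
  const double az = std::fabs(z);
  double cand[6];
  int nc = 0;
  cand[nc++] = 0.0;
  // branch 1: |b| <= lam, stationary at soft(z, lam)/v; sub-epsilon
  // remainders (|z| equal to lam up to rounding) snap to zero
  double t1 = az - lam;
  if (t1 <= 1e-12 * (1.0 + lam)) t1 = 0.0;
  double b1 = s * t1 / v;
  if (std::fabs(b1) <= lam) cand[nc++] = b1;
  // branch 2: lam < |b| <= a*lam
  double den = v - 1.0 / (a - 1.0);
  if (den > 1e-12) {
    double b2 = (z - s * a * lam / (a - 1.0)) / den;
    if (b2 * s > lam && b2 * s <= a * lam) cand[nc++] = b2;
  }
  // branch 3: |b| > a*lam, unpenalized slope
  double b3 = z / v;
  if (std::fabs(b3) > a * lam) cand[nc++] = b3;
  // branch boundaries (cover concave branch-2 cases, e.g. a close to 2)
  cand[nc++] = s * lam;
  cand[nc++] = s * a * lam;

  double best = 0.0, bestval = R_PosInf;
  for (int i = 0; i < nc; ++i) {
    double b = cand[i];
    double val = 0.5 * v * b * b - z * b + scad_pen(b, a, lam);
    if (val < bestval) { bestval = val; best = b; }
  }
  return best;
}

// One coordinate-descent solve at fixed (a, lam). beta and g are modified in
// place; g tracks Xty - XtX * beta. Returns number of sweeps used (negative if
// not converged).
static double cd_sweep(const NumericMatrix& XtX, std::vector<double>& g,
                       std::vector<double>& beta, int n, double a, double lam,
                       const std::vector<int>& idx) {
  const int p = XtX.nrow();
  double maxdiff = 0.0;
  for (size_t m = 0; m < idx.size(); ++m) {
    int j = idx[m];
    double v = XtX(j, j) / n;
    if (v <= 0.0) continue;
    double z = (g[j] + XtX(j, j) * beta[j]) / n;
    double bn = scad_min1d(z, v, a, lam);
    double d = bn - beta[j];
    if (std::fabs(d) > 0.0) {
      beta[j] = bn;
      const double* col = &XtX(0, j);
      for (int k = 0; k < p; ++k) g[k] -= col[k] * d;
      if (std::fabs(d) > maxdiff) maxdiff = std::fabs(d);
    }
  }
  return maxdiff;
}

// Full sweeps establish the active set; inner sweeps iterate it to
// convergence; termination requires a full sweep to move < tol.
static int cd_solve(const NumericMatrix& XtX, std::vector<double>& g,
                    std::vector<double>& beta, int n, double a, double lam,
                    double tol, int maxit) {
  const int p = XtX.nrow();
  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;
  int it = 0;
  while (it < maxit) {
    double maxdiff = cd_sweep(XtX, g, beta, n, a, lam, all);
    ++it;
    if (maxdiff < tol) return it;
    std::vector<int> active;
    for (int j = 0; j < p; ++j) if (beta[j] != 0.0) active.push_back(j);
    while (it < maxit) {
      double md = cd_sweep(XtX, g, beta, n, a, lam, active);
      ++it;
      if (md < tol) break;
    }
  }
  return -maxit;
}

// [[Rcpp::export]]
List scad_fit_cpp(NumericMatrix XtX, NumericVector Xty, int n, double a,
                  double lam, double tol, int maxit, NumericVector beta0) {
  const int p = XtX.nrow();
  std::vector<double> beta(p), g(p);
  for (int j = 0; j < p; ++j) beta[j] = beta0[j];
  for (int k = 0; k < p; ++k) {
    double acc = Xty[k];
    for (int j = 0; j < p; ++j) acc -= XtX(k, j) * beta[j];
    g[k] = acc;
  }
  int it = cd_solve(XtX, g, beta, n, a, lam, tol, maxit);
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["converged"] = (it > 0),
                      _["iterations"] = std::abs(it));
}

// Full (a, lambda) path. lamvals must be in decreasing order; the solution is
// warm-started along each a-row and reset at the start of each row. Supports
// are deduplicated across the whole grid; support_id maps grid point
// (row-major in a, then lambda) to an entry of supports (1-based indices).
// [[Rcpp::export]]
List scad_path_cpp(NumericMatrix XtX, NumericVector Xty, int n,
                   NumericVector avals, NumericVector lamvals, double tol,
                   int maxit, bool keep_beta) {
  const int p = XtX.nrow();
  const int na = avals.size(), nl = lamvals.size();
  const int G = na * nl;
  IntegerVector support_id(G);
  LogicalVector conv(G);
  NumericMatrix betas;
  if (keep_beta) betas = NumericMatrix(p, G);

  std::map<std::vector<int>, int> seen;
  std::vector<std::vector<int> > supp_list;

  std::vector<double> beta(p), g(p);
  for (int ai = 0; ai < na; ++ai) {
    double a = avals[ai];
    std::fill(beta.begin(), beta.end(), 0.0);
    for (int k = 0; k < p; ++k) g[k] = Xty[k];
    for (int li = 0; li < nl; ++li) {
      int gi = ai * nl + li;
      int it = cd_solve(XtX, g, beta, n, a, lamvals[li], tol, maxit);
      conv[gi] = (it > 0);
      std::vector<int> s;
      for (int j = 0; j < p; ++j) if (beta[j] != 0.0) s.push_back(j + 1);
      std::map<std::vector<int>, int>::iterator f = seen.find(s);
      int id;
      if (f == seen.end()) {
        id = (int)supp_list.size() + 1;
        seen.insert(std::make_pair(s, id));
        supp_list.push_back(s);
      } else id = f->second;
      support_id[gi] = id;
      if (keep_beta) for (int j = 0; j < p; ++j) betas(j, gi) = beta[j];
    }
  }
  List supports(supp_list.size());
  for (size_t i = 0; i < supp_list.size(); ++i)
    supports[i] = IntegerVector(supp_list[i].begin(), supp_list[i].end());
  List out = List::create(_["support_id"] = support_id,
                          _["supports"] = supports, _["converged"] = conv);
  if (keep_beta) out["beta"] = betas;
  return out;
}
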