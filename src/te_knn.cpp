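#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Kraskov/Frenzel-Pompe conditional mutual information I(xf ; yp | xp) in
// nats: the four-entropy transfer-entropy combination with the Kraskov
// k-nearest-neighbour entropy estimator, whose bias terms cancel into the
// digamma form. Rows are embedded points (possibly pooled across trials);
// `trial` and `tindex` drive the Theiler exclusion window, applied to the
// neighbour search and to the marginal counts alike.
// [[Rcpp::export]]
double cpp_ksg_cmi(NumericMatrix xf, NumericMatrix xp, NumericMatrix yp,
                   int k, int theiler, IntegerVector trial, IntegerVector tindex) {
  const int n = xf.nrow();
  if (xp.nrow() != n || yp.nrow() != n)
    stop("embedded blocks must have the same number of points");
  if (k < 1) stop("k must be >= 1");
  const int df = xf.ncol(), dx = xp.ncol(), dy = yp.ncol();

  // point-major flat copies for contiguous access in the inner loops
  std::vector<double> F((size_t)n * df), X((size_t)n * dx), Y((size_t)n * dy);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < df; ++c) F[(size_t)i * df + c] = xf(i, c);
    for (int c = 0; c < dx; ++c) X[(size_t)i * dx + c] = xp(i, c);
    for (int c = 0; c < dy; ++c) Y[(size_t)i * dy + c] = yp(i, c);
  }
  const int *tr = INTEGER(trial), *ti = INTEGER(tindex);

  std::vector<double> best(k);
  double acc = 0.0;
  int used = 0;

  for (int i = 0; i < n; ++i) {
    const double *fi = &F[(size_t)i * df], *xi = &X[(size_t)i * dx],
                 *yi = &Y[(size_t)i * dy];
    // k smallest joint max-norm distances among admissible points
    int found = 0;
    double worst = R_PosInf;
    for (int j = 0; j < n; ++j) {
      if (j == i || (tr[i] == tr[j] && std::abs(ti[i] - ti[j]) <= theiler))
        continue;
      const double *fj = &F[(size_t)j * df], *xj = &X[(size_t)j * dx],
                   *yj = &Y[(size_t)j * dy];
      double d = 0.0;
      for (int c = 0; c < df; ++c) {
        double v = std::fabs(fi[c] - fj[c]); if (v > d) d = v;
      }
      if (d >= worst) continue;
      for (int c = 0; c < dx; ++c) {
        double v = std::fabs(xi[c] - xj[c]); if (v > d) d = v;
      }
      if (d >= worst) continue;
      for (int c = 0; c < dy; ++c) {
        double v = std::fabs(yi[c] - yj[c]); if (v > d) d = v;
      }
      if (d >= worst) continue;
      int pos = (found < k) ? found : k - 1;
      while (pos > 0 && best[pos - 1] > d) { best[pos] = best[pos - 1]; --pos; }
      best[pos] = d;
      if (found < k) ++found;
      if (found == k) worst = best[k - 1];
    }
    if (found < k) continue;  // too few admissible neighbours for this point
    const double eps = best[k - 1];
    if (!(eps > 0)) continue; // degenerate duplicate points

    int n_xz = 0, n_yz = 0, n_z = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i || (tr[i] == tr[j] && std::abs(ti[i] - ti[j]) <= theiler))
        continue;
      const double *xj = &X[(size_t)j * dx];
      double dz = 0.0;
      for (int c = 0; c < dx; ++c) {
        double v = std::fabs(xi[c] - xj[c]);
        if (v > dz) { dz = v; if (dz >= eps) break; }
      }
      if (dz >= eps) continue;
      ++n_z;
      const double *fj = &F[(size_t)j * df];
      double dxz = dz;
      for (int c = 0; c < df; ++c) {
        double v = std::fabs(fi[c] - fj[c]);
        if (v > dxz) { dxz = v; if (dxz >= eps) break; }
      }
      if (dxz < eps) ++n_xz;
      const double *yj = &Y[(size_t)j * dy];
      double dyz = dz;
      for (int c = 0; c < dy; ++c) {
        double v = std::fabs(yi[c] - yj[c]);
        if (v > dyz) { dyz = v; if (dyz >= eps) break; }
      }
      if (dyz < eps) ++n_yz;
    }
    acc += R::digamma((double)n_z + 1.0) - R::digamma((double)n_xz + 1.0) -
           R::digamma((double)n_yz + 1.0);
    ++used;
  }
  if (used == 0) stop("no point had enough admissible neighbours; series too short");
  return R::digamma((double)k) + acc / (double)used;
}

// Cao's E1/E2 statistics for embedding-dimension selection.
// Returns a (dmax+1) x 2 matrix of E(d) and E*(d) for d = 1..dmax+1 so the
// caller can form E1(d) = E(d+1)/E(d) and E2(d) = E*(d+1)/E*(d).
// [[Rcpp::export]]
NumericMatrix cpp_cao(NumericVector x, int tau, int dmax) {
  const int n = x.size();
  NumericMatrix out(dmax + 1, 2);
  for (int d = 1; d <= dmax + 1; ++d) {
    // points with a (d+1)-dimensional vector: indices t = d*tau .. n-1 (0-based)
    const int first = d * tau;
    const int m = n - first;
    if (m < 10) stop("series too short for the requested embedding dimension");
    double Esum = 0.0, Estar = 0.0;
    int cnt = 0, cnt2 = 0;
    for (int a = 0; a < m; ++a) {
      const int ia = first + a;
      // nearest neighbour in d dimensions under max-norm
      double bestd = R_PosInf;
      int bj = -1;
      for (int b = 0; b < m; ++b) {
        if (b == a) continue;
        const int ib = first + b;
        double dd = 0.0;
        for (int c = 0; c < d; ++c) {
          double v = std::fabs(x[ia - c * tau] - x[ib - c * tau]);
          if (v > dd) { dd = v; if (dd >= bestd) break; }
        }
        if (dd < bestd) { bestd = dd; bj = ib; }
      }
      if (bj < 0 || !(bestd > 0)) continue;
      double dd1 = 0.0;
      for (int c = 0; c <= d; ++c) {
        double v = std::fabs(x[ia - c * tau] - x[bj - c * tau]);
        if (v > dd1) dd1 = v;
      }
      Esum += dd1 / bestd;
      ++cnt;
      Estar += std::fabs(x[ia - d * tau] - x[bj - d * tau]);
      ++cnt2;
    }
    out(d - 1, 0) = cnt > 0 ? Esum / cnt : NA_REAL;
    out(d - 1, 1) = cnt2 > 0 ? Estar / cnt2 : NA_REAL;
  }
  return out;
}
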