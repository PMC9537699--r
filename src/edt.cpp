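#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Exact squared Euclidean distance transform of one grid line
// (lower envelope of parabolas), in physical coordinates so anisotropic
// voxel spacing is honoured exactly. Sites with f = +Inf carry no parabola.
static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& z,
                  int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = -1;
  double s = 0.0;
  for (int q = 0; q < n; q++) {
    if (f[q] == INF) continue;
    double xq = q * w;
    while (k >= 0) {
      int p = v[k];
      double xp = p * w;
      s = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k]) k--; else break;
    }
    k++;
    v[k] = q;
    z[k] = (k == 0) ? -INF : s;
    z[k + 1] = INF;
  }
  if (k == -1) {
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * w;
    while (z[k + 1] < xq) k++;
    double dx = xq - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_squared_cpp")]]
NumericVector edt_squared_cpp(LogicalVector mask, IntegerVector dims,
                              NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; i++) out[i] = mask[i] ? 0.0 : INF;

  int nmax = std::max(n1, std::max(n2, n3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (fastest-varying)
  for (int i3 = 0; i3 < n3; i3++)
    for (int i2 = 0; i2 < n2; i2++) {
      R_xlen_t base = (R_xlen_t)n1 * (i2 + (R_xlen_t)n2 * i3);
      for (int i1 = 0; i1 < n1; i1++) f[i1] = out[base + i1];
      edt1d(f, d, v, z, n1, spacing[0]);
      for (int i1 = 0; i1 < n1; i1++) out[base + i1] = d[i1];
    }
  // axis 2
  for (int i3 = 0; i3 < n3; i3++)
    for (int i1 = 0; i1 < n1; i1++) {
      R_xlen_t base = i1 + (R_xlen_t)n1 * n2 * i3;
      for (int i2 = 0; i2 < n2; i2++) f[i2] = out[base + (R_xlen_t)n1 * i2];
      edt1d(f, d, v, z, n2, spacing[1]);
      for (int i2 = 0; i2 < n2; i2++) out[base + (R_xlen_t)n1 * i2] = d[i2];
    }
  // axis 3
  if (n3 > 1) {
    R_xlen_t stride = (R_xlen_t)n1 * n2;
    for (int i2 = 0; i2 < n2; i2++)
      for (int i1 = 0; i1 < n1; i1++) {
        R_xlen_t base = i1 + (R_xlen_t)n1 * i2;
        for (int i3 = 0; i3 < n3; i3++) f[i3] = out[base + stride * i3];
        edt1d(f, d, v, z, n3, spacing[2]);
        for (int i3 = 0; i3 < n3; i3++) out[base + stride * i3] = d[i3];
      }
  }
  return out;
}

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  R_xlen_t ntot = (R_xlen_t)n1 * n2 * n3;
  IntegerVector lab(ntot, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  R_xlen_t s12 = (R_xlen_t)n1 * n2;
  for (R_xlen_t seed = 0; seed < ntot; seed++) {
    if (!mask[seed] || lab[seed] != 0) continue;
    cur++;
    stack.clear();
    stack.push_back(seed);
    lab[seed] = cur;
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int i3 = (int)(p / s12);
      R_xlen_t r = p - (R_xlen_t)i3 * s12;
      int i2 = (int)(r / n1);
      int i1 = (int)(r - (R_xlen_t)i2 * n1);
      // 6-connected neighbours
      if (i1 > 0      && mask[p - 1]   && !lab[p - 1])   { lab[p - 1] = cur;   stack.push_back(p - 1); }
      if (i1 < n1 - 1 && mask[p + 1]   && !lab[p + 1])   { lab[p + 1] = cur;   stack.push_back(p + 1); }
      if (i2 > 0      && mask[p - n1]  && !lab[p - n1])  { lab[p - n1] = cur;  stack.push_back(p - n1); }
      if (i2 < n2 - 1 && mask[p + n1]  && !lab[p + n1])  { lab[p + n1] = cur;  stack.push_back(p + n1); }
      if (i3 > 0      && mask[p - s12] && !lab[p - s12]) { lab[p - s12] = cur; stack.push_back(p - s12); }
      if (i3 < n3 - 1 && mask[p + s12] && !lab[p + s12]) { lab[p + s12] = cur; stack.push_back(p + s12); }
    }
  }
  return lab;
}
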