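#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared-distance transform (lower envelope of parabolas), after
// Felzenszwalb & Huttenlocher, generalised to physical sample pitch `w`
// and to +Inf entries (no site on that sample). f: input squared
// distances sampled at positions 0, w, 2w, ...; d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  int q0 = 0;
  while (q0 < n && f[q0] == INF) q0++;
  if (q0 == n) {                       // no finite site at all
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = +INF;
  for (int q = q0 + 1; q < n; q++) {
    if (f[q] == INF) continue;
    double qq = q * w;
    double s;
    for (;;) {
      double pp = v[k] * w;
      s = ((f[q] + qq * qq) - (f[v[k]] + pp * pp)) / (2.0 * (qq - pp));
      if (s > z[k]) break;
      k--;                              // z[0] = -Inf guarantees k >= 0
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = +INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double qq = q * w;
    while (z[k + 1] < qq) k++;
    double pp = v[k] * w;
    d[q] = (qq - pp) * (qq - pp) + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel centre to the nearest
// set voxel centre of `mask`, with per-axis physical spacing in mm. `dim`
// follows the R array layout (dim[0] has the fastest stride). An empty
// mask yields Inf everywhere.
// [[Rcpp::export]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim,
                     NumericVector spacing) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  NumericVector out(mask.size());
  for (R_xlen_t i = 0; i < mask.size(); i++)
    out[i] = (mask[i] == TRUE) ? 0.0 : INF;

  std::vector<double> f, d;

  f.assign(n1, 0.0); d.assign(n1, 0.0);
  for (int k = 0; k < n3; k++)
    for (int j = 0; j < n2; j++) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + (R_xlen_t)j * n1;
      for (int i = 0; i < n1; i++) f[i] = out[base + i];
      dt1d(f, d, n1, spacing[0]);
      for (int i = 0; i < n1; i++) out[base + i] = d[i];
    }

  f.assign(n2, 0.0); d.assign(n2, 0.0);
  for (int k = 0; k < n3; k++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = (R_xlen_t)k * n1 * n2 + i;
      for (int j = 0; j < n2; j++) f[j] = out[base + (R_xlen_t)j * n1];
      dt1d(f, d, n2, spacing[1]);
      for (int j = 0; j < n2; j++) out[base + (R_xlen_t)j * n1] = d[j];
    }

  const R_xlen_t plane = (R_xlen_t)n1 * n2;
  f.assign(n3, 0.0); d.assign(n3, 0.0);
  for (int j = 0; j < n2; j++)
    for (int i = 0; i < n1; i++) {
      R_xlen_t base = (R_xlen_t)j * n1 + i;
      for (int k = 0; k < n3; k++) f[k] = out[base + (R_xlen_t)k * plane];
      dt1d(f, d, n3, spacing[2]);
      for (int k = 0; k < n3; k++) out[base + (R_xlen_t)k * plane] = d[k];
    }

  out.attr("dim") = dim;
  return out;
}
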