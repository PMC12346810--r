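#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// bins: length d1*d2*d3 vector in R array (column-major) order; 0 = outside
// the ROI, 1..ngray inside. offsets: ndir x 3 integer matrix of voxel steps.

static inline bool inside(int x, int y, int z, const int* d) {
  return x >= 0 && x < d[0] && y >= 0 && y < d[1] && z >= 0 && z < d[2];
}

// Symmetric co-occurrence counts for every direction: returns an
// ngray x ngray x ndir array; each ordered in-ROI pair contributes to both
// (a,b) and (b,a).
// [[Rcpp::export]]
NumericVector cpp_glcm_counts(IntegerVector bins, IntegerVector dim,
                              IntegerMatrix offsets, int ngray) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const int ndir = offsets.nrow();
  NumericVector out(ngray * ngray * ndir);
  for (int o = 0; o < ndir; ++o) {
    const int dx = offsets(o, 0), dy = offsets(o, 1), dz = offsets(o, 2);
    double* mat = &out[o * ngray * ngray];
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          const int a = bins[x + d[0] * (y + d[1] * z)];
          if (a == 0) continue;
          const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
          if (!inside(x2, y2, z2, d)) continue;
          const int b = bins[x2 + d[0] * (y2 + d[1] * z2)];
          if (b == 0) continue;
          mat[(a - 1) + ngray * (b - 1)] += 1.0;
          mat[(b - 1) + ngray * (a - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ngray, ngray, ndir);
  return out;
}

// Run-length counts: maximal runs of equal gray level along each direction,
// broken by ROI boundaries. Returns ngray x maxlen x ndir.
// [[Rcpp::export]]
NumericVector cpp_glrlm_counts(IntegerVector bins, IntegerVector dim,
                               IntegerMatrix offsets, int ngray) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const int ndir = offsets.nrow();
  const int maxlen = std::max(std::max(d[0], d[1]), d[2]);
  NumericVector out(ngray * maxlen * ndir);
  for (int o = 0; o < ndir; ++o) {
    const int dx = offsets(o, 0), dy = offsets(o, 1), dz = offsets(o, 2);
    double* mat = &out[o * ngray * maxlen];
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          const int g = bins[x + d[0] * (y + d[1] * z)];
          if (g == 0) continue;
          // run start: predecessor out of bounds or different gray level
          const int xp = x - dx, yp = y - dy, zp = z - dz;
          if (inside(xp, yp, zp, d) &&
              bins[xp + d[0] * (yp + d[1] * zp)] == g)
            continue;
          int len = 1;
          int xn = x + dx, yn = y + dy, zn = z + dz;
          while (inside(xn, yn, zn, d) &&
                 bins[xn + d[0] * (yn + d[1] * zn)] == g) {
            ++len;
            xn += dx; yn += dy; zn += dz;
          }
          mat[(g - 1) + ngray * (len - 1)] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ngray, maxlen, ndir);
  return out;
}

// 26-connected components of equal gray level within the ROI. Returns a
// zone label per voxel (0 outside the ROI), labels numbered from 1 in scan
// order of the first voxel reached.
// [[Rcpp::export]]
IntegerVector cpp_label_zones26(IntegerVector bins, IntegerVector dim) {
  const int d[3] = {dim[0], dim[1], dim[2]};
  const R_xlen_t n = bins.size();
  IntegerVector zone(n);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (bins[s] == 0 || zone[s] != 0) continue;
    const int g = bins[s];
    ++next;
    zone[s] = next;
    stack.push_back((int)s);
    while (!stack.empty()) {
      const int v = stack.back();
      stack.pop_back();
      const int x = v % d[0], y = (v / d[0]) % d[1], z = v / (d[0] * d[1]);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int x2 = x + dx, y2 = y + dy, z2 = z + dz;
            if (!inside(x2, y2, z2, d)) continue;
            const int w = x2 + d[0] * (y2 + d[1] * z2);
            if (bins[w] == g && zone[w] == 0) {
              zone[w] = next;
              stack.push_back(w);
            }
          }
    }
  }
  return zone;
}

// Exact maximum pairwise Euclidean distance between point rows (mm).
// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  const int n = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = pts(i, 0) - pts(j, 0);
      const double dy = pts(i, 1) - pts(j, 1);
      const double dz = pts(i, 2) - pts(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
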