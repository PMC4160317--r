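#include <Rcpp.h>
using namespace Rcpp;

// reflect an index into [0, n-1] (symmetric half-sample reflection)
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable 2-D correlation with reflective padding.
// kx runs along columns (x), ky along rows (y); both must have odd length.
// [[Rcpp::export(name = ".sepConvolve")]]
NumericMatrix sep_convolve(const NumericMatrix& img,
                           const NumericVector& kx,
                           const NumericVector& ky) {
  const int nr = img.nrow(), nc = img.ncol();
  const int rx = (kx.size() - 1) / 2, ry = (ky.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  const double* pimg = img.begin();
  double* ptmp = tmp.begin();
  double* pout = out.begin();

  // pass 1: along x — accumulate whole columns (contiguous axpy)
  for (int j = 0; j < nc; ++j) {
    double* __restrict dst = ptmp + (R_xlen_t)j * nr;
    for (int t = -rx; t <= rx; ++t) {
      const double w = kx[t + rx];
      const double* __restrict src = pimg + (R_xlen_t)reflect_idx(j + t, nc) * nr;
      for (int i = 0; i < nr; ++i) dst[i] += w * src[i];
    }
  }
  // pass 2: along y — dot products over a reflect-padded column buffer
  std::vector<double> padded(nr + 2 * ry);
  for (int j = 0; j < nc; ++j) {
    const double* src = ptmp + (R_xlen_t)j * nr;
    for (int i = -ry; i < nr + ry; ++i)
      padded[i + ry] = src[reflect_idx(i, nr)];
    double* __restrict dst = pout + (R_xlen_t)j * nr;
    const int klen = 2 * ry + 1;
    const double* __restrict kyp = ky.begin();
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      const double* __restrict pp = padded.data() + i;
      for (int t = 0; t < klen; ++t) acc += kyp[t] * pp[t];
      dst[i] = acc;
    }
  }
  return out;
}

// Strict local minima of a (nr x nc x ns) response stack over the full
// 26-neighborhood in (row, col, level). Non-finite centers are skipped;
// per-level border margins exclude positions closer than margin[l] to the
// image border; the first and last levels are never reported (no scale
// neighbor on one side). Returns 1-based (row, col, level) triples.
// [[Rcpp::export(name = ".stackMinima")]]
IntegerMatrix stack_minima(const NumericVector& cube,
                           const IntegerVector& dims,
                           const IntegerVector& margin) {
  const int nr = dims[0], nc = dims[1], ns = dims[2];
  std::vector<int> rows, cols, lvls;
  const double* p = cube.begin();
  const R_xlen_t sl = (R_xlen_t)nr * nc;

  for (int l = 1; l < ns - 1; ++l) {
    const int m = std::max(1, margin[l]);
    for (int j = m; j < nc - m; ++j) {
      for (int i = m; i < nr - m; ++i) {
        const double v = p[(R_xlen_t)l * sl + (R_xlen_t)j * nr + i];
        if (!R_finite(v)) continue;
        bool is_min = true;
        for (int dl = -1; dl <= 1 && is_min; ++dl)
          for (int dj = -1; dj <= 1 && is_min; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dl == 0) continue;
              const double w =
                p[(R_xlen_t)(l + dl) * sl + (R_xlen_t)(j + dj) * nr + (i + di)];
              if (!(v < w)) { is_min = false; break; }
            }
        if (is_min) { rows.push_back(i + 1); cols.push_back(j + 1); lvls.push_back(l + 1); }
      }
    }
  }
  IntegerMatrix out(rows.size(), 3);
  for (size_t k = 0; k < rows.size(); ++k) {
    out(k, 0) = rows[k]; out(k, 1) = cols[k]; out(k, 2) = lvls[k];
  }
  return out;
}

// Quadratic (3x3x3) sub-grid refinement of discrete scale-space minima:
// gradient and Hessian of the lattice values, Newton step clamped to half a
// grid step per axis. Returns (dx, dy, dl, value) per hit; hits with any
// non-finite neighbor keep offset 0.
// [[Rcpp::export(name = ".refineMinima")]]
NumericMatrix refine_minima(const NumericVector& cube,
                            const IntegerVector& dims,
                            const IntegerMatrix& hits) {
  const int nr = dims[0];
  const R_xlen_t sl = (R_xlen_t)nr * dims[1];
  const double* p = cube.begin();
  const int n = hits.nrow();
  NumericMatrix out(n, 4);
  for (int k = 0; k < n; ++k) {
    const int i = hits(k, 0) - 1, j = hits(k, 1) - 1, l = hits(k, 2) - 1;
    double nb[3][3][3];
    bool finite = true;
    for (int dl = -1; dl <= 1; ++dl)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          const double v =
            p[(R_xlen_t)(l + dl) * sl + (R_xlen_t)(j + dj) * nr + (i + di)];
          nb[di + 1][dj + 1][dl + 1] = v;
          if (!R_finite(v)) finite = false;
        }
    const double v0 = nb[1][1][1];
    double ox = 0, oy = 0, ol = 0, value = v0;
    if (finite) {
      const double gx = (nb[1][2][1] - nb[1][0][1]) / 2;
      const double gy = (nb[2][1][1] - nb[0][1][1]) / 2;
      const double gl = (nb[1][1][2] - nb[1][1][0]) / 2;
      const double hxx = nb[1][2][1] - 2 * v0 + nb[1][0][1];
      const double hyy = nb[2][1][1] - 2 * v0 + nb[0][1][1];
      const double hll = nb[1][1][2] - 2 * v0 + nb[1][1][0];
      const double hxy = (nb[2][2][1] - nb[2][0][1] - nb[0][2][1] + nb[0][0][1]) / 4;
      const double hxl = (nb[1][2][2] - nb[1][0][2] - nb[1][2][0] + nb[1][0][0]) / 4;
      const double hyl = (nb[2][1][2] - nb[0][1][2] - nb[2][1][0] + nb[0][1][0]) / 4;
      // solve H * o = -g by Cramer's rule
      const double det = hxx * (hyy * hll - hyl * hyl)
                       - hxy * (hxy * hll - hyl * hxl)
                       + hxl * (hxy * hyl - hyy * hxl);
      if (R_finite(det) && std::abs(det) > 1e-12) {
        const double bx = -gx, by = -gy, bl = -gl;
        double sx = (bx * (hyy * hll - hyl * hyl)
                   - hxy * (by * hll - hyl * bl)
                   + hxl * (by * hyl - hyy * bl)) / det;
        double sy = (hxx * (by * hll - hyl * bl)
                   - bx * (hxy * hll - hyl * hxl)
                   + hxl * (hxy * bl - by * hxl)) / det;
        double sz = (hxx * (hyy * bl - by * hyl)
                   - hxy * (hxy * bl - by * hxl)
                   + bx * (hxy * hyl - hyy * hxl)) / det;
        if (R_finite(sx) && R_finite(sy) && R_finite(sz)) {
          ox = std::min(0.5, std::max(-0.5, sx));
          oy = std::min(0.5, std::max(-0.5, sy));
          ol = std::min(0.5, std::max(-0.5, sz));
          value = v0 + (gx * ox + gy * oy + gl * ol) / 2;
        }
      }
    }
    out(k, 0) = ox; out(k, 1) = oy; out(k, 2) = ol; out(k, 3) = value;
  }
  return out;
}

// Signed head-polarity response: -det where the point has dark-blob polarity
// (positive determinant and positive Laplacian), +Inf elsewhere so masked
// positions can never be strict minima.
// [[Rcpp::export(name = ".polarityResponse")]]
NumericMatrix polarity_response(const NumericMatrix& det,
                                const NumericMatrix& trace) {
  NumericMatrix out(det.nrow(), det.ncol());
  const double inf = R_PosInf;
  for (R_xlen_t k = 0; k < det.size(); ++k)
    out[k] = (det[k] > 0.0 && trace[k] > 0.0) ? -det[k] : inf;
  return out;
}

static int uf_find(std::vector<int>& parent, int a) {
  while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
  return a;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  a = uf_find(parent, a); b = uf_find(parent, b);
  if (a != b) parent[std::max(a, b)] = std::min(a, b);
}

// Two-pass 8-connectivity connected-component labeling of a logical mask.
// Labels are consecutive positive integers in raster order; background is 0.
// [[Rcpp::export(name = ".labelComponents")]]
IntegerMatrix label_components(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);
  int next = 0;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      // previously-visited 8-neighbors in column-major raster order
      int cand[4][2] = {{i - 1, j}, {i - 1, j - 1}, {i, j - 1}, {i + 1, j - 1}};
      int best = 0;
      for (int k = 0; k < 4; ++k) {
        int ii = cand[k][0], jj = cand[k][1];
        if (ii < 0 || ii >= nr || jj < 0) continue;
        int lb = lab(ii, jj);
        if (lb > 0) best = best ? std::min(best, lb) : lb;
      }
      if (best == 0) {
        best = ++next;
        parent.push_back(best);
      } else {
        for (int k = 0; k < 4; ++k) {
          int ii = cand[k][0], jj = cand[k][1];
          if (ii < 0 || ii >= nr || jj < 0) continue;
          if (lab(ii, jj) > 0) uf_union(parent, best, lab(ii, jj));
        }
      }
      lab(i, j) = best;
    }
  }
  // flatten and renumber consecutively
  std::vector<int> remap(next + 1, 0);
  int nlab = 0;
  for (int l = 1; l <= next; ++l) {
    int root = uf_find(parent, l);
    if (remap[root] == 0) remap[root] = ++nlab;
    remap[l] = remap[root];
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) lab(i, j) = remap[lab(i, j)];
  return lab;
}
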