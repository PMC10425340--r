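// Low-level 3D image primitives on R arrays stored dim = (z, y, x),
// i.e. linear index = i + d0*(j + d1*k) for (i, j, k) zero-based.
// EBImage only offers frame-wise (2D) versions of these operations,
// so the true 3D variants live here.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline R_xlen_t lin(int i, int j, int k, int d0, int d1) {
  return (R_xlen_t)i + (R_xlen_t)d0 * ((R_xlen_t)j + (R_xlen_t)d1 * k);
}

// Separable Gaussian blur; sigma in voxel units per dimension (d0, d1, d2).
// Reflective boundaries; sigma <= 0 skips that axis.
// [[Rcpp::export(name = ".blur3d")]]
NumericVector blur3d(NumericVector img, NumericVector sigma) {
  IntegerVector dim = img.attr("dim");
  if (dim.size() != 3) stop("blur3d: expected a 3D array");
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  NumericVector src = clone(img);
  NumericVector dst(src.size());
  dst.attr("dim") = dim;

  int dims[3] = {d0, d1, d2};
  // strides for each axis
  R_xlen_t strides[3] = {1, (R_xlen_t)d0, (R_xlen_t)d0 * d1};

  for (int ax = 0; ax < 3; ++ax) {
    double s = sigma[ax];
    if (s <= 0) continue;
    int r = (int)std::ceil(3.0 * s);
    if (r < 1) r = 1;
    std::vector<double> ker(2 * r + 1);
    double sum = 0.0;
    for (int t = -r; t <= r; ++t) {
      ker[t + r] = std::exp(-0.5 * (double)t * t / (s * s));
      sum += ker[t + r];
    }
    for (double &v : ker) v /= sum;

    int n = dims[ax];
    R_xlen_t stride = strides[ax];
    const double *ps = REAL(src);
    double *pd = REAL(dst);
    // copy each line into a reflect-padded buffer, convolve contiguously
    std::vector<double> buf(n + 2 * r);
    int oa = (ax == 0) ? 1 : 0;          // first other axis
    int ob = (ax == 2) ? 1 : 2;          // second other axis
    for (int b = 0; b < dims[ob]; ++b) {
      for (int a = 0; a < dims[oa]; ++a) {
        int idx3[3];
        idx3[ax] = 0; idx3[oa] = a; idx3[ob] = b;
        R_xlen_t base = lin(idx3[0], idx3[1], idx3[2], d0, d1);
        for (int p = 0; p < n; ++p) buf[r + p] = ps[base + (R_xlen_t)p * stride];
        for (int t = 0; t < r; ++t) {
          int qa = std::min(t, n - 1);              // left: index -(t+1) -> t
          buf[r - 1 - t] = ps[base + (R_xlen_t)qa * stride];
          int qb = std::max(n - 1 - t, 0);          // right: index n+t -> n-1-t
          buf[n + r + t] = ps[base + (R_xlen_t)qb * stride];
        }
        for (int p = 0; p < n; ++p) {
          double acc = 0.0;
          const double *bp = &buf[p];
          for (int t = 0; t <= 2 * r; ++t) acc += ker[t] * bp[t];
          pd[base + (R_xlen_t)p * stride] = acc;
        }
      }
    }
    std::swap(src, dst);
  }
  src.attr("dim") = dim;
  return src;
}

static void neighbor_offsets(int connectivity, std::vector<std::array<int,3>> &off) {
  off.clear();
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj)
      for (int dk = -1; dk <= 1; ++dk) {
        int m = std::abs(di) + std::abs(dj) + std::abs(dk);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({di, dj, dk});
      }
}

// Connected-component labeling of a 3D logical/integer mask.
// Returns integer array with dense labels 1..K (0 = background).
// [[Rcpp::export(name = ".label3d")]]
IntegerVector label3d(IntegerVector mask, int connectivity) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("label3d: expected a 3D array");
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("label3d: connectivity must be 6, 18 or 26");
  std::vector<std::array<int,3>> off;
  neighbor_offsets(connectivity, off);

  IntegerVector lab(mask.size());
  lab.attr("dim") = dim;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (int k = 0; k < d2; ++k)
    for (int j = 0; j < d1; ++j)
      for (int i = 0; i < d0; ++i) {
        R_xlen_t v = lin(i, j, k, d0, d1);
        if (mask[v] == 0 || lab[v] != 0) continue;
        ++next;
        lab[v] = next;
        stack.clear();
        stack.push_back(v);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back(); stack.pop_back();
          int ci = (int)(cur % d0);
          int cj = (int)((cur / d0) % d1);
          int ck = (int)(cur / ((R_xlen_t)d0 * d1));
          for (auto &o : off) {
            int ni = ci + o[0], nj = cj + o[1], nk = ck + o[2];
            if (ni < 0 || nj < 0 || nk < 0 || ni >= d0 || nj >= d1 || nk >= d2) continue;
            R_xlen_t w = lin(ni, nj, nk, d0, d1);
            if (mask[w] != 0 && lab[w] == 0) {
              lab[w] = next;
              stack.push_back(w);
            }
          }
        }
      }
  return lab;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher) used per axis.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double step2, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int q = 0;
  v[0] = 0; z[0] = -INFINITY; z[1] = INFINITY;
  for (int i = 1; i < n; ++i) {
    double s;
    while (true) {
      s = ((f[i] + step2 * i * i) - (f[v[q]] + step2 * v[q] * v[q])) /
          (2.0 * step2 * (i - v[q]));
      if (s <= z[q]) { --q; } else break;
    }
    ++q;
    v[q] = i; z[q] = s; z[q + 1] = INFINITY;
  }
  q = 0;
  for (int i = 0; i < n; ++i) {
    while (z[q + 1] < i) ++q;
    double di = (double)(i - v[q]);
    d[i] = step2 * di * di + f[v[q]];
  }
}

// Anisotropic squared Euclidean distance transform: for foreground voxels,
// squared distance (in physical units given by `spacing`, per dim) to the
// nearest background voxel. Background gets 0.
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(IntegerVector mask, NumericVector spacing) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("edt3d_sq: expected a 3D array");
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  NumericVector out(mask.size());
  out.attr("dim") = dim;
  const double BIG = 1e30;
  for (R_xlen_t v = 0; v < mask.size(); ++v) out[v] = mask[v] ? BIG : 0.0;

  int dims[3] = {d0, d1, d2};
  R_xlen_t strides[3] = {1, (R_xlen_t)d0, (R_xlen_t)d0 * d1};
  for (int ax = 0; ax < 3; ++ax) {
    int n = dims[ax];
    double step2 = spacing[ax] * spacing[ax];
    R_xlen_t stride = strides[ax];
    int oa = (ax == 0) ? 1 : 0;
    int ob = (ax == 2) ? 1 : 2;
    std::vector<double> f(n), d(n);
    for (int b = 0; b < dims[ob]; ++b)
      for (int a = 0; a < dims[oa]; ++a) {
        int idx3[3];
        idx3[ax] = 0; idx3[oa] = a; idx3[ob] = b;
        R_xlen_t base = lin(idx3[0], idx3[1], idx3[2], d0, d1);
        for (int p = 0; p < n; ++p) f[p] = out[base + (R_xlen_t)p * stride];
        dt1d(f, d, step2, n);
        for (int p = 0; p < n; ++p) out[base + (R_xlen_t)p * stride] = d[p];
      }
  }
  return out;
}

// Marker-based watershed on a priority map (e.g. the EDT): voxels are flooded
// from the seeds in order of decreasing priority; each foreground voxel takes
// the label of the neighbor that reached it first.
// seeds: zero-based linear indices; seed s gets label s+1.
// [[Rcpp::export(name = ".watershed_seeded")]]
IntegerVector watershed_seeded(IntegerVector mask, NumericVector priority,
                               IntegerVector seeds, int connectivity) {
  IntegerVector dim = mask.attr("dim");
  if (dim.size() != 3) stop("watershed_seeded: expected a 3D array");
  int d0 = dim[0], d1 = dim[1], d2 = dim[2];
  std::vector<std::array<int,3>> off;
  neighbor_offsets(connectivity, off);

  IntegerVector lab(mask.size());
  lab.attr("dim") = dim;
  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node> pq;
  for (int s = 0; s < seeds.size(); ++s) {
    R_xlen_t v = seeds[s];
    if (v < 0 || v >= mask.size() || mask[v] == 0)
      stop("watershed_seeded: seed outside foreground");
    lab[v] = s + 1;
    pq.push({priority[v], v});
  }
  while (!pq.empty()) {
    R_xlen_t cur = pq.top().second; pq.pop();
    int ci = (int)(cur % d0);
    int cj = (int)((cur / d0) % d1);
    int ck = (int)(cur / ((R_xlen_t)d0 * d1));
    for (auto &o : off) {
      int ni = ci + o[0], nj = cj + o[1], nk = ck + o[2];
      if (ni < 0 || nj < 0 || nk < 0 || ni >= d0 || nj >= d1 || nk >= d2) continue;
      R_xlen_t w = lin(ni, nj, nk, d0, d1);
      if (mask[w] != 0 && lab[w] == 0) {
        lab[w] = lab[cur];
        pq.push({priority[w], w});
      }
    }
  }
  return lab;
}
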