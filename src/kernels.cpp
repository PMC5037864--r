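// Low-level 3D grid kernels shared by the preprocessing and segmentation
// stages. Arrays are R arrays with dim = c(n1, n2, n3) and the first index
// fastest-varying (column-major); in this package that is (z, y, x).

#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Reflect an out-of-range index into [0, n) by mirroring at the array
// edges (edge sample repeated, i.e. ... c b a | a b c ...).
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Separable 1D convolution along one array dimension with reflective
// boundary handling. kernel has odd length; axis is 1-based.
// [[Rcpp::export]]
NumericVector conv1d_reflect(NumericVector x, IntegerVector dims,
                             NumericVector kernel, int axis) {
  const int nd = dims.size();
  if (nd != 3) stop("dims must have length 3");
  if (axis < 1 || axis > 3) stop("axis must be 1, 2 or 3");
  const int K = kernel.size();
  if (K % 2 != 1) stop("kernel length must be odd");
  const int r = (K - 1) / 2;
  const int n = dims[axis - 1];
  R_xlen_t stride = 1;
  for (int a = 0; a < axis - 1; ++a) stride *= dims[a];
  R_xlen_t total = 1;
  for (int a = 0; a < 3; ++a) total *= dims[a];
  const R_xlen_t nouter = total / (stride * n);
  NumericVector out(total);
  const double* xp = REAL(x);
  double* op = REAL(out);
  const double* w = REAL(kernel);

  if (stride == 1) {
    // contiguous lines: vectorize over j for each tap
    std::vector<double> padded((size_t)n + 2 * r);
    for (R_xlen_t o = 0; o < nouter; ++o) {
      const double* line = xp + o * n;
      double* oline = op + o * n;
      for (int i = 0; i < n + 2 * r; ++i)
        padded[i] = line[reflect_idx(i - r, n)];
      const double* __restrict__ pp = padded.data();
      for (int k = 0; k < K; ++k) {
        const double wk = w[k];
        const double* __restrict__ sp = pp + k;
        for (int j = 0; j < n; ++j) oline[j] += wk * sp[j];
      }
    }
  } else {
    bool symmetric = true;
    for (int k = 0; k < r; ++k)
      if (w[k] != w[K - 1 - k]) { symmetric = false; break; }
    std::vector<double> accbuf((size_t)stride);
    for (R_xlen_t o = 0; o < nouter; ++o) {
      const R_xlen_t base = o * stride * n;
      for (int j = 0; j < n; ++j) {
        double* __restrict__ acc = accbuf.data();
        std::fill(accbuf.begin(), accbuf.end(), 0.0);
        if (!symmetric) {
          for (int k = 0; k < K; ++k) {
            const int src = reflect_idx(j + k - r, n);
            const double* __restrict__ sp = xp + base + (R_xlen_t)src * stride;
            const double wk = w[k];
            for (R_xlen_t p = 0; p < stride; ++p) acc[p] += wk * sp[p];
          }
          double* dst0 = op + base + (R_xlen_t)j * stride;
          std::copy(accbuf.begin(), accbuf.end(), dst0);
          continue;
        }
        // fold symmetric taps: Gaussian kernels are symmetric around centre
        for (int k = 0; k < r; ++k) {
          const int sa = reflect_idx(j + k - r, n);
          const int sb = reflect_idx(j + (K - 1 - k) - r, n);
          const double* __restrict__ pa = xp + base + (R_xlen_t)sa * stride;
          const double* __restrict__ pb = xp + base + (R_xlen_t)sb * stride;
          const double wk = w[k];
          for (R_xlen_t p = 0; p < stride; ++p) acc[p] += wk * (pa[p] + pb[p]);
        }
        {
          const double* __restrict__ pc = xp + base + (R_xlen_t)j * stride;
          const double wc = w[r];
          for (R_xlen_t p = 0; p < stride; ++p) acc[p] += wc * pc[p];
        }
        double* dst = op + base + (R_xlen_t)j * stride;
        std::copy(accbuf.begin(), accbuf.end(), dst);
      }
    }
  }
  return out;
}

static inline void decode3(R_xlen_t i, int n1, int n2, int& i1, int& i2, int& i3) {
  i1 = (int)(i % n1);
  R_xlen_t rest = i / n1;
  i2 = (int)(rest % n2);
  i3 = (int)(rest / n2);
}

// 26-connected component labelling of a logical mask. Labels are assigned
// in order of first encounter during an ascending linear-index scan, so
// the result is fully deterministic.
// [[Rcpp::export]]
IntegerVector label3d_26(LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t total = (R_xlen_t)n1 * n2 * n3;
  if (mask.size() != total) stop("mask length does not match dims");
  IntegerVector labels(total, 0);
  const int* mp = LOGICAL(mask);
  int* lp = INTEGER(labels);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < total; ++i) {
    if (!mp[i] || lp[i]) continue;
    ++next;
    lp[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int z, y, x;
      decode3(cur, n1, n2, z, y, x);
      for (int dx = -1; dx <= 1; ++dx) {
        const int xx = x + dx;
        if (xx < 0 || xx >= n3) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          const int yy = y + dy;
          if (yy < 0 || yy >= n2) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int zz = z + dz;
            if (zz < 0 || zz >= n1) continue;
            const R_xlen_t ni = (R_xlen_t)zz + (R_xlen_t)n1 * (yy + (R_xlen_t)n2 * xx);
            if (mp[ni] && !lp[ni]) {
              lp[ni] = next;
              stack.push_back(ni);
            }
          }
        }
      }
    }
  }
  return labels;
}

struct WsNode {
  double value;
  R_xlen_t index;
  int label;
};
struct WsCmp {
  // max-heap on value; ties broken toward the smaller linear index so the
  // flooding order is deterministic
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.value != b.value) return a.value < b.value;
    return a.index > b.index;
  }
};

// Marker-based watershed by priority flooding of the (smoothed) intensity
// inside a mask, descending from the seed maxima. Every masked voxel ends
// up with exactly one label.
// [[Rcpp::export]]
IntegerVector watershed3d(NumericVector intensity, IntegerVector markers,
                          LogicalVector mask, IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t total = (R_xlen_t)n1 * n2 * n3;
  if (intensity.size() != total || markers.size() != total || mask.size() != total)
    stop("array lengths do not match dims");
  IntegerVector labels(total, 0);
  const double* ip = REAL(intensity);
  const int* mk = INTEGER(markers);
  const int* mp = LOGICAL(mask);
  int* lp = INTEGER(labels);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  for (R_xlen_t i = 0; i < total; ++i) {
    if (mk[i] > 0 && mp[i]) {
      lp[i] = mk[i];
      pq.push(WsNode{ip[i], i, mk[i]});
    }
  }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    int z, y, x;
    decode3(nd.index, n1, n2, z, y, x);
    for (int dx = -1; dx <= 1; ++dx) {
      const int xx = x + dx;
      if (xx < 0 || xx >= n3) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        const int yy = y + dy;
        if (yy < 0 || yy >= n2) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          const int zz = z + dz;
          if (zz < 0 || zz >= n1) continue;
          const R_xlen_t ni = (R_xlen_t)zz + (R_xlen_t)n1 * (yy + (R_xlen_t)n2 * xx);
          if (mp[ni] && !lp[ni]) {
            lp[ni] = nd.label;
            pq.push(WsNode{ip[ni], ni, nd.label});
          }
        }
      }
    }
  }
  return labels;
}

// 1-based linear indices of masked voxels whose value is >= all of their
// in-bounds 26-neighbours.
// [[Rcpp::export]]
IntegerVector local_maxima3d(NumericVector x, LogicalVector mask,
                             IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t total = (R_xlen_t)n1 * n2 * n3;
  if (x.size() != total || mask.size() != total)
    stop("array lengths do not match dims");
  const double* xp = REAL(x);
  const int* mp = LOGICAL(mask);
  std::vector<int> hits;
  for (R_xlen_t i = 0; i < total; ++i) {
    if (!mp[i]) continue;
    int z, y, xx0;
    decode3(i, n1, n2, z, y, xx0);
    const double v = xp[i];
    bool is_max = true;
    for (int dx = -1; dx <= 1 && is_max; ++dx) {
      const int xx = xx0 + dx;
      if (xx < 0 || xx >= n3) continue;
      for (int dy = -1; dy <= 1 && is_max; ++dy) {
        const int yy = y + dy;
        if (yy < 0 || yy >= n2) continue;
        for (int dz = -1; dz <= 1; ++dz) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          const int zz = z + dz;
          if (zz < 0 || zz >= n1) continue;
          const R_xlen_t ni = (R_xlen_t)zz + (R_xlen_t)n1 * (yy + (R_xlen_t)n2 * xx);
          if (xp[ni] > v) { is_max = false; break; }
        }
      }
    }
    if (is_max) hits.push_back((int)(i + 1));
  }
  return wrap(hits);
}
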