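#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Column-major raster helpers. `img` holds 0/1; `eight` selects 8-adjacency.
// Component counting is an iterative depth-first flood over an explicit stack;
// the `visited` buffer is reused across calls within a sweep.

namespace {

inline int idx(int r, int c, int nr) { return c * nr + r; }

// Count connected components of pixels with value `phase` (0 or 1).
// If borderTouch != nullptr, components containing a border pixel are
// excluded from the count (the hole rule for the background phase).
int countComponents(const std::vector<unsigned char>& img, int nr, int nc,
                    unsigned char phase, bool eight, bool excludeBorder,
                    std::vector<unsigned char>& visited,
                    std::vector<int>& stack) {
  std::fill(visited.begin(), visited.end(), 0);
  int count = 0;
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = eight ? dr8 : dr4;
  const int* dc = eight ? dc8 : dc4;
  const int nn = eight ? 8 : 4;

  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      int i0 = idx(r0, c0, nr);
      if (img[i0] != phase || visited[i0]) continue;
      bool touchesBorder = false;
      stack.clear();
      stack.push_back(i0);
      visited[i0] = 1;
      while (!stack.empty()) {
        int i = stack.back();
        stack.pop_back();
        int r = i % nr, c = i / nr;
        if (r == 0 || r == nr - 1 || c == 0 || c == nc - 1)
          touchesBorder = true;
        for (int k = 0; k < nn; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          int j = idx(rr, cc, nr);
          if (img[j] == phase && !visited[j]) {
            visited[j] = 1;
            stack.push_back(j);
          }
        }
      }
      if (!excludeBorder || !touchesBorder) ++count;
    }
  }
  return count;
}

void bettiFromBuffer(const std::vector<unsigned char>& img, int nr, int nc,
                     bool fgEight, bool bgEight,
                     std::vector<unsigned char>& visited,
                     std::vector<int>& stack, int out[2]) {
  out[0] = countComponents(img, nr, nc, 1, fgEight, false, visited, stack);
  out[1] = countComponents(img, nr, nc, 0, bgEight, true, visited, stack);
}

// Bit-quad (Gray) Euler characteristic. Counts 2x2 windows over the raster
// padded with one background ring: n1 = one foreground pixel, n3 = three,
// nd = two diagonal foreground pixels. chi_4 = (n1 - n3 + 2 nd) / 4,
// chi_8 = (n1 - n3 - 2 nd) / 4.
int eulerBitQuad(const std::vector<unsigned char>& img, int nr, int nc,
                 bool fgEight) {
  long n1 = 0, n3 = 0, nd = 0;
  for (int c = -1; c < nc; ++c) {
    for (int r = -1; r < nr; ++r) {
      unsigned char a = (r >= 0 && c >= 0) ? img[idx(r, c, nr)] : 0;          // tl
      unsigned char b = (r >= 0 && c + 1 < nc) ? img[idx(r, c + 1, nr)] : 0;  // tr
      unsigned char d = (r + 1 < nr && c >= 0) ? img[idx(r + 1, c, nr)] : 0;  // bl
      unsigned char e = (r + 1 < nr && c + 1 < nc) ? img[idx(r + 1, c + 1, nr)] : 0; // br
      int s = a + b + d + e;
      if (s == 1) ++n1;
      else if (s == 3) ++n3;
      else if (s == 2 && ((a && e) || (b && d))) ++nd;
    }
  }
  long num = fgEight ? (n1 - n3 - 2 * nd) : (n1 - n3 + 2 * nd);
  return (int)(num / 4);
}

void toBuffer(const LogicalMatrix& m, std::vector<unsigned char>& buf) {
  int n = m.nrow() * m.ncol();
  buf.resize(n);
  for (int i = 0; i < n; ++i) buf[i] = m[i] == TRUE ? 1 : 0;
}

} // namespace

// [[Rcpp::export(name = ".cppBetti")]]
IntegerVector cppBetti(LogicalMatrix img, bool fgEight, bool bgEight) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<unsigned char> buf, visited((size_t)nr * nc);
  std::vector<int> stack;
  toBuffer(img, buf);
  int out[2];
  bettiFromBuffer(buf, nr, nc, fgEight, bgEight, visited, stack, out);
  return IntegerVector::create(out[0], out[1]);
}

// [[Rcpp::export(name = ".cppEuler")]]
int cppEuler(LogicalMatrix img, bool fgEight) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<unsigned char> buf;
  toBuffer(img, buf);
  return eulerBitQuad(buf, nr, nc, fgEight);
}

// Disjoint-set forest over pixels with lazy activation and border
// bookkeeping; supports the monotone filtration sweeps below.
struct PixelDSU {
  std::vector<int> parent;
  std::vector<unsigned char> isBorder;
  int comps, borderComps;
  void init(int n) {
    parent.assign(n, -1);
    isBorder.assign(n, 0);
    comps = 0;
    borderComps = 0;
  }
  int find(int i) {
    int r = i;
    while (parent[r] != r) r = parent[r];
    while (parent[i] != r) { int nx = parent[i]; parent[i] = r; i = nx; }
    return r;
  }
  void activate(int i, bool border) {
    parent[i] = i;
    isBorder[i] = border ? 1 : 0;
    ++comps;
    if (border) ++borderComps;
  }
  bool active(int i) const { return parent[i] >= 0; }
  void unite(int a, int b) {
    int ra = find(a), rb = find(b);
    if (ra == rb) return;
    --comps;
    if (isBorder[ra] && isBorder[rb]) --borderComps;
    parent[rb] = ra;
    isBorder[ra] = isBorder[ra] | isBorder[rb];
  }
};

namespace {

// Add pixel `i` to the active phase, merging with active neighbours.
inline void addPixel(PixelDSU& dsu, const int i, int nr, int nc, bool eight) {
  int r = i % nr, c = i / nr;
  dsu.activate(i, r == 0 || r == nr - 1 || c == 0 || c == nc - 1);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = eight ? 8 : 4;
  for (int k = 0; k < nn; ++k) {
    int rr = r + dr8[k], cc = c + dc8[k];
    if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
    int j = idx(rr, cc, nr);
    if (dsu.active(j)) dsu.unite(i, j);
  }
}

} // namespace

// Betti pair at every threshold of a sweep. Foreground is
// (hu >= t) when `ge`, else (hu <= t); pixels outside `mask` are background.
//
// Both curves are computed by monotone filtration sweeps with an
// incremental union-find: with ge polarity the foreground only grows as the
// threshold descends (b0 sweep) and the background only grows as it
// ascends (b1 sweep: holes = background components minus border-touching
// ones); `le` polarity mirrors the directions.
// [[Rcpp::export(name = ".cppProfile")]]
IntegerMatrix cppProfile(NumericMatrix hu, LogicalMatrix mask,
                         NumericVector thresholds, bool ge,
                         bool fgEight, bool bgEight) {
  int nr = hu.nrow(), nc = hu.ncol(), n = nr * nc, nt = thresholds.size();
  IntegerMatrix out(nt, 2);
  PixelDSU dsu;

  // in-mask pixel indices sorted by HU
  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i)
    if (mask[i] == TRUE) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return hu[a] < hu[b]; });

  // ---- b0: foreground sweep ------------------------------------------------
  // ge: descending thresholds, activate pixels with hu >= t (sorted
  // descending); le: ascending thresholds, activate hu <= t.
  dsu.init(n);
  if (ge) {
    int p = (int)order.size() - 1;
    for (int k = nt - 1; k >= 0; --k) {
      double t = thresholds[k];
      while (p >= 0 && hu[order[p]] >= t) {
        addPixel(dsu, order[p], nr, nc, fgEight);
        --p;
      }
      out(k, 0) = dsu.comps;
    }
  } else {
    size_t p = 0;
    for (int k = 0; k < nt; ++k) {
      double t = thresholds[k];
      while (p < order.size() && hu[order[p]] <= t) {
        addPixel(dsu, order[p], nr, nc, fgEight);
        ++p;
      }
      out(k, 0) = dsu.comps;
    }
  }

  // ---- b1: background sweep ------------------------------------------------
  // Background = out-of-mask pixels (always) plus in-mask pixels failing the
  // polarity predicate; it grows as the threshold ascends (ge) / descends
  // (le). Holes exclude components that reach the raster border.
  dsu.init(n);
  for (int i = 0; i < n; ++i)
    if (mask[i] != TRUE) addPixel(dsu, i, nr, nc, bgEight);
  if (ge) {
    size_t p = 0;
    for (int k = 0; k < nt; ++k) {
      double t = thresholds[k];
      while (p < order.size() && hu[order[p]] < t) {
        addPixel(dsu, order[p], nr, nc, bgEight);
        ++p;
      }
      out(k, 1) = dsu.comps - dsu.borderComps;
    }
  } else {
    int p = (int)order.size() - 1;
    for (int k = nt - 1; k >= 0; --k) {
      double t = thresholds[k];
      while (p >= 0 && hu[order[p]] > t) {
        addPixel(dsu, order[p], nr, nc, bgEight);
        --p;
      }
      out(k, 1) = dsu.comps - dsu.borderComps;
    }
  }
  return out;
}
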