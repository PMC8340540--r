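#include <Rcpp.h>
#include <queue>
#include <vector>
#include <utility>
#include <cmath>

using namespace Rcpp;

// 8-neighbour offsets in the order x1..x8 = E, NE, N, NW, W, SW, S, SE
// (counterclockwise; x1, x3, x5, x7 are the 4-neighbours).
static const int DI8[8] = { 0, -1, -1, -1,  0,  1,  1,  1 };
static const int DJ8[8] = { 1,  1,  0, -1, -1, -1,  0,  1 };

static inline int nbval(const IntegerMatrix &b, int i, int j) {
  if (i < 0 || j < 0 || i >= b.nrow() || j >= b.ncol()) return 0;
  return b(i, j) != 0 ? 1 : 0;
}

static inline int fg_count_at(const IntegerMatrix &b, int i, int j) {
  int n = 0;
  for (int k = 0; k < 8; ++k) n += nbval(b, i + DI8[k], j + DJ8[k]);
  return n;
}

// Eight-way neighbourhood number N_c: the connectivity number of the
// foreground (8-connectivity) computed from the complemented neighbourhood,
// with the cyclic wrap x9 == x1.  N_c == 1 marks a simple (deletable) pixel.
static int nc8_at(const IntegerMatrix &b, int i, int j) {
  int x[10];
  for (int k = 1; k <= 8; ++k) x[k] = nbval(b, i + DI8[k - 1], j + DJ8[k - 1]);
  x[9] = x[1];
  int s = 0;
  for (int k = 1; k <= 7; k += 2) {
    int xb0 = 1 - x[k], xb1 = 1 - x[k + 1], xb2 = 1 - x[k + 2];
    s += xb0 - xb0 * xb1 * xb2;
  }
  return s;
}

// Exact gray-weighted distance transform: multi-source Dijkstra on the
// 4-connected grid where entering pixel (i,j) costs f(i,j); sources are all
// background (zero) pixels.  Costs are integer-valued and exact (doubles are
// exact for sums of 8-bit values on any realistic image size).
// [[Rcpp::export]]
NumericMatrix gwdt_cpp(IntegerMatrix f) {
  int h = f.nrow(), w = f.ncol(), n = h * w;
  std::vector<double> dist((size_t)n, R_PosInf);
  typedef std::pair<double, int> PQE;
  std::priority_queue<PQE, std::vector<PQE>, std::greater<PQE> > pq;
  bool any_bg = false;
  for (int id = 0; id < n; ++id) {
    if (f[id] == 0) { dist[id] = 0.0; pq.push(PQE(0.0, id)); any_bg = true; }
  }
  if (!any_bg) stop("no background reachable: image contains no zero-valued pixel");
  const int di[4] = { -1, 1, 0, 0 }, dj[4] = { 0, 0, -1, 1 };
  while (!pq.empty()) {
    double d = pq.top().first;
    int id = pq.top().second;
    pq.pop();
    if (d > dist[id]) continue;
    int i = id % h, j = id / h; // column-major linear index
    for (int k = 0; k < 4; ++k) {
      int ni = i + di[k], nj = j + dj[k];
      if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
      int nid = nj * h + ni;
      if (f[nid] == 0) continue;
      double nd = d + (double)f[nid];
      if (nd < dist[nid]) { dist[nid] = nd; pq.push(PQE(nd, nid)); }
    }
  }
  NumericMatrix out(h, w);
  for (int id = 0; id < n; ++id) out[id] = dist[id];
  return out;
}

// Gray-weighted path skeletonize: ordered homotopic thinning of the GWDT
// surface.  Foreground pixels are visited in ascending (cost, row-major
// index) order; a pixel is deleted iff N_c == 1 and it has at least two
// foreground 8-neighbours (endpoints and isolated pixels survive).  After a
// deletion the foreground neighbours are re-enqueued, so the pass runs to a
// fixed point and the surviving crest is 8-connected and thin.
// [[Rcpp::export]]
IntegerMatrix gwps_cpp(NumericMatrix t) {
  int h = t.nrow(), w = t.ncol();
  IntegerMatrix b(h, w);
  typedef std::pair<double, long long> PQE; // (cost, row-major index)
  std::priority_queue<PQE, std::vector<PQE>, std::greater<PQE> > pq;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      if (t(i, j) > 0) {
        b(i, j) = 1;
        pq.push(PQE(t(i, j), (long long)i * w + j));
      }
  while (!pq.empty()) {
    long long idx = pq.top().second;
    pq.pop();
    int i = (int)(idx / w), j = (int)(idx % w);
    if (!b(i, j)) continue;
    if (nc8_at(b, i, j) == 1 && fg_count_at(b, i, j) >= 2) {
      b(i, j) = 0;
      for (int k = 0; k < 8; ++k) {
        int ni = i + DI8[k], nj = j + DJ8[k];
        if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
        if (b(ni, nj)) pq.push(PQE(t(ni, nj), (long long)ni * w + nj));
      }
    }
  }
  return b;
}

// Zhang-Suen two-subiteration thinning of a binary image ('2D' baseline).
// p2..p9 numbering: p2=N, p3=NE, p4=E, p5=SE, p6=S, p7=SW, p8=W, p9=NW.
// [[Rcpp::export]]
IntegerMatrix zhang_suen_cpp(IntegerMatrix input) {
  IntegerMatrix b = clone(input);
  int h = b.nrow(), w = b.ncol();
  const int pi[8] = { -1, -1,  0,  1,  1,  1,  0, -1 };
  const int pj[8] = {  0,  1,  1,  1,  0, -1, -1, -1 };
  bool changed = true;
  std::vector<std::pair<int, int> > del;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      del.clear();
      for (int i = 0; i < h; ++i)
        for (int j = 0; j < w; ++j) {
          if (!b(i, j)) continue;
          int p[8];
          int B = 0;
          for (int k = 0; k < 8; ++k) { p[k] = nbval(b, i + pi[k], j + pj[k]); B += p[k]; }
          if (B < 2 || B > 6) continue;
          int A = 0;
          for (int k = 0; k < 8; ++k) if (p[k] == 0 && p[(k + 1) % 8] == 1) ++A;
          if (A != 1) continue;
          if (step == 0) {
            if (p[0] * p[2] * p[4] != 0) continue; // p2*p4*p6
            if (p[2] * p[4] * p[6] != 0) continue; // p4*p6*p8
          } else {
            if (p[0] * p[2] * p[6] != 0) continue; // p2*p4*p8
            if (p[0] * p[4] * p[6] != 0) continue; // p2*p6*p8
          }
          del.push_back(std::make_pair(i, j));
        }
      for (size_t k = 0; k < del.size(); ++k) b(del[k].first, del[k].second) = 0;
      if (!del.empty()) changed = true;
    }
  }
  return b;
}

// Directional border thinning of a binary image ('3D' baseline): the
// six-subiteration border-deletion scheme of volumetric thinning applied to
// a single-slice volume, where the two out-of-plane subiterations are
// vacuous and the remaining four (N, S, W, E) delete simple, non-endpoint
// border pixels with sequential re-verification.
// [[Rcpp::export]]
IntegerMatrix dir_thin_cpp(IntegerMatrix input) {
  IntegerMatrix b = clone(input);
  int h = b.nrow(), w = b.ncol();
  const int di[4] = { -1, 1, 0, 0 }, dj[4] = { 0, 0, -1, 1 };
  bool changed = true;
  std::vector<std::pair<int, int> > cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 4; ++d) {
      cand.clear();
      for (int i = 0; i < h; ++i)
        for (int j = 0; j < w; ++j) {
          if (!b(i, j)) continue;
          if (nbval(b, i + di[d], j + dj[d])) continue; // not a d-border pixel
          if (fg_count_at(b, i, j) < 2) continue;       // endpoint / isolated
          if (nc8_at(b, i, j) != 1) continue;           // not simple
          cand.push_back(std::make_pair(i, j));
        }
      for (size_t k = 0; k < cand.size(); ++k) {
        int i = cand[k].first, j = cand[k].second;
        // sequential re-check: earlier deletions may have changed the local
        // configuration
        if (fg_count_at(b, i, j) < 2) continue;
        if (nc8_at(b, i, j) != 1) continue;
        b(i, j) = 0;
        changed = true;
      }
    }
  }
  return b;
}

// Label 8-connected foreground components (BFS flood fill), labels 1..k.
// [[Rcpp::export]]
IntegerMatrix label8_cpp(IntegerMatrix b) {
  int h = b.nrow(), w = b.ncol();
  IntegerMatrix lab(h, w);
  int next_label = 0;
  std::vector<int> stack;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      if (!b(i, j) || lab(i, j)) continue;
      ++next_label;
      stack.clear();
      stack.push_back(j * h + i);
      lab(i, j) = next_label;
      while (!stack.empty()) {
        int id = stack.back();
        stack.pop_back();
        int ci = id % h, cj = id / h;
        for (int k = 0; k < 8; ++k) {
          int ni = ci + DI8[k], nj = cj + DJ8[k];
          if (ni < 0 || ni >= h || nj < 0 || nj >= w) continue;
          if (b(ni, nj) && !lab(ni, nj)) {
            lab(ni, nj) = next_label;
            stack.push_back(nj * h + ni);
          }
        }
      }
    }
  return lab;
}

// For every pixel of an h x w grid, the Euclidean distance to the nearest
// point of a 0-based coordinate list, and the (1-based) index of that point.
// Ties resolve to the earliest index.  Brute force: O(h*w*m), intended for
// the sparse pixel sets of thin edges.
// [[Rcpp::export]]
List nearest_to_coords_cpp(int h, int w, IntegerVector ri, IntegerVector rj) {
  int m = ri.size();
  if (m == 0) stop("empty coordinate set");
  NumericMatrix dist(h, w);
  IntegerMatrix idx(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double best = R_PosInf;
      int bk = 0;
      for (int k = 0; k < m; ++k) {
        double di = (double)(i - ri[k]), dj = (double)(j - rj[k]);
        double d2 = di * di + dj * dj;
        if (d2 < best) { best = d2; bk = k; }
      }
      dist(i, j) = std::sqrt(best);
      idx(i, j) = bk + 1;
    }
  return List::create(Named("dist") = dist, Named("index") = idx);
}
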