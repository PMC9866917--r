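#include <Rcpp.h>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// reflect (half-sample symmetric) index: -1 -> 0, n -> n-1
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export]]
IntegerMatrix cpp_median_filter(IntegerMatrix ch, int side) {
  int nr = ch.nrow(), nc = ch.ncol(), h = side / 2;
  IntegerMatrix out(nr, nc);
  std::vector<int> buf(side * side);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -h; dj <= h; ++dj) {
        int jj = reflect_idx(j + dj, nc);
        for (int di = -h; di <= h; ++di)
          buf[k++] = ch(reflect_idx(i + di, nr), jj);
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
      out(i, j) = buf[k / 2];
    }
  }
  return out;
}

// binary erosion/dilation with the 3x3 cross ("elliptical" 3x3) element
static LogicalMatrix morph(const LogicalMatrix& m, int iter, bool dilate) {
  int nr = m.nrow(), nc = m.ncol();
  LogicalMatrix cur = clone(m);
  for (int it = 0; it < iter; ++it) {
    LogicalMatrix nxt(nr, nc);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        bool c = cur(i, j);
        // outside the image counts as background
        bool up    = (i > 0)      ? cur(i - 1, j) : false;
        bool down  = (i < nr - 1) ? cur(i + 1, j) : false;
        bool left  = (j > 0)      ? cur(i, j - 1) : false;
        bool right = (j < nc - 1) ? cur(i, j + 1) : false;
        nxt(i, j) = dilate ? (c || up || down || left || right)
                           : (c && up && down && left && right);
      }
    cur = nxt;
  }
  return cur;
}

// [[Rcpp::export]]
LogicalMatrix cpp_erode(LogicalMatrix m, int iter) { return morph(m, iter, false); }

// [[Rcpp::export]]
LogicalMatrix cpp_dilate(LogicalMatrix m, int iter) { return morph(m, iter, true); }

// 1-D squared distance transform (Felzenszwalb & Huttenlocher)
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -R_PosInf; z[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// exact Euclidean distance to the nearest background (false) pixel
// [[Rcpp::export]]
NumericMatrix cpp_distance_transform(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix d2(nr, nc);
  const double INF = 1e18;
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // columns
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? INF : 0.0;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) d2(i, j) = d[i];
  }
  // rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = d2(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) d2(i, j) = d[j];
  }
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = std::sqrt(d2(i, j));
  return out;
}

// 4-connected components; labels assigned in column-major scan order
// [[Rcpp::export]]
IntegerMatrix cpp_label4(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      lab(i, j) = next;
      q.push(i + j * nr);
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int pi = p % nr, pj = p / nr;
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int t = 0; t < 4; ++t) {
          int ii = pi + di[t], jj = pj + dj[t];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && !lab(ii, jj)) { lab(ii, jj) = next; q.push(ii + jj * nr); }
        }
      }
    }
  return lab;
}

// Sobel gradient magnitude with replicated borders
// [[Rcpp::export]]
NumericMatrix cpp_sobel(NumericMatrix img) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix g(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int im = std::max(i - 1, 0), ip = std::min(i + 1, nr - 1);
      int jm = std::max(j - 1, 0), jp = std::min(j + 1, nc - 1);
      double gx = (img(im, jp) + 2 * img(i, jp) + img(ip, jp))
                - (img(im, jm) + 2 * img(i, jm) + img(ip, jm));
      double gy = (img(ip, jm) + 2 * img(ip, j) + img(ip, jp))
                - (img(im, jm) + 2 * img(im, j) + img(im, jp));
      g(i, j) = std::sqrt(gx * gx + gy * gy);
    }
  return g;
}

struct WsEntry {
  double prio;
  long long order;
  int idx;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.prio != b.prio) return a.prio > b.prio;
    return a.order > b.order;  // FIFO among equal priorities
  }
};

// Meyer flooding watershed. markers: 0 = unknown (to flood), >=1 = seeded
// labels. Returns labels with -1 on ridge pixels. 4-connectivity.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix grad, IntegerMatrix markers) {
  int nr = grad.nrow(), nc = grad.ncol();
  IntegerMatrix lab = clone(markers);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  std::vector<char> queued((size_t)nr * nc, 0);
  long long order = 0;
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (lab(i, j) != 0) continue;
      bool seeded = false;
      for (int t = 0; t < 4 && !seeded; ++t) {
        int ii = i + di[t], jj = j + dj[t];
        if (ii >= 0 && ii < nr && jj >= 0 && jj < nc && lab(ii, jj) > 0) seeded = true;
      }
      if (seeded) {
        pq.push({grad(i, j), order++, i + j * nr});
        queued[(size_t)(i + j * nr)] = 1;
      }
    }
  while (!pq.empty()) {
    WsEntry e = pq.top(); pq.pop();
    int i = e.idx % nr, j = e.idx / nr;
    if (lab(i, j) != 0) continue;
    int found = 0; bool conflict = false;
    for (int t = 0; t < 4; ++t) {
      int ii = i + di[t], jj = j + dj[t];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      int l = lab(ii, jj);
      if (l > 0) {
        if (found == 0) found = l;
        else if (found != l) conflict = true;
      }
    }
    if (found == 0) { lab(i, j) = -1; continue; }  // isolated among ridges
    lab(i, j) = conflict ? -1 : found;
    if (!conflict) {
      for (int t = 0; t < 4; ++t) {
        int ii = i + di[t], jj = j + dj[t];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        size_t p = (size_t)(ii + jj * nr);
        if (lab(ii, jj) == 0 && !queued[p]) {
          pq.push({grad(ii, jj), order++, ii + jj * nr});
          queued[p] = 1;
        }
      }
    }
  }
  return lab;
}
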