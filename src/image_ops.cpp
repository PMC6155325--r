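#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 2D median filter with an odd square window; borders are mirror-padded so
// the output has the same extent as the input and edge maxima survive.
// [[Rcpp::export]]
NumericMatrix median_filter_cpp(NumericMatrix img, int size) {
  const int nr = img.nrow(), nc = img.ncol(), h = size / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)size * size);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      buf.clear();
      for (int di = -h; di <= h; ++di) {
        int ii = i + di;
        if (ii < 0) ii = -ii - 1;
        else if (ii >= nr) ii = 2 * nr - ii - 1;
        for (int dj = -h; dj <= h; ++dj) {
          int jj = j + dj;
          if (jj < 0) jj = -jj - 1;
          else if (jj >= nc) jj = 2 * nc - jj - 1;
          buf.push_back(img(ii, jj));
        }
      }
      const size_t m = buf.size() / 2; // window is odd^2, so this is the median
      std::nth_element(buf.begin(), buf.begin() + m, buf.end());
      out(i, j) = buf[m];
    }
  }
  return out;
}

namespace {
int uf_find(std::vector<int>& parent, int i) {
  int root = i;
  while (parent[root] != root) root = parent[root];
  while (parent[i] != root) { int nxt = parent[i]; parent[i] = root; i = nxt; }
  return root;
}
} // namespace

// Local maxima with topographic prominence, computed by persistence:
// pixels are processed in order of decreasing height and merged (union-find,
// 8-connectivity) into components, each owned by its highest pixel (the
// peak). When a component dies by merging into one with a higher peak at
// level v, the dying peak's prominence is peak height minus v -- exactly the
// drop required before reaching a higher pixel via any connected path.
// Plateaus join the component of an equal-valued earlier neighbour and do
// not spawn extra peaks. The global maximum has infinite prominence.
// Returns 1-based (row, col), peak height, prominence.
// [[Rcpp::export]]
DataFrame detect_peaks_cpp(NumericMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = nr * nc;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  const double* v = img.begin(); // column-major: id = i + nr * j
  std::stable_sort(ord.begin(), ord.end(), [v](int a, int b) {
    if (v[a] != v[b]) return v[a] > v[b];
    return a < b;
  });
  std::vector<int> parent(n, -1);       // -1 = not yet processed
  std::vector<int> peak_of(n, -1);      // root id -> id of its peak pixel
  std::vector<double> prom(n, -1.0);    // peak pixel id -> prominence
  std::vector<int> peaks;

  for (int k = 0; k < n; ++k) {
    const int p = ord[k];
    const int pi = p % nr, pj = p / nr;
    // roots of already-processed neighbours
    int best_root = -1;
    int nb_roots[8];
    int n_roots = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      const int jj = pj + dj;
      if (jj < 0 || jj >= nc) continue;
      for (int di = -1; di <= 1; ++di) {
        if (di == 0 && dj == 0) continue;
        const int ii = pi + di;
        if (ii < 0 || ii >= nr) continue;
        const int q = ii + nr * jj;
        if (parent[q] < 0) continue;
        const int r = uf_find(parent, q);
        bool seen = false;
        for (int t = 0; t < n_roots; ++t) if (nb_roots[t] == r) { seen = true; break; }
        if (!seen) nb_roots[n_roots++] = r;
      }
    }
    if (n_roots == 0) {
      parent[p] = p;
      peak_of[p] = p;
      peaks.push_back(p);
      continue;
    }
    for (int t = 0; t < n_roots; ++t) {
      if (best_root < 0 || v[peak_of[nb_roots[t]]] > v[peak_of[best_root]])
        best_root = nb_roots[t];
    }
    parent[p] = best_root;
    for (int t = 0; t < n_roots; ++t) {
      const int r = nb_roots[t];
      if (r == best_root) continue;
      // component r dies at level v[p]
      prom[peak_of[r]] = v[peak_of[r]] - v[p];
      parent[r] = best_root;
    }
  }

  const int np = (int)peaks.size();
  IntegerVector row(np), col(np);
  NumericVector height(np), prominence(np);
  for (int t = 0; t < np; ++t) {
    const int p = peaks[t];
    row[t] = p % nr + 1;
    col[t] = p / nr + 1;
    height[t] = v[p];
    prominence[t] = (prom[p] < 0) ? R_PosInf : prom[p];
  }
  return DataFrame::create(_["row"] = row, _["col"] = col,
                           _["height"] = height, _["prominence"] = prominence);
}

// Nearest-neighbour index for 2D points via a uniform grid of buckets,
// searching outward ring by ring until the ring's lower distance bound
// exceeds the best match. Exact; ties broken by lowest index.
// Returns 1-based indices (NA when n < 2).
// [[Rcpp::export]]
IntegerVector nn_index_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  IntegerVector res(n, NA_INTEGER);
  if (n < 2) return res;
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  const double w = std::max(xmax - xmin, 1e-12);
  const double h = std::max(ymax - ymin, 1e-12);
  // cap the grid at n cells per axis so degenerate (e.g. collinear)
  // configurations cannot blow up the ring search
  int ngx = std::max(1, std::min(n, (int)std::floor(std::sqrt((double)n * w / h))));
  int ngy = std::max(1, std::min(n, (int)std::floor(std::sqrt((double)n * h / w))));
  const double cx = w / ngx, cy = h / ngy;
  const double cmin = std::min(cx, cy);
  std::vector<std::vector<int> > cells((size_t)ngx * ngy);
  std::vector<int> gx(n), gy(n);
  for (int i = 0; i < n; ++i) {
    gx[i] = std::min(ngx - 1, (int)((x[i] - xmin) / cx));
    gy[i] = std::min(ngy - 1, (int)((y[i] - ymin) / cy));
    cells[(size_t)gx[i] + (size_t)ngx * gy[i]].push_back(i);
  }
  const int max_ring = ngx + ngy + 1;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bi = -1;
    for (int ring = 0; ring <= max_ring; ++ring) {
      if (bi >= 0 && (double)(ring - 1) * cmin > std::sqrt(best)) break;
      for (int dy = -ring; dy <= ring; ++dy) {
        const int yy = gy[i] + dy;
        if (yy < 0 || yy >= ngy) continue;
        for (int dx = -ring; dx <= ring; ++dx) {
          if (std::max(std::abs(dx), std::abs(dy)) != ring) continue;
          const int xx = gx[i] + dx;
          if (xx < 0 || xx >= ngx) continue;
          const std::vector<int>& cell = cells[(size_t)xx + (size_t)ngx * yy];
          for (size_t c = 0; c < cell.size(); ++c) {
            const int k = cell[c];
            if (k == i) continue;
            const double ddx = x[k] - x[i], ddy = y[k] - y[i];
            const double d2 = ddx * ddx + ddy * ddy;
            if (d2 < best || (d2 == best && k < bi)) { best = d2; bi = k; }
          }
        }
      }
    }
    res[i] = bi + 1;
  }
  return res;
}
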