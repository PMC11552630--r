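#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Integer background-noise fill: draws each pixel from the discrete
// distribution given by (vals, probs) -- the caller supplies the exact
// discretized (integer-rounded, range-clipped) Gaussian -- via Walker's
// alias method on R's RNG stream, so results are reproducible from
// set.seed() on the R side.
// [[Rcpp::export(name = ".noise_matrix")]]
IntegerMatrix noise_matrix(int nrow, int ncol, IntegerVector vals, NumericVector probs) {
  int k = vals.size();
  std::vector<double> prob(k);
  std::vector<int> alias(k);
  // Walker alias-table construction
  std::vector<double> scaled(k);
  std::vector<int> small, large;
  for (int i = 0; i < k; i++) {
    scaled[i] = probs[i] * k;
    (scaled[i] < 1.0 ? small : large).push_back(i);
  }
  while (!small.empty() && !large.empty()) {
    int s = small.back(); small.pop_back();
    int l = large.back(); large.pop_back();
    prob[s] = scaled[s];
    alias[s] = l;
    scaled[l] = (scaled[l] + scaled[s]) - 1.0;
    (scaled[l] < 1.0 ? small : large).push_back(l);
  }
  while (!large.empty()) { prob[large.back()] = 1.0; alias[large.back()] = large.back(); large.pop_back(); }
  while (!small.empty()) { prob[small.back()] = 1.0; alias[small.back()] = small.back(); small.pop_back(); }
  IntegerMatrix out(nrow, ncol);
  R_xlen_t n = (R_xlen_t)nrow * (R_xlen_t)ncol;
  for (R_xlen_t i = 0; i < n; i++) {
    double u = unif_rand() * k;
    int j = (int)u;
    if (j >= k) j = k - 1;
    out[i] = (u - j) < prob[j] ? vals[j] : vals[alias[j]];
  }
  return out;
}

// Paint filled ellipses (value = max(current, intensity)) into an integer
// image, in place; returns the rasterized pixel-count area of each ellipse.
// Centers/axes in pixel units, 1-based R row/col convention on entry is
// handled by the caller passing 0-based coordinates.
// [[Rcpp::export(name = ".render_ellipses")]]
IntegerVector render_ellipses(IntegerMatrix img, NumericVector cy, NumericVector cx,
                              NumericVector a, NumericVector b, NumericVector theta,
                              IntegerVector intensity) {
  int h = img.nrow(), w = img.ncol();
  int n = cy.size();
  IntegerVector area(n);
  for (int k = 0; k < n; k++) {
    double ct = std::cos(theta[k]), st = std::sin(theta[k]);
    int ext = (int)std::ceil(a[k]) + 1;
    int r0 = std::max(0, (int)std::floor(cy[k]) - ext);
    int r1 = std::min(h - 1, (int)std::ceil(cy[k]) + ext);
    int c0 = std::max(0, (int)std::floor(cx[k]) - ext);
    int c1 = std::min(w - 1, (int)std::ceil(cx[k]) + ext);
    int cnt = 0;
    for (int c = c0; c <= c1; c++) {
      double dx = c - cx[k];
      for (int r = r0; r <= r1; r++) {
        double dy = r - cy[k];
        double u = (dy * ct + dx * st) / a[k];
        double v = (-dy * st + dx * ct) / b[k];
        if (u * u + v * v <= 1.0) {
          cnt++;
          if (img(r, c) < intensity[k]) img(r, c) = intensity[k];
        }
      }
    }
    area[k] = cnt;
  }
  return area;
}

// Paint filled disks (foci) into an integer image, in place.
// [[Rcpp::export(name = ".render_disks")]]
void render_disks(IntegerMatrix img, NumericVector fy, NumericVector fx,
                  double radius, int intensity) {
  int h = img.nrow(), w = img.ncol();
  double r2 = radius * radius;
  int ext = (int)std::ceil(radius);
  for (int k = 0; k < fy.size(); k++) {
    int r0 = std::max(0, (int)std::floor(fy[k]) - ext);
    int r1 = std::min(h - 1, (int)std::ceil(fy[k]) + ext);
    int c0 = std::max(0, (int)std::floor(fx[k]) - ext);
    int c1 = std::min(w - 1, (int)std::ceil(fx[k]) + ext);
    for (int c = c0; c <= c1; c++) {
      double dx = c - fx[k];
      for (int r = r0; r <= r1; r++) {
        double dy = r - fy[k];
        if (dy * dy + dx * dx <= r2 && img(r, c) < intensity) img(r, c) = intensity;
      }
    }
  }
}

static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass connected-component labeling with union-find.
// connectivity is 4 or 8; labels are 1..K in first-encounter (column-major
// raster scan) order of the component's minimal provisional label.
// [[Rcpp::export(name = ".label_cc")]]
IntegerMatrix label_cc(IntegerMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // label 0 = background
  int next = 1;
  // column-major scan; neighbors already visited: (r-1,c), (r,c-1),
  // and for 8-connectivity (r-1,c-1), (r+1,c-1)
  for (int c = 0; c < nc; c++) {
    for (int r = 0; r < nr; r++) {
      if (mask(r, c) == 0) continue;
      int best = 0;
      int neigh[4] = {0, 0, 0, 0};
      int nn = 0;
      if (r > 0 && lab(r - 1, c) > 0) neigh[nn++] = lab(r - 1, c);
      if (c > 0 && lab(r, c - 1) > 0) neigh[nn++] = lab(r, c - 1);
      if (connectivity == 8 && c > 0) {
        if (r > 0 && lab(r - 1, c - 1) > 0) neigh[nn++] = lab(r - 1, c - 1);
        if (r + 1 < nr && lab(r + 1, c - 1) > 0) neigh[nn++] = lab(r + 1, c - 1);
      }
      for (int i = 0; i < nn; i++) {
        int root = uf_find(parent, neigh[i]);
        if (best == 0 || root < best) best = root;
      }
      if (best == 0) {
        parent.push_back(next);
        lab(r, c) = next++;
      } else {
        lab(r, c) = best;
        for (int i = 0; i < nn; i++) uf_union(parent, best, neigh[i]);
      }
    }
  }
  // second pass: resolve to roots, renumber compactly in scan order
  std::vector<int> newlab(parent.size(), 0);
  int k = 0;
  for (int c = 0; c < nc; c++) {
    for (int r = 0; r < nr; r++) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (newlab[root] == 0) newlab[root] = ++k;
      lab(r, c) = newlab[root];
    }
  }
  return lab;
}
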