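// Tolerance-based watershed flooding of a height map (typically a distance
// transform) restricted to a foreground mask.
//
// Voxels are processed in decreasing height (ties broken by linear index, so
// the result is fully deterministic). Each voxel joins the neighboring basin
// with the highest seed; neighboring basins whose seed rises less than
// `tolerance` above the contact height are merged into it (the h-maxima
// marker rule). Voxels where two surviving basins meet are flagged as
// boundary, and removing the flag set disconnects the basins under
// face connectivity.
//
// Works for 3D volumes and, with a singleton leading dimension, for 2D
// slices (26-connectivity then reduces to the in-plane 8-neighborhood).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export]]
List nsg_tol_watershed(NumericVector height, IntegerVector mask,
                       IntegerVector dims, double tolerance) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int N = Z * Y * X;
  if ((int)height.size() != N || (int)mask.size() != N)
    stop("watershed: length/dims mismatch");
  std::vector<int> fg;
  fg.reserve(N);
  for (int i = 0; i < N; ++i) if (mask[i] != 0) fg.push_back(i);
  std::stable_sort(fg.begin(), fg.end(), [&](int a, int b) {
    if (height[a] != height[b]) return height[a] > height[b];
    return a < b;
  });
  std::vector<int> lab(N, 0);          // provisional label per voxel (1-based)
  std::vector<int> parent;             // union-find over labels (0 unused)
  std::vector<double> seed_h;          // seed height per label
  parent.push_back(0);
  seed_h.push_back(0);
  LogicalVector boundary(N, false);
  std::vector<int> roots;
  roots.reserve(26);
  for (int v : fg) {
    const int z = v % Z, y = (v / Z) % Y, x = v / (Z * Y);
    roots.clear();
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          if (!dz && !dy && !dx) continue;
          const int z2 = z + dz, y2 = y + dy, x2 = x + dx;
          if (z2 < 0 || z2 >= Z || y2 < 0 || y2 >= Y || x2 < 0 || x2 >= X)
            continue;
          const int n = z2 + Z * (y2 + Y * x2);
          if (lab[n] == 0) continue;
          const int r = find_root(parent, lab[n]);
          bool seen = false;
          for (int rr : roots) if (rr == r) { seen = true; break; }
          if (!seen) roots.push_back(r);
        }
    if (roots.empty()) {
      const int nl = (int)parent.size();
      parent.push_back(nl);
      seed_h.push_back(height[v]);
      lab[v] = nl;
      continue;
    }
    // basin with the highest seed wins; ties to the oldest (smallest id)
    int best = roots[0];
    for (int r : roots)
      if (seed_h[r] > seed_h[best] || (seed_h[r] == seed_h[best] && r < best))
        best = r;
    int survivors = 0;
    for (int r : roots) {
      if (r == best) { ++survivors; continue; }
      if (seed_h[r] - height[v] < tolerance) {
        parent[r] = best;               // shallow basin: merge (h-maxima rule)
      } else {
        ++survivors;
      }
    }
    if (survivors > 1) {
      // watershed line: flag, leave unlabeled, and do not propagate, so the
      // line stays one voxel thin instead of marching into the losing basin
      boundary[v] = true;
    } else {
      lab[v] = best;
    }
  }
  // compress to final labels in raster-scan order of first occurrence
  std::vector<int> remap(parent.size(), 0);
  IntegerVector out(N, 0);
  int next = 0;
  for (int i = 0; i < N; ++i) {
    if (lab[i] == 0) continue;
    const int r = find_root(parent, lab[i]);
    if (remap[r] == 0) remap[r] = ++next;
    out[i] = remap[r];
  }
  out.attr("dim") = dims;
  boundary.attr("dim") = dims;
  return List::create(_["label"] = out, _["boundary"] = boundary,
                      _["n_basins"] = next);
}
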