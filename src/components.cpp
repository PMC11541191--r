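#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Union-find with path compression
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Connected-component labelling of a 3D (z, y, x) logical array stored in
// column-major order (z fastest). connectivity: 26 (3D) or 6 (3D faces);
// with nz == 1 the same code yields 8- or 4-connectivity in 2D.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (mask.size() != n) stop("mask length does not match dims");
  if (connectivity != 26 && connectivity != 6)
    stop("connectivity must be 6 or 26");

  IntegerVector labels(n, 0);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 1;

  // First pass: scan in storage order, look at already-visited neighbours
  // (those with a smaller linear index).
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        R_xlen_t idx = (R_xlen_t)z + (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        if (!mask[idx]) continue;
        int best = 0;
        std::vector<int> nbr;
        for (int dx = -1; dx <= 0; ++dx) {
          int xx = x + dx;
          if (xx < 0) continue;
          for (int dy = -1; dy <= 1; ++dy) {
            int yy = y + dy;
            if (yy < 0 || yy >= ny) continue;
            for (int dz = -1; dz <= 1; ++dz) {
              int zz = z + dz;
              if (zz < 0 || zz >= nz) continue;
              // only previously visited voxels
              if (dx == 0 && (dy > 0 || (dy == 0 && dz >= 0))) continue;
              int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
              if (connectivity == 6 && manh != 1) continue;
              R_xlen_t j = (R_xlen_t)zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
              if (mask[j]) nbr.push_back(labels[j]);
            }
          }
        }
        if (nbr.empty()) {
          parent.push_back(next);
          labels[idx] = next;
          ++next;
        } else {
          best = nbr[0];
          for (size_t k = 1; k < nbr.size(); ++k)
            best = std::min(best, nbr[k]);
          labels[idx] = best;
          for (size_t k = 0; k < nbr.size(); ++k)
            uf_union(parent, best, nbr[k]);
        }
      }
    }
  }

  // Second pass: resolve equivalences and renumber densely.
  std::vector<int> remap(next, 0);
  int nlab = 0;
  for (int i = 1; i < next; ++i) {
    int r = uf_find(parent, i);
    if (remap[r] == 0) remap[r] = ++nlab;
    remap[i] = remap[r];
  }
  for (R_xlen_t i = 0; i < n; ++i)
    if (labels[i] > 0) labels[i] = remap[labels[i]];

  labels.attr("n_labels") = nlab;
  return labels;
}
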