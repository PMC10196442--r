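// DBSCAN over foreground voxels of a 3D label volume.
//
// Points are the integer voxel coordinates of all nonzero voxels; the
// eps-neighborhood is the Euclidean ball realised as a fixed offset stencil
// on the lattice, so neighbor queries are O(|ball|) per voxel. Traversal is
// in ascending linear-index order, which makes the labeling deterministic
// and independent of how the mask was produced.

#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Returns an integer array of the same shape: 0 background, -1 noise,
// 1..K cluster ids. A voxel is a core point when the number of foreground
// voxels within distance eps (the voxel itself included) is >= min_samples.
// [[Rcpp::export(rng = false)]]
IntegerVector dbscan_voxels_cpp(NumericVector mask, IntegerVector mdim,
                                double eps, int min_samples) {
  const int X = mdim[0], Y = mdim[1], Z = mdim[2];
  const R_xlen_t N = (R_xlen_t)X * Y * Z;
  const R_xlen_t XY = (R_xlen_t)X * Y;

  // offset stencil: all lattice offsets with |o| <= eps, including self
  const int r = (int)std::floor(eps);
  std::vector<int> odx, ody, odz;
  std::vector<R_xlen_t> olin;
  for (int dz = -r; dz <= r; ++dz)
    for (int dy = -r; dy <= r; ++dy)
      for (int dx = -r; dx <= r; ++dx)
        if (dx * dx + dy * dy + dz * dz <= eps * eps) {
          odx.push_back(dx); ody.push_back(dy); odz.push_back(dz);
          olin.push_back(dx + (R_xlen_t)X * dy + XY * dz);
        }
  const int nOff = (int)odx.size();

  const double* m = mask.begin();
  IntegerVector lab(N); // 0 = background
  std::vector<char> fore(N, 0);
  for (R_xlen_t i = 0; i < N; ++i) fore[i] = m[i] != 0;

  const int UNSEEN = 0, NOISE = -1;
  int nclust = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < N; ++i) {
    if (!fore[i] || lab[i] != UNSEEN) continue;
    const int x0 = (int)(i % X), y0 = (int)((i / X) % Y), z0 = (int)(i / XY);
    // neighbor count for the seed
    int cnt = 0;
    for (int o = 0; o < nOff; ++o) {
      const int x = x0 + odx[o], y = y0 + ody[o], z = z0 + odz[o];
      if (x < 0 || x >= X || y < 0 || y >= Y || z < 0 || z >= Z) continue;
      if (fore[i + olin[o]]) ++cnt;
    }
    if (cnt < min_samples) { lab[i] = NOISE; continue; }
    ++nclust;
    lab[i] = nclust;
    q.push(i);
    while (!q.empty()) {
      const R_xlen_t p = q.front(); q.pop();
      const int px = (int)(p % X), py = (int)((p / X) % Y), pz = (int)(p / XY);
      // p is known core: expand its neighborhood
      int pcnt = 0;
      std::vector<R_xlen_t> nb;
      nb.reserve(nOff);
      for (int o = 0; o < nOff; ++o) {
        const int x = px + odx[o], y = py + ody[o], z = pz + odz[o];
        if (x < 0 || x >= X || y < 0 || y >= Y || z < 0 || z >= Z) continue;
        const R_xlen_t j = p + olin[o];
        if (fore[j]) { ++pcnt; nb.push_back(j); }
      }
      if (pcnt < min_samples) continue; // border point: claimed, not expanded
      for (R_xlen_t j : nb) {
        if (lab[j] == UNSEEN || lab[j] == NOISE) {
          const bool was_unseen = lab[j] == UNSEEN;
          lab[j] = nclust;
          if (was_unseen) q.push(j);
        }
      }
    }
  }
  lab.attr("dim") = mdim;
  return lab;
}
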