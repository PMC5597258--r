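#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// 3-D curve thinning by sequential deletion of simple border points.
//
// A foreground voxel is *simple* (its deletion preserves local topology) iff
//  (A) its foreground 26-neighbours form exactly one 26-connected component, and
//  (B) the background voxels among its 18 face/edge neighbours form exactly one
//      6-connected component that is 6-adjacent to the voxel
// (Bertrand & Malandain characterisation). Endpoints (<= 1 foreground
// 26-neighbour) are preserved so strand ends are not eroded. Voxels are
// visited in ascending linear (lexicographic) order and deleted immediately,
// so the result is deterministic.

namespace {

int off[26][3];      // the 26 neighbour offsets
bool adj26[26][26];  // 26-adjacency between neighbour positions
bool adj6[26][26];   // 6-adjacency between neighbour positions
bool in18[26];       // face or edge neighbour (not corner)
bool face6[26];      // face neighbour (6-adjacent to centre)
bool tables_ready = false;

void build_tables() {
  if (tables_ready) return;
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        off[n][0] = dx; off[n][1] = dy; off[n][2] = dz;
        int a = std::abs(dx) + std::abs(dy) + std::abs(dz);
        in18[n] = (a <= 2);
        face6[n] = (a == 1);
        ++n;
      }
  for (int i = 0; i < 26; ++i)
    for (int j = 0; j < 26; ++j) {
      int dx = off[i][0] - off[j][0];
      int dy = off[i][1] - off[j][1];
      int dz = off[i][2] - off[j][2];
      int m = std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz)));
      int a = std::abs(dx) + std::abs(dy) + std::abs(dz);
      adj26[i][j] = (i != j) && (m == 1);
      adj6[i][j] = (a == 1);
    }
  tables_ready = true;
}

inline bool is_simple(const bool nb[26]) {
  // (A) one 26-component of foreground neighbours
  int seen[26]; bool vis[26] = {false};
  int ncomp = 0, nfg = 0;
  for (int i = 0; i < 26; ++i) if (nb[i]) ++nfg;
  if (nfg == 0) return false;
  for (int i = 0; i < 26; ++i) {
    if (!nb[i] || vis[i]) continue;
    if (++ncomp > 1) return false;
    int top = 0; seen[top++] = i; vis[i] = true;
    while (top) {
      int c = seen[--top];
      for (int j = 0; j < 26; ++j)
        if (nb[j] && !vis[j] && adj26[c][j]) { vis[j] = true; seen[top++] = j; }
    }
  }
  if (ncomp != 1) return false;
  // (B) one 6-component of background within N18 touching a face neighbour
  bool bg[26];
  for (int i = 0; i < 26; ++i) bg[i] = in18[i] && !nb[i];
  bool vis2[26] = {false};
  int ncomp6 = 0;
  for (int i = 0; i < 26; ++i) {
    if (!bg[i] || vis2[i] || !face6[i]) continue;
    ++ncomp6;
    if (ncomp6 > 1) return false;
    int top = 0; seen[top++] = i; vis2[i] = true;
    while (top) {
      int c = seen[--top];
      for (int j = 0; j < 26; ++j)
        if (bg[j] && !vis2[j] && adj6[c][j]) { vis2[j] = true; seen[top++] = j; }
    }
  }
  return ncomp6 == 1;
}

} // namespace

// [[Rcpp::export]]
LogicalVector skeletonize3d_cpp(LogicalVector mask, IntegerVector dims) {
  build_tables();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  if (mask.size() != nvox) stop("mask length does not match dims");
  std::vector<char> fg(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) fg[i] = mask[i] ? 1 : 0;

  auto at = [&](int x, int y, int z) -> char {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return 0;
    return fg[(R_xlen_t)x + nx * ((R_xlen_t)y + (R_xlen_t)ny * z)];
  };

  bool changed = true;
  while (changed) {
    changed = false;
    R_xlen_t idx = 0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x, ++idx) {
          if (!fg[idx]) continue;
          // border: some face neighbour is background (incl. out of bounds)
          if (at(x - 1, y, z) && at(x + 1, y, z) && at(x, y - 1, z) &&
              at(x, y + 1, z) && at(x, y, z - 1) && at(x, y, z + 1))
            continue;
          bool nb[26];
          int nfg = 0;
          for (int i = 0; i < 26; ++i) {
            nb[i] = at(x + off[i][0], y + off[i][1], z + off[i][2]);
            if (nb[i]) ++nfg;
          }
          if (nfg <= 1) continue;  // endpoint: keep
          if (is_simple(nb)) {
            fg[idx] = 0;
            changed = true;
          }
        }
  }

  LogicalVector out(nvox);
  for (R_xlen_t i = 0; i < nvox; ++i) out[i] = fg[i] != 0;
  out.attr("dim") = dims;
  return out;
}
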