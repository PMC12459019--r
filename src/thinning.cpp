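#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Homotopy-preserving 3-D thinning of a binary volume to one-voxel-wide
// centerlines. A border voxel may be deleted only if it is a simple point
// in the (26, 6) adjacency pair — deletion then leaves both the object's
// 26-topology and the background's 6-topology unchanged (topological
// numbers T26 = 1 and T6 = 1, Bertrand & Malandain characterization) —
// and is not a curve endpoint (<= 1 object 26-neighbour). Deletion is
// sequential within six directional subiterations (U/D/N/S/E/W) so the
// result is deterministic and well-centered; iteration stops when a full
// cycle removes nothing.

namespace {

// offsets of the 26-neighbourhood, fixed enumeration order
struct N26 {
  int d[26][3];
  int idx[3][3][3]; // (di+1, dj+1, dk+1) -> neighbour index, center = -1
  N26() {
    int c = 0;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (!di && !dj && !dk) { idx[di + 1][dj + 1][dk + 1] = -1; continue; }
          d[c][0] = di; d[c][1] = dj; d[c][2] = dk;
          idx[di + 1][dj + 1][dk + 1] = c;
          ++c;
        }
  }
};
const N26 NB;

// number of 26-connected components of the object restricted to N26(p)
int t26(const bool nb[26]) {
  int comp = 0;
  bool seen[26] = {false};
  int stack[26];
  for (int s = 0; s < 26; ++s) {
    if (!nb[s] || seen[s]) continue;
    ++comp;
    int top = 0;
    stack[top++] = s; seen[s] = true;
    while (top) {
      int u = stack[--top];
      for (int v = 0; v < 26; ++v) {
        if (!nb[v] || seen[v]) continue;
        if (std::abs(NB.d[u][0] - NB.d[v][0]) <= 1 &&
            std::abs(NB.d[u][1] - NB.d[v][1]) <= 1 &&
            std::abs(NB.d[u][2] - NB.d[v][2]) <= 1) {
          seen[v] = true; stack[top++] = v;
        }
      }
    }
  }
  return comp;
}

// number of 6-connected components of the background restricted to the
// 18-neighbourhood, counting only components 6-adjacent to the center
int t6(const bool nb[26]) {
  // positions in N18: at most two nonzero offsets
  bool in18[26], bg[26];
  for (int s = 0; s < 26; ++s) {
    int nz = (NB.d[s][0] != 0) + (NB.d[s][1] != 0) + (NB.d[s][2] != 0);
    in18[s] = nz <= 2;
    bg[s] = in18[s] && !nb[s];
  }
  int comp = 0;
  bool seen[26] = {false};
  int stack[26];
  for (int s = 0; s < 26; ++s) {
    if (!bg[s] || seen[s]) continue;
    int nz = (NB.d[s][0] != 0) + (NB.d[s][1] != 0) + (NB.d[s][2] != 0);
    if (nz != 1) continue; // seed only from face neighbours of p
    ++comp;
    int top = 0;
    stack[top++] = s; seen[s] = true;
    while (top) {
      int u = stack[--top];
      for (int v = 0; v < 26; ++v) {
        if (!bg[v] || seen[v]) continue;
        int dd = std::abs(NB.d[u][0] - NB.d[v][0]) +
                 std::abs(NB.d[u][1] - NB.d[v][1]) +
                 std::abs(NB.d[u][2] - NB.d[v][2]);
        if (dd == 1) { seen[v] = true; stack[top++] = v; }
      }
    }
  }
  return comp;
}

} // namespace

// [[Rcpp::export]]
IntegerVector thin3(IntegerVector vol, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  IntegerVector img = clone(vol);
  auto at = [&](int i, int j, int k) -> int& {
    return img[i + (size_t)n1 * (j + (size_t)n2 * k)];
  };
  auto inb = [&](int i, int j, int k) {
    return i >= 0 && i < n1 && j >= 0 && j < n2 && k >= 0 && k < n3;
  };
  auto neighbours = [&](int i, int j, int k, bool nb[26]) {
    int cnt = 0;
    for (int s = 0; s < 26; ++s) {
      int ii = i + NB.d[s][0], jj = j + NB.d[s][1], kk = k + NB.d[s][2];
      nb[s] = inb(ii, jj, kk) && at(ii, jj, kk) != 0;
      cnt += nb[s];
    }
    return cnt;
  };
  // six deletion directions: the face neighbour that must be background
  const int dirs[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      // collection pass: border points in direction d that are simple and
      // not endpoints *before* this subiteration touches anything
      std::vector<size_t> cand;
      for (int k = 0; k < n3; ++k)
        for (int j = 0; j < n2; ++j)
          for (int i = 0; i < n1; ++i) {
            if (!at(i, j, k)) continue;
            int ii = i + dirs[d][0], jj = j + dirs[d][1], kk = k + dirs[d][2];
            bool open_side = !inb(ii, jj, kk) || !at(ii, jj, kk);
            if (!open_side) continue;
            bool nb[26];
            int cnt = neighbours(i, j, k, nb);
            if (cnt <= 1) continue;
            if (t26(nb) != 1 || t6(nb) != 1) continue;
            cand.push_back(i + (size_t)n1 * (j + (size_t)n2 * k));
          }
      // deletion pass: sequential recheck so each deletion stays simple
      for (size_t p : cand) {
        if (!img[p]) continue;
        int i = p % n1, j = (p / n1) % n2, k = p / ((size_t)n1 * n2);
        bool nb[26];
        int cnt = neighbours(i, j, k, nb);
        if (cnt <= 1) continue;              // became an endpoint: keep
        if (t26(nb) != 1 || t6(nb) != 1) continue; // no longer simple
        img[p] = 0;
        changed = true;
      }
    }
  }
  return img;
}
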