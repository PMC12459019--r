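#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Connected-component labeling of a binary 3-D volume at 26-connectivity.
// Returns an integer volume with labels 1..n_components (0 = background).
// [[Rcpp::export]]
IntegerVector label_components26(IntegerVector vol, IntegerVector dim) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const size_t total = (size_t)n1 * n2 * n3;
  IntegerVector lab(vol.size());
  std::vector<size_t> stack;
  int next = 0;
  for (size_t p0 = 0; p0 < total; ++p0) {
    if (!vol[p0] || lab[p0]) continue;
    ++next;
    lab[p0] = next;
    stack.clear();
    stack.push_back(p0);
    while (!stack.empty()) {
      size_t p = stack.back(); stack.pop_back();
      int i = p % n1, j = (p / n1) % n2, k = p / ((size_t)n1 * n2);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
              continue;
            size_t q = ii + (size_t)n1 * (jj + (size_t)n2 * kk);
            if (vol[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
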