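#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// Best-first limited region growing over 4-neighbours.
//
// Bands 1-2 (density, height) are numeric on a common [0,1] scale; band 3 is
// a categorical class label whose dissimilarity to a region is
// 1 - (fraction of the region's pixels sharing the pixel's class).
// Dissimilarity of pixel p to region R:
//   d = w1*|b1(p) - mean1(R)| + w2*|b2(p) - mean2(R)| + w3*(1 - f_class(R))
// At every step the globally best frontier pair (smallest d, then smallest
// region id, then row-major pixel order) is annexed iff d <= bound.
//
// A region's statistics change only when it annexes a pixel, so the heap
// holds one current entry per (pixel, region) frontier pair, re-keyed for
// the pairs of the annexing region only; stale entries are recognized by a
// per-region version stamp and skipped. This reproduces exactly the naive
// scan that re-evaluates every frontier pair at every step.

struct Entry {
  double d;
  int reg;
  long rm;      // row-major pixel order, tie-break after region id
  int idx;
  int ver;      // region version at push time
};
struct EntryCmp {
  bool operator()(const Entry& a, const Entry& b) const {
    if (a.d != b.d) return a.d > b.d;
    if (a.reg != b.reg) return a.reg > b.reg;
    return a.rm > b.rm;
  }
};

// [[Rcpp::export]]
IntegerMatrix rg_grow_cpp(NumericMatrix band1, NumericMatrix band2,
                          IntegerMatrix cls, LogicalMatrix valid,
                          IntegerMatrix labels_in, NumericVector w,
                          double bound, int n_regions, int max_class) {
  const int nr = band1.nrow(), nc = band1.ncol(), npix = nr * nc;
  IntegerMatrix labels = clone(labels_in);
  const double w1 = w[0], w2 = w[1], w3 = w[2];

  std::vector<double> n(n_regions + 1, 0.0), s1(n_regions + 1, 0.0),
      s2(n_regions + 1, 0.0);
  std::vector<std::vector<double> > ccnt(
      n_regions + 1, std::vector<double>(max_class + 1, 0.0));
  std::vector<int> ver(n_regions + 1, 0);
  std::vector<std::vector<int> > rfront(n_regions + 1);
  for (int i = 0; i < npix; ++i) {
    int lab = labels[i];
    if (lab > 0) {
      n[lab] += 1.0; s1[lab] += band1[i]; s2[lab] += band2[i];
      ccnt[lab][cls[i]] += 1.0;
    }
  }

  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  auto neighbour = [&](int idx, int k) -> int {
    int r = idx % nr, c = idx / nr;
    int r2 = r + dr[k], c2 = c + dc[k];
    if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) return -1;
    return c2 * nr + r2;
  };
  auto dissim = [&](int idx, int reg) -> double {
    return w1 * std::abs(band1[idx] - s1[reg] / n[reg]) +
           w2 * std::abs(band2[idx] - s2[reg] / n[reg]) +
           w3 * (1.0 - ccnt[reg][cls[idx]] / n[reg]);
  };
  std::priority_queue<Entry, std::vector<Entry>, EntryCmp> heap;
  auto push_pair = [&](int idx, int reg) {
    int r = idx % nr, c = idx / nr;
    Entry e = {dissim(idx, reg), reg, (long)r * nc + c, idx, ver[reg]};
    heap.push(e);
    rfront[reg].push_back(idx);
  };

  // initial frontier: unlabeled valid pixels adjacent to labeled ones,
  // one entry per distinct adjacent region
  for (int i = 0; i < npix; ++i) {
    if (!valid[i] || labels[i] != 0) continue;
    int seen[4]; int nseen = 0;
    for (int k = 0; k < 4; ++k) {
      int nb = neighbour(i, k);
      if (nb < 0 || labels[nb] <= 0) continue;
      int reg = labels[nb];
      bool dup = false;
      for (int t = 0; t < nseen; ++t) if (seen[t] == reg) { dup = true; break; }
      if (!dup) { seen[nseen++] = reg; push_pair(i, reg); }
    }
  }

  while (!heap.empty()) {
    Entry e = heap.top();
    heap.pop();
    if (labels[e.idx] != 0 || ver[e.reg] != e.ver) continue;  // stale
    if (e.d > bound) break;                 // current global minimum too far
    const int reg = e.reg;
    labels[e.idx] = reg;
    n[reg] += 1.0; s1[reg] += band1[e.idx]; s2[reg] += band2[e.idx];
    ccnt[reg][cls[e.idx]] += 1.0;
    ver[reg] += 1;
    // re-key surviving frontier pairs of this region, add new neighbours
    std::vector<int> old;
    old.swap(rfront[reg]);
    for (size_t k = 0; k < old.size(); ++k) {
      int p = old[k];
      if (labels[p] != 0) continue;
      bool adj = false;
      for (int q = 0; q < 4; ++q) {
        int nb = neighbour(p, q);
        if (nb >= 0 && labels[nb] == reg) { adj = true; break; }
      }
      if (adj) push_pair(p, reg);
    }
    for (int q = 0; q < 4; ++q) {
      int nb = neighbour(e.idx, q);
      if (nb < 0 || !valid[nb] || labels[nb] != 0) continue;
      // new pair unless the pixel was already adjacent to reg (then it was
      // just re-keyed above via old)
      bool had = false;
      for (size_t k = 0; k < rfront[reg].size(); ++k)
        if (rfront[reg][k] == nb) { had = true; break; }
      if (!had) push_pair(nb, reg);
    }
  }
  return labels;
}
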