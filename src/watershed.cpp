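#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

struct NeighW {
  std::vector<int> di, dj, dk;
};

static NeighW make_neigh_w(int connectivity) {
  NeighW nb;
  for (int a = -1; a <= 1; a++)
    for (int b = -1; b <= 1; b++)
      for (int c = -1; c <= 1; c++) {
        int m = std::abs(a) + std::abs(b) + std::abs(c);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        nb.di.push_back(a);
        nb.dj.push_back(b);
        nb.dk.push_back(c);
      }
  return nb;
}

// Grayscale reconstruction by dilation of `marker` under `mask` (marker <=
// mask everywhere), hybrid raster/queue algorithm (Vincent 1993). Used for
// the h-maxima suppression of shallow distance-map maxima before watershed.
// [[Rcpp::export]]
NumericVector cpp_reconstruct(NumericVector marker, NumericVector mask,
                              IntegerVector dim, int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NeighW nb = make_neigh_w(connectivity);
  const int nn = (int)nb.di.size();
  NumericVector J(n);
  for (R_xlen_t s = 0; s < n; s++) J[s] = std::min(marker[s], mask[s]);

  // split neighborhood into "before" (negative raster offset) and "after"
  std::vector<int> befi, befj, befk, afti, aftj, aftk;
  for (int t = 0; t < nn; t++) {
    R_xlen_t off = nb.di[t] + (R_xlen_t)d1 * (nb.dj[t] + (R_xlen_t)d2 * nb.dk[t]);
    if (off < 0) { befi.push_back(nb.di[t]); befj.push_back(nb.dj[t]); befk.push_back(nb.dk[t]); }
    else { afti.push_back(nb.di[t]); aftj.push_back(nb.dj[t]); aftk.push_back(nb.dk[t]); }
  }

  // forward raster sweep
  R_xlen_t idx = 0;
  for (int k = 0; k < d3; k++)
    for (int j = 0; j < d2; j++)
      for (int i = 0; i < d1; i++, idx++) {
        double m = J[idx];
        for (size_t t = 0; t < befi.size(); t++) {
          int ii = i + befi[t], jj = j + befj[t], kk = k + befk[t];
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
          R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
          if (J[q] > m) m = J[q];
        }
        if (m > mask[idx]) m = mask[idx];
        J[idx] = m;
      }

  // backward raster sweep + queue seeding
  std::queue<R_xlen_t> fifo;
  idx = n - 1;
  for (int k = d3 - 1; k >= 0; k--)
    for (int j = d2 - 1; j >= 0; j--)
      for (int i = d1 - 1; i >= 0; i--, idx--) {
        double m = J[idx];
        for (size_t t = 0; t < afti.size(); t++) {
          int ii = i + afti[t], jj = j + aftj[t], kk = k + aftk[t];
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
          R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
          if (J[q] > m) m = J[q];
        }
        if (m > mask[idx]) m = mask[idx];
        J[idx] = m;
        for (size_t t = 0; t < afti.size(); t++) {
          int ii = i + afti[t], jj = j + aftj[t], kk = k + aftk[t];
          if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
          R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
          if (J[q] < J[idx] && J[q] < mask[q]) {
            fifo.push(idx);
            break;
          }
        }
      }

  while (!fifo.empty()) {
    R_xlen_t p = fifo.front();
    fifo.pop();
    int i = (int)(p % d1);
    int j = (int)((p / d1) % d2);
    int k = (int)(p / ((R_xlen_t)d1 * d2));
    for (int t = 0; t < nn; t++) {
      int ii = i + nb.di[t], jj = j + nb.dj[t], kk = k + nb.dk[t];
      if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
      R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
      if (J[q] < J[p] && mask[q] != J[q]) {
        double v = std::min(J[p], mask[q]);
        if (v > J[q]) {
          J[q] = v;
          fifo.push(q);
        }
      }
    }
  }
  return J;
}

// Regional maxima of img restricted to mask: connected plateaus of constant
// value with no higher neighbor inside the mask. Out-of-mask neighbors are
// ignored. Plateaus are labeled 1..K in raster discovery order.
// [[Rcpp::export]]
IntegerVector cpp_regional_maxima(NumericVector img, LogicalVector mask,
                                  IntegerVector dim, int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NeighW nb = make_neigh_w(connectivity);
  const int nn = (int)nb.di.size();
  IntegerVector lab(n, 0);
  std::vector<signed char> state(n, 0); // 0 unvisited, 1 visited
  std::vector<R_xlen_t> plateau;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || state[s]) continue;
    double v0 = img[s];
    bool isMax = true;
    plateau.clear();
    plateau.push_back(s);
    state[s] = 1;
    size_t head = 0;
    while (head < plateau.size()) {
      R_xlen_t p = plateau[head++];
      int i = (int)(p % d1);
      int j = (int)((p / d1) % d2);
      int k = (int)(p / ((R_xlen_t)d1 * d2));
      for (int t = 0; t < nn; t++) {
        int ii = i + nb.di[t], jj = j + nb.dj[t], kk = k + nb.dk[t];
        if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
        R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
        if (!mask[q]) continue;
        if (img[q] > v0) isMax = false;
        else if (img[q] == v0 && !state[q]) {
          state[q] = 1;
          plateau.push_back(q);
        }
      }
    }
    if (isMax) {
      next++;
      for (size_t t = 0; t < plateau.size(); t++) lab[plateau[t]] = next;
    }
  }
  return lab;
}

// Marker-based watershed by priority flooding of the distance map (highest
// distance first). Ties are broken first-in-first-out, so the result is
// deterministic for identical inputs. Every mask voxel reachable from a
// marker through the mask receives a label.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector dist, IntegerVector markers,
                            LogicalVector mask, IntegerVector dim,
                            int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  NeighW nb = make_neigh_w(connectivity);
  const int nn = (int)nb.di.size();
  IntegerVector lab(n, 0);

  typedef std::pair<double, std::pair<long long, R_xlen_t> > Item;
  // priority: largest dist first; among equal dist, smallest insertion seq
  struct Cmp {
    bool operator()(const Item& a, const Item& b) const {
      if (a.first != b.first) return a.first < b.first;
      return a.second.first > b.second.first;
    }
  };
  std::priority_queue<Item, std::vector<Item>, Cmp> pq;
  long long seq = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (markers[s] > 0 && mask[s]) {
      lab[s] = markers[s];
      pq.push(Item(dist[s], std::make_pair(seq++, s)));
    }
  }
  while (!pq.empty()) {
    R_xlen_t p = pq.top().second.second;
    pq.pop();
    int i = (int)(p % d1);
    int j = (int)((p / d1) % d2);
    int k = (int)(p / ((R_xlen_t)d1 * d2));
    for (int t = 0; t < nn; t++) {
      int ii = i + nb.di[t], jj = j + nb.dj[t], kk = k + nb.dk[t];
      if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
      R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
      if (mask[q] && lab[q] == 0) {
        lab[q] = lab[p];
        pq.push(Item(dist[q], std::make_pair(seq++, q)));
      }
    }
  }
  return lab;
}
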