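#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Neighbor offset machinery shared by the flood-fill style operations.
// Offsets are (di,dj,dk) triples filtered by connectivity 6/18/26.

struct Neigh {
  std::vector<int> di, dj, dk;
};

static Neigh make_neigh(int connectivity) {
  Neigh nb;
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

// Connected-component labeling of a 3D logical mask. Components are numbered
// 1..K in raster-scan discovery order, which makes labels deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  Neigh nb = make_neigh(connectivity);
  const int nn = (int)nb.di.size();
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> queue;
  int next = 0;
  for (R_xlen_t s = 0; s < n; s++) {
    if (!mask[s] || lab[s] != 0) continue;
    next++;
    lab[s] = next;
    queue.clear();
    queue.push_back(s);
    size_t head = 0;
    while (head < queue.size()) {
      R_xlen_t p = queue[head++];
      int i = (int)(p % d1);
      int j = (int)((p / d1) % d2);
      int k = (int)(p / ((R_xlen_t)d1 * d2));
      for (int t = 0; t < nn; t++) {
        int ii = i + nb.di[t], jj = j + nb.dj[t], kk = k + nb.dk[t];
        if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
        R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          queue.push_back(q);
        }
      }
    }
  }
  return lab;
}

// Hysteresis selection: keep weak voxels connected (through weak voxels)
// to at least one strong voxel. strong is assumed to be a subset of weak.
// [[Rcpp::export]]
LogicalVector cpp_hysteresis(LogicalVector weak, LogicalVector strong,
                             IntegerVector dim, int connectivity) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  Neigh nb = make_neigh(connectivity);
  const int nn = (int)nb.di.size();
  LogicalVector out(n, false);
  std::vector<R_xlen_t> queue;
  for (R_xlen_t s = 0; s < n; s++) {
    if (strong[s] && weak[s] && !out[s]) {
      out[s] = true;
      queue.push_back(s);
    }
  }
  size_t head = 0;
  while (head < queue.size()) {
    R_xlen_t p = queue[head++];
    int i = (int)(p % d1);
    int j = (int)((p / d1) % d2);
    int k = (int)(p / ((R_xlen_t)d1 * d2));
    for (int t = 0; t < nn; t++) {
      int ii = i + nb.di[t], jj = j + nb.dj[t], kk = k + nb.dk[t];
      if (ii < 0 || ii >= d1 || jj < 0 || jj >= d2 || kk < 0 || kk >= d3) continue;
      R_xlen_t q = ii + (R_xlen_t)d1 * (jj + (R_xlen_t)d2 * kk);
      if (weak[q] && !out[q]) {
        out[q] = true;
        queue.push_back(q);
      }
    }
  }
  return out;
}

// Per-label voxel count, max of an auxiliary field, sum of coordinates
// (for centroids) and bounding boxes, in one pass. labels: 0 = background.
// [[Rcpp::export]]
List cpp_region_stats(IntegerVector labels, NumericVector aux, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = (R_xlen_t)d1 * d2 * d3;
  int K = 0;
  for (R_xlen_t s = 0; s < n; s++)
    if (labels[s] > K) K = labels[s];
  NumericVector cnt(K), mx(K), s1(K), s2(K), s3(K);
  IntegerVector lo1(K), hi1(K), lo2(K), hi2(K), lo3(K), hi3(K);
  for (int g = 0; g < K; g++) {
    mx[g] = R_NegInf;
    lo1[g] = d1; lo2[g] = d2; lo3[g] = d3;
    hi1[g] = -1; hi2[g] = -1; hi3[g] = -1;
  }
  const bool haveAux = aux.size() == n;
  R_xlen_t idx = 0;
  for (int k = 0; k < d3; k++)
    for (int j = 0; j < d2; j++)
      for (int i = 0; i < d1; i++, idx++) {
        int L = labels[idx];
        if (L <= 0) continue;
        int g = L - 1;
        cnt[g] += 1;
        s1[g] += i; s2[g] += j; s3[g] += k;
        if (i < lo1[g]) lo1[g] = i;
        if (i > hi1[g]) hi1[g] = i;
        if (j < lo2[g]) lo2[g] = j;
        if (j > hi2[g]) hi2[g] = j;
        if (k < lo3[g]) lo3[g] = k;
        if (k > hi3[g]) hi3[g] = k;
        if (haveAux && aux[idx] > mx[g]) mx[g] = aux[idx];
      }
  return List::create(_["count"] = cnt, _["max_aux"] = mx,
                      _["sum1"] = s1, _["sum2"] = s2, _["sum3"] = s3,
                      _["lo1"] = lo1, _["hi1"] = hi1,
                      _["lo2"] = lo2, _["hi2"] = hi2,
                      _["lo3"] = lo3, _["hi3"] = hi3);
}

// Face-adjacency necks: for every pair of face-adjacent voxels with
// different positive labels, track the max of the distance field over the
// two voxels. Returns the adjacency list with one row per unordered pair.
// [[Rcpp::export]]
DataFrame cpp_neck_table(IntegerVector labels, NumericVector dist, IntegerVector dim) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  std::map<std::pair<int, int>, double> best;
  R_xlen_t idx = 0;
  const R_xlen_t str2 = d1, str3 = (R_xlen_t)d1 * d2;
  for (int k = 0; k < d3; k++)
    for (int j = 0; j < d2; j++)
      for (int i = 0; i < d1; i++, idx++) {
        int a = labels[idx];
        if (a <= 0) continue;
        for (int axis = 0; axis < 3; axis++) {
          R_xlen_t q;
          if (axis == 0) { if (i + 1 >= d1) continue; q = idx + 1; }
          else if (axis == 1) { if (j + 1 >= d2) continue; q = idx + str2; }
          else { if (k + 1 >= d3) continue; q = idx + str3; }
          int b = labels[q];
          if (b <= 0 || b == a) continue;
          std::pair<int, int> key = a < b ? std::make_pair(a, b) : std::make_pair(b, a);
          double v = std::max(dist[idx], dist[q]);
          std::map<std::pair<int, int>, double>::iterator it = best.find(key);
          if (it == best.end()) best[key] = v;
          else if (v > it->second) it->second = v;
        }
      }
  int m = (int)best.size();
  IntegerVector ia(m), ib(m);
  NumericVector nd(m);
  int r = 0;
  for (std::map<std::pair<int, int>, double>::iterator it = best.begin();
       it != best.end(); ++it, ++r) {
    ia[r] = it->first.first;
    ib[r] = it->first.second;
    nd[r] = it->second;
  }
  return DataFrame::create(_["id_a"] = ia, _["id_b"] = ib, _["max_dist"] = nd);
}
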