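#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Random-sequential-addition helpers for the phantom generator. Candidate
// centers/radii are drawn in R (so all randomness flows through R's RNG);
// these routines only test voxel overlap and stamp accepted bodies, which
// keeps the generator bit-reproducible for a fixed seed.

// Spheres: candidate accepted iff none of its voxels is already solid
// (occ > 0) or blocked (blocked > 0, e.g. organic-matter particles).
// Stops once `targetVoxels` newly solid voxels have been added.
// [[Rcpp::export]]
List cpp_place_spheres(IntegerVector occ, LogicalVector blocked,
                       IntegerVector dim, NumericMatrix centers,
                       NumericVector radii, int phaseCode,
                       double targetVoxels) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  IntegerVector o = clone(occ);
  const int nc = centers.nrow();
  LogicalVector accepted(nc, false);
  double added = 0.0;
  int nacc = 0, tried = 0;
  const bool haveBlocked = blocked.size() == o.size();
  for (int s = 0; s < nc; s++) {
    if (added >= targetVoxels) break;
    tried++;
    double cx = centers(s, 0), cy = centers(s, 1), cz = centers(s, 2);
    double r = radii[s], r2 = r * r;
    // skip candidates that would clearly overshoot the volume budget, so
    // the achieved solid fraction stays close to target
    double est = 4.0 / 3.0 * M_PI * r2 * r;
    if (added + 0.9 * est > targetVoxels) continue;
    int i0 = std::max(0, (int)std::ceil(cx - r)), i1 = std::min(d1 - 1, (int)std::floor(cx + r));
    int j0 = std::max(0, (int)std::ceil(cy - r)), j1 = std::min(d2 - 1, (int)std::floor(cy + r));
    int k0 = std::max(0, (int)std::ceil(cz - r)), k1 = std::min(d3 - 1, (int)std::floor(cz + r));
    if (i0 > i1 || j0 > j1 || k0 > k1) continue;
    bool free = true;
    for (int k = k0; k <= k1 && free; k++) {
      double dz = k - cz, dz2 = dz * dz;
      for (int j = j0; j <= j1 && free; j++) {
        double dy = j - cy, dyz2 = dy * dy + dz2;
        if (dyz2 > r2) continue;
        R_xlen_t base = (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        for (int i = i0; i <= i1; i++) {
          double dx = i - cx;
          if (dx * dx + dyz2 > r2) continue;
          R_xlen_t q = base + i;
          if (o[q] > 0 || (haveBlocked && blocked[q])) { free = false; break; }
        }
      }
    }
    if (!free) continue;
    int vol = 0;
    for (int k = k0; k <= k1; k++) {
      double dz = k - cz, dz2 = dz * dz;
      for (int j = j0; j <= j1; j++) {
        double dy = j - cy, dyz2 = dy * dy + dz2;
        if (dyz2 > r2) continue;
        R_xlen_t base = (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        for (int i = i0; i <= i1; i++) {
          double dx = i - cx;
          if (dx * dx + dyz2 > r2) continue;
          o[base + i] = phaseCode;
          vol++;
        }
      }
    }
    if (vol == 0) continue; // degenerate: sphere covered no voxel center
    accepted[s] = true;
    nacc++;
    added += vol;
  }
  return List::create(_["occ"] = o, _["accepted"] = accepted,
                      _["added_voxels"] = added, _["n_accepted"] = nacc,
                      _["n_tried"] = tried);
}

// Axis-aligned ellipsoids for organic-matter particles. A candidate is
// rejected only if it would overlap a voxel already carrying an OM id
// (mutual non-overlap); other phases are replaced by the caller.
// Accepted particles are stamped with ids firstId, firstId+1, ...
// [[Rcpp::export]]
List cpp_place_ellipsoids(IntegerVector om, IntegerVector dim,
                          NumericMatrix centers, NumericMatrix semi,
                          int nWanted, int firstId) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  IntegerVector o = clone(om);
  const int nc = centers.nrow();
  LogicalVector accepted(nc, false);
  int placed = 0;
  for (int s = 0; s < nc && placed < nWanted; s++) {
    double cx = centers(s, 0), cy = centers(s, 1), cz = centers(s, 2);
    double ax = semi(s, 0), ay = semi(s, 1), az = semi(s, 2);
    int i0 = std::max(0, (int)std::ceil(cx - ax)), i1 = std::min(d1 - 1, (int)std::floor(cx + ax));
    int j0 = std::max(0, (int)std::ceil(cy - ay)), j1 = std::min(d2 - 1, (int)std::floor(cy + ay));
    int k0 = std::max(0, (int)std::ceil(cz - az)), k1 = std::min(d3 - 1, (int)std::floor(cz + az));
    if (i0 > i1 || j0 > j1 || k0 > k1) continue;
    // reject particles whose bounding box is clipped by the grid: embedded
    // particles should lie fully inside the core
    if (cx - ax < 0 || cx + ax > d1 - 1 || cy - ay < 0 || cy + ay > d2 - 1 ||
        cz - az < 0 || cz + az > d3 - 1) continue;
    bool free = true;
    for (int k = k0; k <= k1 && free; k++) {
      double fz = (k - cz) / az, fz2 = fz * fz;
      for (int j = j0; j <= j1 && free; j++) {
        double fy = (j - cy) / ay, fyz2 = fy * fy + fz2;
        if (fyz2 > 1.0) continue;
        R_xlen_t base = (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        for (int i = i0; i <= i1; i++) {
          double fx = (i - cx) / ax;
          if (fx * fx + fyz2 > 1.0) continue;
          if (o[base + i] > 0) { free = false; break; }
        }
      }
    }
    if (!free) continue;
    int id = firstId + placed;
    int vol = 0;
    for (int k = k0; k <= k1; k++) {
      double fz = (k - cz) / az, fz2 = fz * fz;
      for (int j = j0; j <= j1; j++) {
        double fy = (j - cy) / ay, fyz2 = fy * fy + fz2;
        if (fyz2 > 1.0) continue;
        R_xlen_t base = (R_xlen_t)d1 * (j + (R_xlen_t)d2 * k);
        for (int i = i0; i <= i1; i++) {
          double fx = (i - cx) / ax;
          if (fx * fx + fyz2 > 1.0) continue;
          o[base + i] = id;
          vol++;
        }
      }
    }
    if (vol == 0) continue;
    accepted[s] = true;
    placed++;
  }
  return List::create(_["om"] = o, _["accepted"] = accepted,
                      _["n_placed"] = placed);
}
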