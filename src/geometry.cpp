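#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
using namespace Rcpp;

// Shrake-Rupley solvent accessible surface area.
// Sphere points from a Fibonacci (golden-section) spiral: deterministic,
// near-uniform coverage for any n_points.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix xyz, NumericVector radii,
                       double probe, int n_points) {
  int n = xyz.nrow();
  NumericVector area(n);
  if (n == 0) return area;

  // unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = z;
  }

  std::vector<double> er(n); // expanded radii
  for (int i = 0; i < n; ++i) er[i] = radii[i] + probe;

  for (int i = 0; i < n; ++i) {
    double ri = er[i];
    double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    // neighbour prefilter
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double cut = ri + er[j];
      double dx = xi - xyz(j, 0), dy = yi - xyz(j, 1), dz = zi - xyz(j, 2);
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double sx = xi + ri * px[k], sy = yi + ri * py[k], sz = zi + ri * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double rj = er[j];
        double dx = sx - xyz(j, 0), dy = sy - xyz(j, 1), dz = sz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)acc / (double)n_points;
  }
  return area;
}

struct CellKey {
  int x, y, z;
  bool operator<(const CellKey &o) const {
    if (x != o.x) return x < o.x;
    if (y != o.y) return y < o.y;
    return z < o.z;
  }
};

static std::map<CellKey, std::vector<int> > build_grid(const NumericMatrix &xyz,
                                                       double cell) {
  std::map<CellKey, std::vector<int> > grid;
  for (int i = 0; i < xyz.nrow(); ++i) {
    CellKey k;
    k.x = (int)std::floor(xyz(i, 0) / cell);
    k.y = (int)std::floor(xyz(i, 1) / cell);
    k.z = (int)std::floor(xyz(i, 2) / cell);
    grid[k].push_back(i);
  }
  return grid;
}

// Any pair of atoms (one from each set) closer than cutoff?
// Cell-list neighbour search, early exit on first hit.
// [[Rcpp::export]]
bool cpp_any_contact(NumericMatrix xyzA, NumericMatrix xyzB, double cutoff) {
  if (xyzA.nrow() == 0 || xyzB.nrow() == 0) return false;
  double c2 = cutoff * cutoff;
  std::map<CellKey, std::vector<int> > grid = build_grid(xyzB, cutoff);
  for (int i = 0; i < xyzA.nrow(); ++i) {
    int cx = (int)std::floor(xyzA(i, 0) / cutoff);
    int cy = (int)std::floor(xyzA(i, 1) / cutoff);
    int cz = (int)std::floor(xyzA(i, 2) / cutoff);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          CellKey k; k.x = cx + dx; k.y = cy + dy; k.z = cz + dz;
          std::map<CellKey, std::vector<int> >::const_iterator it = grid.find(k);
          if (it == grid.end()) continue;
          const std::vector<int> &v = it->second;
          for (size_t m = 0; m < v.size(); ++m) {
            int j = v[m];
            double ddx = xyzA(i, 0) - xyzB(j, 0);
            double ddy = xyzA(i, 1) - xyzB(j, 1);
            double ddz = xyzA(i, 2) - xyzB(j, 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz < c2) return true;
          }
        }
  }
  return false;
}

// Minimal inter-atomic distance between two atom sets (exact, all pairs).
// [[Rcpp::export]]
double cpp_min_dist(NumericMatrix xyzA, NumericMatrix xyzB) {
  double best = R_PosInf;
  for (int i = 0; i < xyzA.nrow(); ++i)
    for (int j = 0; j < xyzB.nrow(); ++j) {
      double dx = xyzA(i, 0) - xyzB(j, 0);
      double dy = xyzA(i, 1) - xyzB(j, 1);
      double dz = xyzA(i, 2) - xyzB(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}

// Residue pairs with minimal inter-atomic distance < cutoff.
// resA/resB: residue index (1-based seqres position) per atom.
// Cell-list accelerated; the minimum over atom pairs within the cutoff is the
// true residue-pair minimum whenever that minimum is below the cutoff.
// Returns a 3-column matrix: resA, resB, d.
// [[Rcpp::export]]
NumericMatrix cpp_contact_pairs(NumericMatrix xyzA, IntegerVector resA,
                                NumericMatrix xyzB, IntegerVector resB,
                                double cutoff) {
  std::map<std::pair<int, int>, double> best;
  double c2 = cutoff * cutoff;
  std::map<CellKey, std::vector<int> > grid = build_grid(xyzB, cutoff);
  for (int i = 0; i < xyzA.nrow(); ++i) {
    int cx = (int)std::floor(xyzA(i, 0) / cutoff);
    int cy = (int)std::floor(xyzA(i, 1) / cutoff);
    int cz = (int)std::floor(xyzA(i, 2) / cutoff);
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          CellKey k; k.x = cx + dx; k.y = cy + dy; k.z = cz + dz;
          std::map<CellKey, std::vector<int> >::const_iterator it = grid.find(k);
          if (it == grid.end()) continue;
          const std::vector<int> &v = it->second;
          for (size_t m = 0; m < v.size(); ++m) {
            int j = v[m];
            double ddx = xyzA(i, 0) - xyzB(j, 0);
            double ddy = xyzA(i, 1) - xyzB(j, 1);
            double ddz = xyzA(i, 2) - xyzB(j, 2);
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 < c2) {
              std::pair<int, int> key(resA[i], resB[j]);
              std::map<std::pair<int, int>, double>::iterator f = best.find(key);
              if (f == best.end() || d2 < f->second) best[key] = d2;
            }
          }
        }
  }
  NumericMatrix out(best.size(), 3);
  int r = 0;
  for (std::map<std::pair<int, int>, double>::const_iterator it = best.begin();
       it != best.end(); ++it, ++r) {
    out(r, 0) = it->first.first;
    out(r, 1) = it->first.second;
    out(r, 2) = std::sqrt(it->second);
  }
  colnames(out) = CharacterVector::create("resA", "resB", "d");
  return out;
}

// Full residue-by-residue minimal distance matrix (brute force, exact).
// Used for the dASA admission rule, where the nearest partner may lie beyond
// any contact cutoff. nresA/nresB give matrix dimensions; residues without
// atoms get +Inf rows/columns.
// [[Rcpp::export]]
NumericMatrix cpp_res_min_dist(NumericMatrix xyzA, IntegerVector resA, int nresA,
                               NumericMatrix xyzB, IntegerVector resB, int nresB) {
  NumericMatrix out(nresA, nresB);
  std::fill(out.begin(), out.end(), R_PosInf);
  for (int i = 0; i < xyzA.nrow(); ++i) {
    int ri = resA[i] - 1;
    for (int j = 0; j < xyzB.nrow(); ++j) {
      int rj = resB[j] - 1;
      double dx = xyzA(i, 0) - xyzB(j, 0);
      double dy = xyzA(i, 1) - xyzB(j, 1);
      double dz = xyzA(i, 2) - xyzB(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < out(ri, rj)) out(ri, rj) = d2;
    }
  }
  for (int i = 0; i < nresA; ++i)
    for (int j = 0; j < nresB; ++j)
      if (R_finite(out(i, j))) out(i, j) = std::sqrt(out(i, j));
  return out;
}
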