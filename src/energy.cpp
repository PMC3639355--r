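#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

// Pairwise nonbonded kernels for the surrogate force field, Shrake-Rupley
// SASA, and receptor grid maps. Systems are small (<= a few thousand atoms);
// plain double loops are fast enough and keep the code auditable against the
// R brute-force oracles.

static inline double lj_pair(double r2, double eps, double sig,
                             double lambda, double cap) {
  double s2 = sig * sig / r2;
  double s6 = s2 * s2 * s2;
  double e = 4.0 * eps * (s6 * s6 - s6);
  if (e > 0.0 && lambda > 0.0) {
    // soft-core: bounded repulsion, cap/lambda as r -> 0
    e = e / (1.0 + lambda * e / cap);
  }
  return e;
}

// [[Rcpp::export]]
double cpp_min_pair_distance(NumericMatrix A, NumericMatrix B) {
  double best = R_PosInf;
  for (int i = 0; i < A.nrow(); ++i) {
    for (int j = 0; j < B.nrow(); ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1),
             dz = A(i, 2) - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}

// Nonbonded vdW + electrostatic energy.
// sel_a / sel_b: 0-based atom indices. If sel_b is empty, all pairs within
// sel_a are summed; otherwise only cross pairs sel_a x sel_b (disjoint sets).
// excl: 2-column 0-based matrix of excluded (1-2/1-3/1-4) pairs.
// elec_mode 0: distance-dependent dielectric eps(r) = 4r; 1: constant 4.
// [[Rcpp::export]]
NumericVector cpp_nb_energy(NumericMatrix coords, NumericVector eps,
                            NumericVector sig, NumericVector q,
                            IntegerMatrix excl, IntegerVector sel_a,
                            IntegerVector sel_b, double lambda, double cap,
                            int elec_mode) {
  const double KCOUL = 332.06;
  const int n = coords.nrow();
  // per-atom sorted exclusion adjacency (bonded 1-2/1-3/1-4 neighbours)
  std::vector<std::vector<int> > exadj(n);
  for (int k = 0; k < excl.nrow(); ++k) {
    int i = excl(k, 0), j = excl(k, 1);
    exadj[i].push_back(j);
    exadj[j].push_back(i);
  }
  for (int i = 0; i < n; ++i) std::sort(exadj[i].begin(), exadj[i].end());
  const double *X = &coords(0, 0);
  const double *Y = X + n, *Z = X + 2 * n;
  const double *E = &eps[0], *S = &sig[0], *Q = &q[0];
  double evdw = 0.0, eelec = 0.0;
  const bool ddd = (elec_mode == 0);
  auto accumulate = [&](int i, int j) {
    const std::vector<int> &ea = exadj[i];
    if (!ea.empty() && std::binary_search(ea.begin(), ea.end(), j)) return;
    double dx = X[i] - X[j], dy = Y[i] - Y[j], dz = Z[i] - Z[j];
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 1e-12) r2 = 1e-12;
    double e = std::sqrt(E[i] * E[j]);
    double s = 0.5 * (S[i] + S[j]);
    evdw += lj_pair(r2, e, s, lambda, cap);
    double qq = Q[i] * Q[j];
    if (qq != 0.0) {
      if (ddd) eelec += KCOUL * qq / (4.0 * r2);  // eps(r)=4r -> q1q2/(4 r^2)
      else eelec += KCOUL * qq / (4.0 * std::sqrt(r2));
    }
  };
  if (sel_b.size() == 0) {
    for (int a = 0; a < sel_a.size(); ++a)
      for (int b = a + 1; b < sel_a.size(); ++b)
        accumulate(sel_a[a], sel_a[b]);
  } else {
    for (int a = 0; a < sel_a.size(); ++a)
      for (int b = 0; b < sel_b.size(); ++b)
        accumulate(sel_a[a], sel_b[b]);
  }
  return NumericVector::create(_["vdw"] = evdw, _["elec"] = eelec);
}

// Shrake-Rupley solvent-accessible surface area, per atom.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii,
                       double probe, int n_points) {
  int n = coords.nrow();
  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    px[k] = r * std::cos(ga * k);
    py[k] = r * std::sin(ga * k);
    pz[k] = z;
  }
  NumericVector area(n);
  for (int i = 0; i < n; ++i) {
    double ri = radii[i] + probe;
    // neighbours
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = coords(i, 0) - coords(j, 0), dy = coords(i, 1) - coords(j, 1),
             dz = coords(i, 2) - coords(j, 2);
      double lim = ri + radii[j] + probe;
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      double x = coords(i, 0) + ri * px[k], y = coords(i, 1) + ri * py[k],
             z = coords(i, 2) + ri * pz[k];
      bool buried = false;
      for (size_t t = 0; t < nb.size(); ++t) {
        int j = nb[t];
        double rj = radii[j] + probe;
        double dx = x - coords(j, 0), dy = y - coords(j, 1), dz = z - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * acc / n_points;
  }
  return area;
}

// Occupancy grid: 1 where a voxel center lies within radii[i] + pad of atom i.
// dims = (nx, ny, nz); returned vector is x-fastest.
// [[Rcpp::export]]
IntegerVector cpp_occupancy(NumericMatrix coords, NumericVector radii,
                            NumericVector origin, double spacing,
                            IntegerVector dims, double pad) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector occ(nx * ny * nz, 0);
  for (int a = 0; a < coords.nrow(); ++a) {
    double r = radii[a] + pad;
    int i0 = std::max(0, (int)std::floor((coords(a, 0) - r - origin[0]) / spacing));
    int i1 = std::min(nx - 1, (int)std::ceil((coords(a, 0) + r - origin[0]) / spacing));
    int j0 = std::max(0, (int)std::floor((coords(a, 1) - r - origin[1]) / spacing));
    int j1 = std::min(ny - 1, (int)std::ceil((coords(a, 1) + r - origin[1]) / spacing));
    int k0 = std::max(0, (int)std::floor((coords(a, 2) - r - origin[2]) / spacing));
    int k1 = std::min(nz - 1, (int)std::ceil((coords(a, 2) + r - origin[2]) / spacing));
    double r2 = r * r;
    for (int k = k0; k <= k1; ++k) {
      double dz = origin[2] + k * spacing - coords(a, 2);
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * spacing - coords(a, 1);
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * spacing - coords(a, 0);
          if (dx * dx + dy * dy + dz * dz <= r2)
            occ[(k * ny + j) * nx + i] = 1;
        }
      }
    }
  }
  return occ;
}

// Receptor interaction grid maps for docking: vdW (carbon probe, soft-capped),
// electrostatic potential (per unit charge, eps(r) = 4r), hydrogen-bond well
// (near donors/acceptors), hydrophobic well (near apolar carbons).
// [[Rcpp::export]]
List cpp_grid_maps(NumericMatrix coords, NumericVector eps, NumericVector sig,
                   NumericVector q, LogicalVector polar, LogicalVector apolar,
                   NumericVector origin, double spacing, IntegerVector dims,
                   double cap) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nv = nx * ny * nz;
  NumericVector mv(nv), me(nv), mh(nv), mp(nv);
  const double KCOUL = 332.06;
  const double peps = 0.066, psig = 3.5;  // aliphatic-carbon probe
  for (int k = 0; k < nz; ++k) {
    double z = origin[2] + k * spacing;
    for (int j = 0; j < ny; ++j) {
      double y = origin[1] + j * spacing;
      for (int i = 0; i < nx; ++i) {
        double x = origin[0] + i * spacing;
        int v = (k * ny + j) * nx + i;
        double sv = 0, se = 0, sh = 0, sp = 0;
        for (int a = 0; a < coords.nrow(); ++a) {
          double dx = x - coords(a, 0), dy = y - coords(a, 1), dz = z - coords(a, 2);
          double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 > 144.0) continue;  // 12 A cutoff
          if (r2 < 0.25) r2 = 0.25;
          double e = std::sqrt(eps[a] * peps);
          double s = 0.5 * (sig[a] + psig);
          sv += lj_pair(r2, e, s, 1.0, cap);
          if (q[a] != 0.0) se += KCOUL * q[a] / (4.0 * r2);
          double r = std::sqrt(r2);
          if (polar[a]) {
            // well centred at 1.9 A (H..A-like), fading by 3.5 A
            double w = 0.0;
            if (r < 2.5) w = 1.0;
            else if (r < 3.5) w = (3.5 - r) / 1.0;
            sh += -w;
          }
          if (apolar[a]) {
            double w = 0.0;
            if (r < 4.5) w = 1.0;
            else if (r < 6.0) w = (6.0 - r) / 1.5;
            sp += -0.1 * w;
          }
        }
        mv[v] = std::min(sv, cap * 5.0);
        me[v] = se; mh[v] = sh; mp[v] = sp;
      }
    }
  }
  return List::create(_["vdw"] = mv, _["elec"] = me, _["hbond"] = mh,
                      _["hydrophobic"] = mp);
}

// Trilinear interpolation of a grid map at arbitrary points; points outside
// the grid get `fill`.
// [[Rcpp::export]]
NumericVector cpp_interp3(NumericVector map, NumericVector origin,
                          double spacing, IntegerVector dims,
                          NumericMatrix pts, double fill) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(pts.nrow());
  for (int p = 0; p < pts.nrow(); ++p) {
    double fx = (pts(p, 0) - origin[0]) / spacing;
    double fy = (pts(p, 1) - origin[1]) / spacing;
    double fz = (pts(p, 2) - origin[2]) / spacing;
    int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
    if (i < 0 || j < 0 || k < 0 || i >= nx - 1 || j >= ny - 1 || k >= nz - 1) {
      out[p] = fill;
      continue;
    }
    double tx = fx - i, ty = fy - j, tz = fz - k;
    double acc = 0.0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          double w = (di ? tx : 1 - tx) * (dj ? ty : 1 - ty) * (dk ? tz : 1 - tz);
          acc += w * map[((k + dk) * ny + (j + dj)) * nx + (i + di)];
        }
    out[p] = acc;
  }
  return out;
}
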