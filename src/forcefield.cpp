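#include <Rcpp.h>
#include <cmath>
#include <unordered_map>
#include <vector>
#include <utility>
using namespace Rcpp;

// Pairwise + bonded molecular-mechanics kernel.
// Units: kcal/mol, Angstrom, elementary charge. Periodicity is in-plane only
// (two lattice vectors in the xy plane); the surface normal is open.

static const double KE_COULOMB = 332.0637128; // kcal*A/(mol*e^2)

struct MinImage {
  bool periodic;
  double a1x, a1y, a2x, a2y;  // lattice vectors (z components are zero)
  double i11, i12, i21, i22;  // inverse of [a1 a2] column matrix
  void init(const NumericMatrix &cell) {
    periodic = true;
    a1x = cell(0, 0); a1y = cell(1, 0);
    a2x = cell(0, 1); a2y = cell(1, 1);
    double det = a1x * a2y - a2x * a1y;
    i11 =  a2y / det; i12 = -a2x / det;
    i21 = -a1y / det; i22 =  a1x / det;
  }
  // Replace dx,dy by the minimum-image displacement. Skewed (hexagonal)
  // cells can defeat plain fractional rounding, so the 3x3 neighbour
  // images around the rounded shift are scanned.
  inline void apply(double &dx, double &dy) const {
    if (!periodic) return;
    double f1 = i11 * dx + i12 * dy;
    double f2 = i21 * dx + i22 * dy;
    double n1 = std::round(f1), n2 = std::round(f2);
    double bx = dx, by = dy, best = 1e300;
    for (int s1 = -1; s1 <= 1; ++s1) {
      for (int s2 = -1; s2 <= 1; ++s2) {
        double m1 = n1 + s1, m2 = n2 + s2;
        double tx = dx - (m1 * a1x + m2 * a2x);
        double ty = dy - (m1 * a1y + m2 * a2y);
        double r2 = tx * tx + ty * ty;
        if (r2 < best) { best = r2; bx = tx; by = ty; }
      }
    }
    dx = bx; dy = by;
  }
};

// Quintic smoothstep switching on [r_on, r_off]; C2 continuous, which
// keeps NVE energy conservation clean as pairs cross the window.
static inline void switch_fn(double r, double ron, double roff,
                             double &S, double &dS) {
  if (r <= ron) { S = 1.0; dS = 0.0; return; }
  if (r >= roff) { S = 0.0; dS = 0.0; return; }
  double w = roff - ron;
  double x = (r - ron) / w;
  S = 1.0 - x * x * x * (10.0 - 15.0 * x + 6.0 * x * x);
  dS = -30.0 * x * x * (1.0 - x) * (1.0 - x) / w;
}

static inline long long pair_key(int i, int j, int n) {
  if (i > j) std::swap(i, j);
  return (long long)i * (long long)n + (long long)j;
}

// [[Rcpp::export(name = ".ff_eval_cpp")]]
List ff_eval_cpp(NumericMatrix coords,
                 IntegerMatrix bonds, NumericVector bond_k, NumericVector bond_r0,
                 IntegerMatrix angles, NumericVector angle_k, NumericVector angle_t0,
                 IntegerMatrix dihedrals, NumericVector dihe_k,
                 IntegerVector dihe_n, NumericVector dihe_phi0,
                 NumericVector charge, NumericVector eps, NumericVector sigma,
                 IntegerMatrix excl12_13, IntegerMatrix pairs14,
                 double scale_lj14, double scale_coul14,
                 Nullable<NumericMatrix> cell,
                 double cutoff, double switch_on,
                 IntegerVector group, int surface_group) {
  const int n = coords.nrow();
  NumericMatrix forces(n, 3);
  NumericVector surf_atom(n);  // per-atom nonbonded energy with the surface group
  double e_bond = 0, e_angle = 0, e_dihedral = 0, e_lj = 0, e_coul = 0,
         e_surface = 0;

  MinImage mi; mi.periodic = false;
  if (cell.isNotNull()) mi.init(NumericMatrix(cell));

  // --- bonds: E = k (r - r0)^2 ---
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0), j = bonds(b, 1);
    double dx = coords(i, 0) - coords(j, 0);
    double dy = coords(i, 1) - coords(j, 1);
    double dz = coords(i, 2) - coords(j, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - bond_r0[b];
    e_bond += bond_k[b] * dr * dr;
    double fmag = -2.0 * bond_k[b] * dr / r;
    forces(i, 0) += fmag * dx; forces(i, 1) += fmag * dy; forces(i, 2) += fmag * dz;
    forces(j, 0) -= fmag * dx; forces(j, 1) -= fmag * dy; forces(j, 2) -= fmag * dz;
  }

  // --- angles: E = k (theta - theta0)^2 ---
  for (int a = 0; a < angles.nrow(); ++a) {
    int i = angles(a, 0), j = angles(a, 1), k = angles(a, 2);
    double rij[3], rkj[3];
    for (int d = 0; d < 3; ++d) {
      rij[d] = coords(i, d) - coords(j, d);
      rkj[d] = coords(k, d) - coords(j, d);
    }
    double nij = std::sqrt(rij[0]*rij[0] + rij[1]*rij[1] + rij[2]*rij[2]);
    double nkj = std::sqrt(rkj[0]*rkj[0] + rkj[1]*rkj[1] + rkj[2]*rkj[2]);
    double cs = (rij[0]*rkj[0] + rij[1]*rkj[1] + rij[2]*rkj[2]) / (nij * nkj);
    if (cs > 1.0) cs = 1.0; if (cs < -1.0) cs = -1.0;
    double theta = std::acos(cs);
    double dt = theta - angle_t0[a];
    e_angle += angle_k[a] * dt * dt;
    double sn = std::sqrt(1.0 - cs * cs);
    if (sn < 1e-8) sn = 1e-8;
    double dEdTheta = 2.0 * angle_k[a] * dt;
    double c = dEdTheta / sn;  // = -dE/dcos(theta) * (dcos/dtheta chain handled)
    for (int d = 0; d < 3; ++d) {
      double fi = c * (rkj[d] / (nij * nkj) - cs * rij[d] / (nij * nij));
      double fk = c * (rij[d] / (nij * nkj) - cs * rkj[d] / (nkj * nkj));
      forces(i, d) += fi;
      forces(k, d) += fk;
      forces(j, d) -= (fi + fk);
    }
  }

  // --- proper dihedrals: E = k (1 + cos(n*phi - phi0)) ---
  for (int t = 0; t < dihedrals.nrow(); ++t) {
    int i = dihedrals(t, 0), j = dihedrals(t, 1),
        k = dihedrals(t, 2), l = dihedrals(t, 3);
    double b1[3], b2[3], b3[3];
    for (int d = 0; d < 3; ++d) {
      b1[d] = coords(j, d) - coords(i, d);
      b2[d] = coords(k, d) - coords(j, d);
      b3[d] = coords(l, d) - coords(k, d);
    }
    double m[3] = { b1[1]*b2[2] - b1[2]*b2[1],
                    b1[2]*b2[0] - b1[0]*b2[2],
                    b1[0]*b2[1] - b1[1]*b2[0] };
    double nv[3] = { b2[1]*b3[2] - b2[2]*b3[1],
                     b2[2]*b3[0] - b2[0]*b3[2],
                     b2[0]*b3[1] - b2[1]*b3[0] };
    double m2 = m[0]*m[0] + m[1]*m[1] + m[2]*m[2];
    double n2 = nv[0]*nv[0] + nv[1]*nv[1] + nv[2]*nv[2];
    double nb2 = std::sqrt(b2[0]*b2[0] + b2[1]*b2[1] + b2[2]*b2[2]);
    if (m2 < 1e-12 || n2 < 1e-12) continue;  // collinear: torsion undefined
    // phi via atan2 (robust near 0 / pi)
    double cosphi = (m[0]*nv[0] + m[1]*nv[1] + m[2]*nv[2]) / std::sqrt(m2 * n2);
    double sinphi = (m[0]*b3[0] + m[1]*b3[1] + m[2]*b3[2]) * nb2 /
                    std::sqrt(m2 * n2);
    double phi = std::atan2(sinphi, cosphi);
    int nn = dihe_n[t];
    e_dihedral += dihe_k[t] * (1.0 + std::cos(nn * phi - dihe_phi0[t]));
    double dEdPhi = -dihe_k[t] * nn * std::sin(nn * phi - dihe_phi0[t]);
    // analytic torsion gradient (standard decomposition)
    double fi[3], fl[3];
    for (int d = 0; d < 3; ++d) {
      fi[d] =  dEdPhi * nb2 / m2 * m[d];
      fl[d] = -dEdPhi * nb2 / n2 * nv[d];
    }
    double b1b2 = (b1[0]*b2[0] + b1[1]*b2[1] + b1[2]*b2[2]) / (nb2 * nb2);
    double b3b2 = (b3[0]*b2[0] + b3[1]*b2[1] + b3[2]*b2[2]) / (nb2 * nb2);
    for (int d = 0; d < 3; ++d) {
      double tj = -(1.0 + b1b2) * fi[d] + b3b2 * fl[d];
      double tk = b1b2 * fi[d] - (1.0 + b3b2) * fl[d];
      forces(i, d) += fi[d];
      forces(j, d) += tj;
      forces(k, d) += tk;
      forces(l, d) += fl[d];
    }
  }

  // --- nonbonded: LJ + Coulomb, exclusions, 1-4 scaling, switching ---
  std::unordered_map<long long, int> special;  // 0 = excluded, 1 = 1-4
  for (int p = 0; p < excl12_13.nrow(); ++p)
    special[pair_key(excl12_13(p, 0), excl12_13(p, 1), n)] = 0;
  for (int p = 0; p < pairs14.nrow(); ++p) {
    long long kk = pair_key(pairs14(p, 0), pairs14(p, 1), n);
    if (special.find(kk) == special.end()) special[kk] = 1;
  }

  double cutoff2 = cutoff * cutoff;
  // candidate in-plane image shifts: {0,0} for open systems, else every
  // image that can fall inside the cutoff (the base displacement is
  // reduced to the home cell first, so +/-2 shells are always enough
  // for cells wider than half the cutoff)
  std::vector<std::pair<double, double> > shifts;
  if (mi.periodic) {
    // home-reduced displacements lie within the cell's half-diagonal;
    // an image at lattice offset L can only reach inside the cutoff if
    // |L| - r_home < cutoff, which prunes the shells for large cells
    double hx = 0.5 * (std::fabs(mi.a1x) + std::fabs(mi.a2x));
    double hy = 0.5 * (std::fabs(mi.a1y) + std::fabs(mi.a2y));
    double r_home = std::sqrt(hx * hx + hy * hy);
    for (int s1 = -2; s1 <= 2; ++s1)
      for (int s2 = -2; s2 <= 2; ++s2) {
        double lx = s1 * mi.a1x + s2 * mi.a2x;
        double ly = s1 * mi.a1y + s2 * mi.a2y;
        if (s1 != 0 || s2 != 0)
          if (std::sqrt(lx * lx + ly * ly) - r_home >= cutoff) continue;
        shifts.push_back(std::make_pair(lx, ly));
      }
  } else {
    shifts.push_back(std::make_pair(0.0, 0.0));
  }
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool i_surf = (surface_group >= 0 && group[i] == surface_group);
      bool j_surf = (surface_group >= 0 && group[j] == surface_group);
      if (i_surf && j_surf) continue;  // rigid substrate: internal pairs skipped
      double slj = 1.0, scl = 1.0;
      auto it = special.find(pair_key(i, j, n));
      if (it != special.end()) {
        if (it->second == 0) continue;
        slj = scale_lj14; scl = scale_coul14;
      }
      double dx0 = coords(i, 0) - coords(j, 0);
      double dy0 = coords(i, 1) - coords(j, 1);
      double dz = coords(i, 2) - coords(j, 2);
      if (mi.periodic) {
        // reduce to the home cell (nearest image) before scanning shells
        double f1 = mi.i11 * dx0 + mi.i12 * dy0;
        double f2 = mi.i21 * dx0 + mi.i22 * dy0;
        double n1 = std::round(f1), n2 = std::round(f2);
        dx0 -= n1 * mi.a1x + n2 * mi.a2x;
        dy0 -= n1 * mi.a1y + n2 * mi.a2y;
      }
      double sij = 0.5 * (sigma[i] + sigma[j]);
      double eij = std::sqrt(eps[i] * eps[j]);
      double qq = charge[i] * charge[j];
      bool cross = (i_surf != j_surf);
      for (size_t im = 0; im < shifts.size(); ++im) {
        double dx = dx0 - shifts[im].first;
        double dy = dy0 - shifts[im].second;
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= cutoff2) continue;
        double r = std::sqrt(r2);
        double sr6 = std::pow(sij * sij / r2, 3.0);
        double elj = slj * 4.0 * eij * (sr6 * sr6 - sr6);
        double dlj = slj * 4.0 * eij * (-12.0 * sr6 * sr6 + 6.0 * sr6) / r;
        double ecl = 0.0, dcl = 0.0;
        if (qq != 0.0) {
          ecl = scl * KE_COULOMB * qq / r;
          dcl = -ecl / r;
        }
        double S, dS;
        switch_fn(r, switch_on, cutoff, S, dS);
        double epair = S * (elj + ecl);
        double dEdr = S * (dlj + dcl) + dS * (elj + ecl);
        e_lj += S * elj;
        e_coul += S * ecl;
        if (cross) {
          e_surface += epair;
          // assign the full pair energy to the non-surface atom
          if (i_surf) surf_atom[j] += epair; else surf_atom[i] += epair;
        }
        double fmag = -dEdr / r;
        forces(i, 0) += fmag * dx; forces(i, 1) += fmag * dy; forces(i, 2) += fmag * dz;
        forces(j, 0) -= fmag * dx; forces(j, 1) -= fmag * dy; forces(j, 2) -= fmag * dz;
      }
    }
  }

  return List::create(
    _["e_bond"] = e_bond, _["e_angle"] = e_angle, _["e_dihedral"] = e_dihedral,
    _["e_lj"] = e_lj, _["e_coul"] = e_coul, _["e_surface"] = e_surface,
    _["surface_per_atom"] = surf_atom, _["forces"] = forces);
}
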