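#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pairwise Lennard-Jones + Coulomb over a precomputed interaction pair
// list. sig/eps are combined per pair (Lorentz-Berthelot, done in R);
// qq carries k * q_i * q_j / eps_r. Pairs beyond the distance cutoff
// contribute zero; cutoff <= 0 disables the cutoff.

// [[Rcpp::export(name = ".nb_energy_cpp")]]
List nb_energy_cpp(NumericMatrix coords, IntegerVector pi, IntegerVector pj,
                   NumericVector sig, NumericVector eps, NumericVector qq,
                   double cutoff) {
  const int np = pi.size();
  double elj = 0.0, ecoul = 0.0;
  const double cut2 = cutoff > 0 ? cutoff * cutoff : R_PosInf;
  for (int k = 0; k < np; ++k) {
    const int a = pi[k] - 1, b = pj[k] - 1;
    const double dx = coords(a, 0) - coords(b, 0);
    const double dy = coords(a, 1) - coords(b, 1);
    const double dz = coords(a, 2) - coords(b, 2);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 1e-24)
      stop("zero interatomic distance between atoms %d and %d", a + 1, b + 1);
    if (r2 > cut2) continue;
    const double s2 = sig[k] * sig[k] / r2;
    const double s6 = s2 * s2 * s2;
    elj += 4.0 * eps[k] * (s6 * s6 - s6);
    ecoul += qq[k] / std::sqrt(r2);
  }
  return List::create(_["lj"] = elj, _["coulomb"] = ecoul);
}

// Energy plus analytic gradient (kcal/mol/A) of LJ + Coulomb.
// [[Rcpp::export(name = ".nb_gradient_cpp")]]
List nb_gradient_cpp(NumericMatrix coords, IntegerVector pi, IntegerVector pj,
                     NumericVector sig, NumericVector eps, NumericVector qq,
                     double cutoff) {
  const int np = pi.size(), n = coords.nrow();
  NumericMatrix grad(n, 3);
  double elj = 0.0, ecoul = 0.0;
  const double cut2 = cutoff > 0 ? cutoff * cutoff : R_PosInf;
  for (int k = 0; k < np; ++k) {
    const int a = pi[k] - 1, b = pj[k] - 1;
    const double dx = coords(a, 0) - coords(b, 0);
    const double dy = coords(a, 1) - coords(b, 1);
    const double dz = coords(a, 2) - coords(b, 2);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 < 1e-24)
      stop("zero interatomic distance between atoms %d and %d", a + 1, b + 1);
    if (r2 > cut2) continue;
    const double r = std::sqrt(r2);
    const double s2 = sig[k] * sig[k] / r2;
    const double s6 = s2 * s2 * s2;
    elj += 4.0 * eps[k] * (s6 * s6 - s6);
    const double ec = qq[k] / r;
    ecoul += ec;
    // dE/dr terms: LJ: 4*eps*(-12 s12 + 6 s6)/r ; Coulomb: -qq/r^2
    const double dedr = (4.0 * eps[k] * (-12.0 * s6 * s6 + 6.0 * s6) - ec) / r;
    const double fx = dedr * dx / r, fy = dedr * dy / r, fz = dedr * dz / r;
    grad(a, 0) += fx; grad(a, 1) += fy; grad(a, 2) += fz;
    grad(b, 0) -= fx; grad(b, 1) -= fy; grad(b, 2) -= fz;
  }
  return List::create(_["lj"] = elj, _["coulomb"] = ecoul,
                      _["gradient"] = grad);
}

// Shrake-Rupley solvent-accessible surface area with a deterministic
// golden-section spiral point set (no RNG). radii must already include
// the probe radius.
// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix coords, NumericVector radii,
                       int n_points) {
  const int n = coords.nrow();
  NumericVector area(n);
  // golden-section spiral on the unit sphere
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    const double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    const double rxy = std::sqrt(std::max(0.0, 1.0 - z * z));
    const double th = golden * k;
    px[k] = rxy * std::cos(th);
    py[k] = rxy * std::sin(th);
    pz[k] = z;
  }
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i];
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(j, 0) - coords(i, 0);
      const double dy = coords(j, 1) - coords(i, 1);
      const double dz = coords(j, 2) - coords(i, 2);
      const double lim = ri + radii[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nbr.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      const double x = coords(i, 0) + ri * px[k];
      const double y = coords(i, 1) + ri * py[k];
      const double z = coords(i, 2) + ri * pz[k];
      bool free_point = true;
      for (size_t m = 0; m < nbr.size(); ++m) {
        const int j = nbr[m];
        const double dx = x - coords(j, 0);
        const double dy = y - coords(j, 1);
        const double dz = z - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < radii[j] * radii[j]) {
          free_point = false;
          break;
        }
      }
      if (free_point) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * acc / n_points;
  }
  return area;
}
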