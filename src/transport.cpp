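#include <Rcpp.h>
using namespace Rcpp;

// Simplified Monte Carlo photon transport on a voxelized material grid.
// Physics: photoelectric absorption + incoherent (Compton) scattering with
// Klein-Nishina angular sampling. Free paths are sampled by Woodcock
// (delta) tracking against the grid-wide majorant attenuation coefficient.
// Attenuation lookups are linear interpolations of per-material linear
// coefficients tabulated on a uniform energy grid (built in R from the
// shipped log-log table).

static inline double interp_mu(const NumericMatrix& mu, int mat,
                               double e, double emin, double estep, int ne) {
  double x = (e - emin) / estep;
  if (x <= 0) x = 0;
  if (x >= ne - 1) x = ne - 1 - 1e-9;
  int i = (int)x;
  double f = x - i;
  return mu(i, mat) * (1 - f) + mu(i + 1, mat) * f;
}

// Kahn's rejection method for sampling the Klein-Nishina scattering angle.
// Returns cos(theta).
static inline double kn_cos_theta(double e_kev) {
  double a = e_kev / 511.0;
  double r1, r2, r3, x, ct;
  for (;;) {
    r1 = unif_rand(); r2 = unif_rand(); r3 = unif_rand();
    if (r1 <= (1.0 + 2.0 * a) / (9.0 + 2.0 * a)) {
      x = 1.0 + 2.0 * a * r2;                    // x = E/E'
      if (r3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) {
        ct = 1.0 - (x - 1.0) / a;
        return ct;
      }
    } else {
      x = (1.0 + 2.0 * a) / (1.0 + 2.0 * a * r2);
      ct = 1.0 - (x - 1.0) / a;
      if (r3 <= 0.5 * (ct * ct + 1.0 / x)) {
        return ct;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_kn_cos_angles(NumericVector energies) {
  int n = energies.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = kn_cos_theta(energies[i]);
  return out;
}

static inline void rotate_direction(double* d, double ct, double phi) {
  // Rotate unit vector d by polar angle acos(ct) about itself with azimuth phi.
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double cp = std::cos(phi), sp = std::sin(phi);
  double dx = d[0], dy = d[1], dz = d[2];
  double s2 = dx * dx + dy * dy;
  if (s2 > 1e-20) {
    double s = std::sqrt(s2);
    double u0 = dx * dz / s, u1 = dy * dz / s, u2 = -s;   // unit, orthogonal to d
    double v0 = -dy / s, v1 = dx / s;                     // d x u
    d[0] = ct * dx + st * (cp * u0 + sp * v0);
    d[1] = ct * dy + st * (cp * u1 + sp * v1);
    d[2] = ct * dz + st * cp * u2;
  } else {
    double sgn = dz >= 0 ? 1.0 : -1.0;
    d[0] = st * cp;
    d[1] = st * sp;
    d[2] = sgn * ct;
  }
  double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= nrm; d[1] /= nrm; d[2] /= nrm;
}

// [[Rcpp::export]]
List cpp_transport(NumericMatrix positions,   // n x 3 world coords (cm)
                   NumericVector energies,    // keV
                   IntegerVector mat_grid,    // material ids, length nx*ny*nz
                   IntegerVector grid_dim,    // nx, ny, nz
                   NumericVector origin,      // cm
                   double voxel_cm,
                   NumericMatrix mu_pe,       // ne x nmat linear coeffs (1/cm)
                   NumericMatrix mu_inc,
                   double emin, double estep,
                   int max_scatters,
                   double e_cutoff) {
  int n = positions.nrow();
  int nx = grid_dim[0], ny = grid_dim[1], nz = grid_dim[2];
  int ne = mu_pe.nrow(), nmat = mu_pe.ncol();
  double ext_x = nx * voxel_cm, ext_y = ny * voxel_cm, ext_z = nz * voxel_cm;

  // Majorant per energy grid point: max over materials of total mu.
  std::vector<double> maj(ne);
  for (int i = 0; i < ne; ++i) {
    double m = 0;
    for (int j = 0; j < nmat; ++j) {
      double t = mu_pe(i, j) + mu_inc(i, j);
      if (t > m) m = t;
    }
    maj[i] = m;
  }
  NumericMatrix maj_m(ne, 1);
  for (int i = 0; i < ne; ++i) maj_m(i, 0) = maj[i];

  NumericVector out_e(n);
  IntegerVector out_ns(n), out_fate(n);  // fate: 1 escaped, 0 absorbed

  RNGScope scope;
  for (int p = 0; p < n; ++p) {
    double pos[3] = {positions(p, 0) - origin[0],
                     positions(p, 1) - origin[1],
                     positions(p, 2) - origin[2]};
    double e = energies[p];
    // isotropic emission direction
    double dir[3];
    {
      double ct = 2.0 * unif_rand() - 1.0;
      double phi = 2.0 * M_PI * unif_rand();
      double st = std::sqrt(1.0 - ct * ct);
      dir[0] = st * std::cos(phi); dir[1] = st * std::sin(phi); dir[2] = ct;
    }
    int ns = 0;
    int fate = -1;
    for (;;) {
      double mu_maj = interp_mu(maj_m, 0, e, emin, estep, ne);
      if (mu_maj <= 1e-12) { fate = 1; break; }   // effectively vacuum: escape
      // Woodcock flight
      double s = -std::log(unif_rand()) / mu_maj;
      pos[0] += s * dir[0]; pos[1] += s * dir[1]; pos[2] += s * dir[2];
      if (pos[0] < 0 || pos[0] >= ext_x ||
          pos[1] < 0 || pos[1] >= ext_y ||
          pos[2] < 0 || pos[2] >= ext_z) { fate = 1; break; }
      int ix = (int)(pos[0] / voxel_cm);
      int iy = (int)(pos[1] / voxel_cm);
      int iz = (int)(pos[2] / voxel_cm);
      if (ix >= nx) ix = nx - 1;
      if (iy >= ny) iy = ny - 1;
      if (iz >= nz) iz = nz - 1;
      int mat = mat_grid[ix + nx * (iy + (R_xlen_t)ny * iz)];
      if (mat == 0) continue;                      // vacuum: virtual collision
      double mpe = interp_mu(mu_pe, mat, e, emin, estep, ne);
      double minc = interp_mu(mu_inc, mat, e, emin, estep, ne);
      double mtot = mpe + minc;
      if (unif_rand() * mu_maj > mtot) continue;   // virtual collision
      // real interaction
      if (unif_rand() * mtot < mpe) { fate = 0; break; }   // photoelectric
      if (ns >= max_scatters) { fate = 0; break; }          // forced absorption
      double ct = kn_cos_theta(e);
      e = e / (1.0 + (e / 511.0) * (1.0 - ct));
      ++ns;
      if (e < e_cutoff) { fate = 0; break; }
      rotate_direction(dir, ct, 2.0 * M_PI * unif_rand());
    }
    out_e[p] = e;
    out_ns[p] = ns;
    out_fate[p] = fate;
  }
  return List::create(_["energy_kev"] = out_e,
                      _["n_scatters"] = out_ns,
                      _["escaped"] = out_fate);
}

// Mean transmission exp(-integral mu dl) from a set of points to the grid
// boundary along a fixed direction, by fixed-step ray marching. Used by the
// analytic attenuation correction.
// [[Rcpp::export]]
NumericVector cpp_ray_transmission(NumericMatrix points, NumericVector dir,
                                   IntegerVector mat_grid, IntegerVector grid_dim,
                                   NumericVector origin, double voxel_cm,
                                   NumericVector mu_by_material) {
  int n = points.nrow();
  int nx = grid_dim[0], ny = grid_dim[1], nz = grid_dim[2];
  double ext_x = nx * voxel_cm, ext_y = ny * voxel_cm, ext_z = nz * voxel_cm;
  double step = voxel_cm / 4.0;
  NumericVector out(n);
  for (int p = 0; p < n; ++p) {
    double pos[3] = {points(p, 0) - origin[0],
                     points(p, 1) - origin[1],
                     points(p, 2) - origin[2]};
    double acc = 0;
    for (;;) {
      pos[0] += step * dir[0]; pos[1] += step * dir[1]; pos[2] += step * dir[2];
      if (pos[0] < 0 || pos[0] >= ext_x ||
          pos[1] < 0 || pos[1] >= ext_y ||
          pos[2] < 0 || pos[2] >= ext_z) break;
      int ix = (int)(pos[0] / voxel_cm);
      int iy = (int)(pos[1] / voxel_cm);
      int iz = (int)(pos[2] / voxel_cm);
      int mat = mat_grid[ix + nx * (iy + (R_xlen_t)ny * iz)];
      acc += mu_by_material[mat] * step;
    }
    out[p] = std::exp(-acc);
  }
  return out;
}
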