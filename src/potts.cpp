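// 3D Cellular Potts model backend.
//
// Lattice: integer array dim (nx, ny, nz); value 0 = medium, otherwise a
// spin id. Each cell owns up to two spins (cytoplasm, nucleus); spin ->
// cell / compartment / target-volume lookups are passed in as vectors
// indexed by spin id. Hamiltonian: adhesion over 6-connected unordered
// neighbor pairs (out-of-lattice neighbors count as medium) plus an
// elastic volume constraint per spin:
//   H = sum_pairs J(tau_i, tau_j) (1 - delta_{s_i,s_j})
//     + sum_spins lambda (v_s - V_s)^2
// Copy attempts pick a random voxel and a random Moore (26) neighbor as
// source; Metropolis acceptance min(1, exp(-dH/T)). One Monte Carlo step
// (MCS) = nx*ny*nz attempts. All randomness comes from R's RNG so results
// are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Lut {
  const int *cell;
  const int *comp;  // 0 = cytoplasm, 1 = nucleus
  double Jcm, Jcc, Jnc, Jnx;
};

// Adhesion energy of an unordered pair of distinct spins (0 = medium).
inline double Jpair(int a, int b, const Lut &L) {
  if (a == b) return 0.0;
  if (a == 0 || b == 0) {
    int s = (a == 0) ? b : a;
    return L.comp[s - 1] == 0 ? L.Jcm : L.Jnx;
  }
  int ka = L.comp[a - 1], kb = L.comp[b - 1];
  if (ka == 0 && kb == 0) return L.Jcc;
  if (ka == 1 && kb == 1) return L.Jnx;
  return (L.cell[a - 1] == L.cell[b - 1]) ? L.Jnc : L.Jnx;
}

const int VN[6][3] = {{1, 0, 0},  {-1, 0, 0}, {0, 1, 0},
                      {0, -1, 0}, {0, 0, 1},  {0, 0, -1}};

} // namespace

// Total Hamiltonian recomputed from scratch (boundary faces pair with
// medium, matching the delta-energy bookkeeping in cpm_run).
// [[Rcpp::export(name = ".cpm_total_energy")]]
double cpm_total_energy(IntegerVector lattice, IntegerVector spin_cell,
                        IntegerVector spin_comp, NumericVector spin_target,
                        NumericVector spin_vol, double Jcm, double Jcc,
                        double Jnc, double Jnx, double lambda) {
  IntegerVector dim = lattice.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  Lut L{spin_cell.begin(), spin_comp.begin(), Jcm, Jcc, Jnc, Jnx};
  const int *lat = lattice.begin();
  double E = 0.0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int s = lat[x + nx * (y + (R_xlen_t)ny * z)];
        // positive-direction neighbors: each interior pair counted once
        for (int d = 0; d < 6; ++d) {
          int xx = x + VN[d][0], yy = y + VN[d][1], zz = z + VN[d][2];
          bool inside = xx >= 0 && xx < nx && yy >= 0 && yy < ny &&
                        zz >= 0 && zz < nz;
          if (inside) {
            if (d % 2 == 0) { // +x, +y, +z only
              int u = lat[xx + nx * (yy + (R_xlen_t)ny * zz)];
              E += Jpair(s, u, L);
            }
          } else {
            E += Jpair(s, 0, L); // boundary face, counted once
          }
        }
      }
  for (int i = 0; i < spin_vol.size(); ++i) {
    double dv = spin_vol[i] - spin_target[i];
    E += lambda * dv * dv;
  }
  return E;
}

// Run n_mcs Monte Carlo steps. Returns the updated lattice and per-spin
// volumes, the incrementally tracked energy change, and acceptance counts.
// [[Rcpp::export(name = ".cpm_run")]]
List cpm_run(IntegerVector lattice, IntegerVector spin_cell,
             IntegerVector spin_comp, NumericVector spin_target,
             NumericVector spin_vol, double Jcm, double Jcc, double Jnc,
             double Jnx, double lambda, double temp, int n_mcs) {
  IntegerVector dim = lattice.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  IntegerVector lat = clone(lattice);
  NumericVector vol = clone(spin_vol);
  Lut L{spin_cell.begin(), spin_comp.begin(), Jcm, Jcc, Jnc, Jnx};
  int *p = lat.begin();

  // Moore neighborhood offsets
  int MO[26][3];
  {
    int k = 0;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx)
          if (dx || dy || dz) {
            MO[k][0] = dx; MO[k][1] = dy; MO[k][2] = dz; ++k;
          }
  }

  double dE_total = 0.0;
  double n_accept = 0.0;
  RNGScope scope;

  for (int step = 0; step < n_mcs; ++step) {
    for (R_xlen_t a = 0; a < nvox; ++a) {
      R_xlen_t v = (R_xlen_t)(unif_rand() * nvox);
      if (v >= nvox) v = nvox - 1;
      int x = (int)(v % nx);
      int y = (int)((v / nx) % ny);
      int z = (int)(v / ((R_xlen_t)nx * ny));
      int m = (int)(unif_rand() * 26);
      if (m >= 26) m = 25;
      int xx = x + MO[m][0], yy = y + MO[m][1], zz = z + MO[m][2];
      int s; // source spin to copy in
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        s = 0;
      else
        s = p[xx + nx * (yy + (R_xlen_t)ny * zz)];
      int t = p[v];
      if (s == t) continue;

      double dE = 0.0;
      for (int d = 0; d < 6; ++d) {
        int ux = x + VN[d][0], uy = y + VN[d][1], uz = z + VN[d][2];
        int u;
        if (ux < 0 || ux >= nx || uy < 0 || uy >= ny || uz < 0 || uz >= nz)
          u = 0;
        else
          u = p[ux + nx * (uy + (R_xlen_t)ny * uz)];
        dE += Jpair(s, u, L) - Jpair(t, u, L);
      }
      if (s > 0) dE += lambda * (2.0 * (vol[s - 1] - spin_target[s - 1]) + 1.0);
      if (t > 0) dE += lambda * (-2.0 * (vol[t - 1] - spin_target[t - 1]) + 1.0);

      if (dE <= 0.0 || unif_rand() < std::exp(-dE / temp)) {
        p[v] = s;
        if (s > 0) vol[s - 1] += 1.0;
        if (t > 0) vol[t - 1] -= 1.0;
        dE_total += dE;
        n_accept += 1.0;
      }
    }
    if (step % 5 == 4) Rcpp::checkUserInterrupt();
  }

  return List::create(_["lattice"] = lat, _["spin_vol"] = vol,
                      _["delta_energy"] = dE_total,
                      _["n_accept"] = n_accept);
}

// Membrane mask: TRUE at cytoplasm voxels that have a 6-connected neighbor
// (out-of-lattice = medium) belonging to a different cell or to medium.
// [[Rcpp::export(name = ".cpm_membrane")]]
LogicalVector cpm_membrane(IntegerVector lattice, IntegerVector spin_cell,
                           IntegerVector spin_comp) {
  IntegerVector dim = lattice.attr("dim");
  int nx = dim[0], ny = dim[1], nz = dim[2];
  const int *lat = lattice.begin();
  LogicalVector out((R_xlen_t)nx * ny * nz);
  out.attr("dim") = dim;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t v = x + nx * (y + (R_xlen_t)ny * z);
        int s = lat[v];
        if (s == 0 || spin_comp[s - 1] != 0) continue; // not cytoplasm
        int own = spin_cell[s - 1];
        bool memb = false;
        for (int d = 0; d < 6 && !memb; ++d) {
          int xx = x + VN[d][0], yy = y + VN[d][1], zz = z + VN[d][2];
          int u;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            u = 0;
          else
            u = lat[xx + nx * (yy + (R_xlen_t)ny * zz)];
          if (u == 0 || spin_cell[u - 1] != own) memb = true;
        }
        out[v] = memb;
      }
  return out;
}
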