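#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rigid-rod polyamine around a soft-cylinder DNA model.
// All lengths nm, energies in units of kBT (temperature enters only via the
// reduction; the coupling Gamma is a length in kBT*nm per unit-charge pair).
//
// A configuration is (ref, axis): position of bead #1 and the unit vector
// pointing from bead #1 towards the last bead. Bead i sits at
// ref + off[i] * axis with off[i] = (i-1)*d.
//
// Periodicity is axial only: z-distances use the minimum image in a cell of
// height H. The radial wall at R_cyl is a rejecting (infinite) boundary for
// every bead; penetration below R_DNA costs a half-harmonic penalty.

struct System {
  const double* off;      // bead offsets along the rod axis
  const double* qb;       // bead charges
  int n_beads;
  const double* px;       // phosphate coordinates
  const double* py;
  const double* pz;
  double qp;              // phosphate charge
  int n_phos;
  double gamma;           // coupling length, kBT*nm
  double inv_lambda;      // 1/Debye length; 0 = unscreened
  double soft_k;          // kBT/nm^2
  bool hard_core;
  double contact;         // bead-phosphate hard-core contact distance
  double R_DNA;
  double H;
  double R_cyl;
};

static inline double wrap_dz(double dz, double H) {
  return dz - H * std::round(dz / H);
}

// Total energy of one configuration; +Inf encodes a rejected state
// (hard-core overlap or a bead outside the radial wall).
static double total_energy_sys(const System& S,
                               double x0, double y0, double z0,
                               double ux, double uy, double uz) {
  double E = 0.0;
  for (int i = 0; i < S.n_beads; ++i) {
    const double bx = x0 + S.off[i] * ux;
    const double by = y0 + S.off[i] * uy;
    const double bz = z0 + S.off[i] * uz;
    const double rho = std::sqrt(bx * bx + by * by);
    if (rho > S.R_cyl) return R_PosInf;
    if (rho < S.R_DNA) {
      const double pen = S.R_DNA - rho;
      E += 0.5 * S.soft_k * pen * pen;
    }
    const bool charged = (S.qb[i] != 0.0);
    for (int j = 0; j < S.n_phos; ++j) {
      const double dx = bx - S.px[j];
      const double dy = by - S.py[j];
      const double dz = wrap_dz(bz - S.pz[j], S.H);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (S.hard_core && r < S.contact) return R_PosInf;
      if (charged) {
        if (r < 1e-12) return R_PosInf;
        double u = S.gamma * S.qb[i] * S.qp / r;
        if (S.inv_lambda > 0.0) u *= std::exp(-r * S.inv_lambda);
        E += u;
      }
    }
  }
  return E;
}

// All charged beads simultaneously within `cutoff` of at least one phosphate.
static bool bound_sys(const System& S, double cutoff,
                      double x0, double y0, double z0,
                      double ux, double uy, double uz) {
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < S.n_beads; ++i) {
    if (S.qb[i] == 0.0) continue;
    const double bx = x0 + S.off[i] * ux;
    const double by = y0 + S.off[i] * uy;
    const double bz = z0 + S.off[i] * uz;
    bool hit = false;
    for (int j = 0; j < S.n_phos; ++j) {
      const double dx = bx - S.px[j];
      const double dy = by - S.py[j];
      const double dz = wrap_dz(bz - S.pz[j], S.H);
      if (dx * dx + dy * dy + dz * dz <= c2) { hit = true; break; }
    }
    if (!hit) return false;
  }
  return true;
}

static System make_system(NumericVector off, NumericVector qb,
                          NumericMatrix P, double qp, List par) {
  System S;
  S.off = off.begin();
  S.qb = qb.begin();
  S.n_beads = off.size();
  S.n_phos = P.nrow();
  S.px = &P(0, 0);
  S.py = &P(0, 1);
  S.pz = &P(0, 2);
  S.qp = qp;
  S.gamma = as<double>(par["gamma"]);
  double lam = as<double>(par["debye_length"]);
  S.inv_lambda = R_finite(lam) ? 1.0 / lam : 0.0;
  S.soft_k = as<double>(par["soft_k"]);
  S.hard_core = as<bool>(par["hard_core"]);
  S.contact = as<double>(par["contact"]);
  S.R_DNA = as<double>(par["R_DNA"]);
  S.H = as<double>(par["H"]);
  S.R_cyl = as<double>(par["R_cyl"]);
  return S;
}

// [[Rcpp::export]]
double cg_total_energy(NumericVector off, NumericVector qb,
                       NumericMatrix P, double qp, List par,
                       NumericVector ref, NumericVector axis) {
  System S = make_system(off, qb, P, qp, par);
  return total_energy_sys(S, ref[0], ref[1], ref[2], axis[0], axis[1], axis[2]);
}

// [[Rcpp::export]]
NumericVector cg_energy_batch(NumericVector off, NumericVector qb,
                              NumericMatrix P, double qp, List par,
                              NumericMatrix refs, NumericMatrix axes) {
  System S = make_system(off, qb, P, qp, par);
  const int n = refs.nrow();
  NumericVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = total_energy_sys(S, refs(k, 0), refs(k, 1), refs(k, 2),
                              axes(k, 0), axes(k, 1), axes(k, 2));
  return out;
}

// [[Rcpp::export]]
LogicalVector cg_bound_batch(NumericVector off, NumericVector qb,
                             NumericMatrix P, double qp, List par,
                             double cutoff,
                             NumericMatrix refs, NumericMatrix axes) {
  System S = make_system(off, qb, P, qp, par);
  const int n = refs.nrow();
  LogicalVector out(n);
  for (int k = 0; k < n; ++k)
    out[k] = bound_sys(S, cutoff, refs(k, 0), refs(k, 1), refs(k, 2),
                       axes(k, 0), axes(k, 1), axes(k, 2));
  return out;
}

// Streaming midpoint quadrature over the 5-D rigid-body configuration
// space (cylindrical position rho, phi, z; orientation mu = cos theta,
// phiu). Accumulates the Boltzmann-weighted marginal over (r_track, mu)
// without materializing the grid, so resolutions of 1e7+ states stay cheap.
// [[Rcpp::export]]
List cg_quad_marginal(NumericVector off, NumericVector qb,
                      NumericMatrix P, double qp, List par,
                      IntegerVector res, double track_off,
                      NumericVector r_edges, NumericVector mu_edges) {
  System S = make_system(off, qb, P, qp, par);
  const int n_r = res[0], n_phi = res[1], n_z = res[2], n_mu = res[3],
            n_phiu = res[4];
  const double dr = S.R_cyl / n_r, dphi = 2.0 * M_PI / n_phi,
               dz = S.H / n_z, dmu = 2.0 / n_mu,
               dphiu = 2.0 * M_PI / n_phiu;
  const int nbr = r_edges.size() - 1, nbm = mu_edges.size() - 1;
  NumericMatrix bins(nbr, nbm);
  double total = 0.0;
  for (int imu = 0; imu < n_mu; ++imu) {
    const double mu = -1.0 + (imu + 0.5) * dmu;
    const double smu = std::sqrt(std::max(0.0, 1.0 - mu * mu));
    int bm = -1;
    for (int k = 0; k < nbm; ++k)
      if (mu >= mu_edges[k] && mu <= mu_edges[k + 1]) { bm = k; break; }
    for (int iphiu = 0; iphiu < n_phiu; ++iphiu) {
      const double phiu = (iphiu + 0.5) * dphiu;
      const double ux = smu * std::cos(phiu), uy = smu * std::sin(phiu);
      for (int ir = 0; ir < n_r; ++ir) {
        const double rho = (ir + 0.5) * dr;
        const double dV = rho * dr * dphi * dz * dmu * dphiu;
        for (int iphi = 0; iphi < n_phi; ++iphi) {
          const double phi = (iphi + 0.5) * dphi;
          const double x = rho * std::cos(phi), y = rho * std::sin(phi);
          const double rt = std::sqrt(
            (x + track_off * ux) * (x + track_off * ux) +
            (y + track_off * uy) * (y + track_off * uy));
          int br = -1;
          for (int k = 0; k < nbr; ++k)
            if (rt >= r_edges[k] && rt <= r_edges[k + 1]) { br = k; break; }
          for (int iz = 0; iz < n_z; ++iz) {
            const double z = (iz + 0.5) * dz;
            const double E = total_energy_sys(S, x, y, z, ux, uy, mu);
            if (!R_finite(E)) continue;
            const double w = std::exp(-E) * dV;
            total += w;
            if (br >= 0 && bm >= 0) bins(br, bm) += w;
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["bins"] = bins, _["total"] = total);
}

// Metropolis sampler with rigid-body moves. Uses R's RNG so that
// set.seed() in the calling R session makes runs bit-reproducible.
// [[Rcpp::export]]
List cg_run_mc(NumericVector off, NumericVector qb,
               NumericMatrix P, double qp, List par,
               NumericVector init_ref, NumericVector init_axis,
               int n_equil, int n_prod, int stride,
               double max_trans, double max_rot,
               bool tune, double bind_cutoff) {
  System S = make_system(off, qb, P, qp, par);

  double x = init_ref[0], y = init_ref[1], z = init_ref[2];
  double ux = init_axis[0], uy = init_axis[1], uz = init_axis[2];
  double unorm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= unorm; uy /= unorm; uz /= unorm;

  double E = total_energy_sys(S, x, y, z, ux, uy, uz);
  if (!R_finite(E))
    stop("initial configuration has infinite energy (overlap or outside cell)");

  const double L = S.n_beads > 1 ? off[S.n_beads - 1] : 0.0;
  double dt = max_trans, da = max_rot;
  const int tune_win = 2000;
  int win_acc = 0, win_n = 0;
  long n_acc_prod = 0;

  const int n_samp = n_prod / stride;
  NumericMatrix samples(n_samp, 7);
  LogicalVector bound(n_samp);
  int ks = 0;

  RNGScope scope;
  const long n_total = (long)n_equil + (long)n_prod;
  for (long step = 0; step < n_total; ++step) {
    const bool prod = step >= n_equil;
    double nx = x, ny = y, nz = z, nux = ux, nuy = uy, nuz = uz;
    // symmetric proposal mixture: local translation / local rotation plus
    // rare axis flips and uniform reorientations for orientation ergodicity
    const double mv = unif_rand();
    if (mv < 0.45) {
      nx += dt * (2.0 * unif_rand() - 1.0);
      ny += dt * (2.0 * unif_rand() - 1.0);
      nz += dt * (2.0 * unif_rand() - 1.0);
      nz -= S.H * std::floor(nz / S.H);   // keep the reference bead in [0, H)
    } else {
      // rotations pivot about the rod centre so both ends move least
      const double half = 0.5 * L;
      const double cxx = x + half * ux, cyy = y + half * uy,
                   czz = z + half * uz;
      if (mv < 0.90) {
        // local rotation: random axis uniform on the sphere, Rodrigues
        const double cz = 2.0 * unif_rand() - 1.0;
        const double sphi = 2.0 * M_PI * unif_rand();
        const double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
        const double kx = sz * std::cos(sphi), ky = sz * std::sin(sphi),
                     kz = cz;
        const double ang = da * (2.0 * unif_rand() - 1.0);
        const double ca = std::cos(ang), sa = std::sin(ang);
        const double kd = kx * ux + ky * uy + kz * uz;
        nux = ux * ca + (ky * uz - kz * uy) * sa + kx * kd * (1.0 - ca);
        nuy = uy * ca + (kz * ux - kx * uz) * sa + ky * kd * (1.0 - ca);
        nuz = uz * ca + (kx * uy - ky * ux) * sa + kz * kd * (1.0 - ca);
        const double nn = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
        nux /= nn; nuy /= nn; nuz /= nn;
      } else if (mv < 0.95) {
        // end-for-end flip: the bead position set is unchanged, only the
        // charge labels move (exact for symmetric rods)
        nux = -ux; nuy = -uy; nuz = -uz;
      } else {
        // uniform reorientation about the centre
        const double cz = 2.0 * unif_rand() - 1.0;
        const double sphi = 2.0 * M_PI * unif_rand();
        const double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
        nux = sz * std::cos(sphi); nuy = sz * std::sin(sphi); nuz = cz;
      }
      nx = cxx - half * nux; ny = cyy - half * nuy; nz = czz - half * nuz;
      nz -= S.H * std::floor(nz / S.H);
    }
    const double En = total_energy_sys(S, nx, ny, nz, nux, nuy, nuz);
    bool acc = false;
    if (R_finite(En)) {
      const double dE = En - E;
      acc = (dE <= 0.0) || (unif_rand() < std::exp(-dE));
    }
    if (acc) {
      x = nx; y = ny; z = nz; ux = nux; uy = nuy; uz = nuz; E = En;
      ++win_acc;
      if (prod) ++n_acc_prod;
    }
    ++win_n;
    if (!prod && tune && win_n == tune_win) {
      const double rate = (double)win_acc / win_n;
      if (rate > 0.5) { dt *= 1.2; da *= 1.2; }
      else if (rate < 0.3) { dt /= 1.2; da /= 1.2; }
      dt = std::min(std::max(dt, 0.01), 1.0);
      da = std::min(std::max(da, 0.02), 1.5);
      win_acc = 0; win_n = 0;
    }
    if (step == (long)n_equil - 1) { win_acc = 0; win_n = 0; }  // freeze steps
    if (prod && ((step - n_equil + 1) % stride == 0) && ks < n_samp) {
      samples(ks, 0) = x; samples(ks, 1) = y; samples(ks, 2) = z;
      samples(ks, 3) = ux; samples(ks, 4) = uy; samples(ks, 5) = uz;
      samples(ks, 6) = E;
      bound[ks] = bound_sys(S, bind_cutoff, x, y, z, ux, uy, uz);
      ++ks;
    }
  }

  return List::create(
    _["samples"] = samples,
    _["bound"] = bound,
    _["acceptance"] = (double)n_acc_prod / n_prod,
    _["max_trans"] = dt,
    _["max_rot"] = da);
}
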