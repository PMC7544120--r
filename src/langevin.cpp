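#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Underdamped Langevin dynamics (BAOAB splitting) for a short bead-spring
// polymer: harmonic bonds, capped soft-core repulsion on non-bonded pairs,
// a weak tanh collapse attraction, and (chromatin-like model only) an extra
// tanh attraction between beads in the same half of the chain.
//
// Uses R's RNG so trajectories are reproducible under set.seed().

struct Params {
  int n;
  double bond_k, bond_r0;
  double lj_d, lj_eps, lj_cut, cap;
  double alpha, eta, rc;
  double alpha_spec;
  int split;           // 0-based index of first bead of the second half
  double dt, gamma, T;
  bool chromatin;
};

static void compute_forces(const std::vector<double>& x,
                           const std::vector<double>& y,
                           const std::vector<double>& z,
                           std::vector<double>& fx,
                           std::vector<double>& fy,
                           std::vector<double>& fz,
                           const Params& p) {
  const int n = p.n;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);

  // bonds
  for (int i = 0; i < n - 1; ++i) {
    double dxv = x[i + 1] - x[i], dyv = y[i + 1] - y[i], dzv = z[i + 1] - z[i];
    double r = std::sqrt(dxv * dxv + dyv * dyv + dzv * dzv);
    if (r < 1e-12) continue;
    double dudr = 2.0 * p.bond_k * (r - p.bond_r0);
    double fac = -dudr / r;
    fx[i] -= fac * dxv; fy[i] -= fac * dyv; fz[i] -= fac * dzv;
    fx[i + 1] += fac * dxv; fy[i + 1] += fac * dyv; fz[i + 1] += fac * dzv;
  }

  // non-bonded pairs |i-j| >= 2
  for (int i = 0; i < n - 2; ++i) {
    for (int j = i + 2; j < n; ++j) {
      double dxv = x[j] - x[i], dyv = y[j] - y[i], dzv = z[j] - z[i];
      double r2 = dxv * dxv + dyv * dyv + dzv * dzv;
      double r = std::sqrt(r2);
      double dudr = 0.0;

      if (r < p.lj_cut && r > 1e-12) {
        double s2 = (p.lj_d * p.lj_d) / r2;
        double s6 = s2 * s2 * s2;
        double ulj = 4.0 * p.lj_eps * (s6 * s6 - s6) + p.lj_eps;
        double dulj = (24.0 * p.lj_eps * s6 - 48.0 * p.lj_eps * s6 * s6) / r;
        double targ = std::tanh(ulj / p.cap);
        dudr += (1.0 - targ * targ) * dulj;
      }

      double a = p.alpha;
      if (p.chromatin && ((i < p.split && j < p.split) ||
                          (i >= p.split && j >= p.split)))
        a += p.alpha_spec;
      if (a != 0.0) {
        double t = std::tanh(p.eta * (p.rc - r));
        dudr += -(a / 2.0) * p.eta * (1.0 - t * t);
      }

      if (r > 1e-12) {
        double fac = -dudr / r;
        fx[i] -= fac * dxv; fy[i] -= fac * dyv; fz[i] -= fac * dzv;
        fx[j] += fac * dxv; fy[j] += fac * dyv; fz[j] += fac * dzv;
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_langevin(NumericMatrix coords0, List par, int n_steps, int save_every,
                  int equil_steps, bool chromatin) {
  Params p;
  p.n = coords0.nrow();
  p.bond_k = as<double>(par["bond_k"]);
  p.bond_r0 = as<double>(par["bond_r0"]);
  p.lj_d = as<double>(par["lj_diameter"]);
  p.lj_eps = as<double>(par["lj_eps"]);
  p.lj_cut = std::pow(2.0, 1.0 / 6.0) * p.lj_d;
  p.cap = as<double>(par["softcore_cap"]);
  p.alpha = as<double>(par["collapse_alpha"]);
  p.eta = as<double>(par["collapse_eta"]);
  p.rc = as<double>(par["collapse_rc"]);
  p.alpha_spec = as<double>(par["specific_alpha"]);
  p.split = as<int>(par["domain_split"]);
  p.dt = as<double>(par["timestep"]);
  p.gamma = as<double>(par["damping"]);
  p.T = as<double>(par["temperature"]);
  p.chromatin = chromatin;

  const int n = p.n;
  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  std::vector<double> fx(n), fy(n), fz(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords0(i, 0); y[i] = coords0(i, 1); z[i] = coords0(i, 2);
  }
  // Maxwell-Boltzmann initial velocities (mass = 1)
  double sv = std::sqrt(p.T);
  for (int i = 0; i < n; ++i) {
    vx[i] = sv * norm_rand(); vy[i] = sv * norm_rand(); vz[i] = sv * norm_rand();
  }

  const double friction = 1.0 / p.gamma;
  const double c1 = std::exp(-friction * p.dt);
  const double c2 = std::sqrt(p.T * (1.0 - c1 * c1));
  const double hdt = 0.5 * p.dt;

  compute_forces(x, y, z, fx, fy, fz, p);

  int n_frames = n_steps / save_every;
  List frames(n_frames);
  NumericVector kinetic(n_frames);
  int frame = 0;
  long total = (long)equil_steps + n_steps;

  for (long step = 1; step <= total; ++step) {
    for (int i = 0; i < n; ++i) {          // B
      vx[i] += hdt * fx[i]; vy[i] += hdt * fy[i]; vz[i] += hdt * fz[i];
    }
    for (int i = 0; i < n; ++i) {          // A
      x[i] += hdt * vx[i]; y[i] += hdt * vy[i]; z[i] += hdt * vz[i];
    }
    for (int i = 0; i < n; ++i) {          // O
      vx[i] = c1 * vx[i] + c2 * norm_rand();
      vy[i] = c1 * vy[i] + c2 * norm_rand();
      vz[i] = c1 * vz[i] + c2 * norm_rand();
    }
    for (int i = 0; i < n; ++i) {          // A
      x[i] += hdt * vx[i]; y[i] += hdt * vy[i]; z[i] += hdt * vz[i];
    }
    compute_forces(x, y, z, fx, fy, fz, p);
    for (int i = 0; i < n; ++i) {          // B
      vx[i] += hdt * fx[i]; vy[i] += hdt * fy[i]; vz[i] += hdt * fz[i];
    }

    if (!R_FINITE(x[0])) stop("Langevin integration diverged at step %ld", step);

    long prod = step - equil_steps;
    if (prod > 0 && prod % save_every == 0) {
      if (!R_FINITE(x[n - 1]))
        stop("Langevin integration diverged at step %ld", step);
      NumericMatrix fr(n, 3);
      double ke = 0.0;
      for (int i = 0; i < n; ++i) {
        fr(i, 0) = x[i]; fr(i, 1) = y[i]; fr(i, 2) = z[i];
        ke += 0.5 * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      }
      kinetic[frame] = ke;
      frames[frame++] = fr;
    }
  }
  return List::create(_["frames"] = frames, _["kinetic"] = kinetic);
}
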