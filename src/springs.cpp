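#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Harmonic spring-lattice kernels.  Bonds use E = k (r - r0)^2, angles use
// E = k (phi - phi0)^2 with phi in radians (the LAMMPS "harmonic" styles,
// which fold the conventional 1/2 into k).  Per-node energies split each
// interaction equally among its 2 (bond) or 3 (angle) participants.

static inline double clamp1(double x) {
  if (x > 1.0) return 1.0;
  if (x < -1.0) return -1.0;
  return x;
}

// Accumulate energy (total + per node) and, if F is non-null, forces.
static double eval_lattice(const NumericMatrix& pos,
                           const IntegerMatrix& bonds,
                           const NumericVector& bond_k,
                           const NumericVector& bond_r0,
                           const IntegerMatrix& angles,
                           const NumericVector& angle_k,
                           const NumericVector& angle_phi0,
                           double* per_node, double* F) {
  const int n = pos.nrow();
  double total = 0.0;
  if (per_node) std::fill(per_node, per_node + n, 0.0);

  const int nb = bonds.nrow();
  for (int b = 0; b < nb; ++b) {
    const int i = bonds(b, 0), j = bonds(b, 1);
    double d[3], r2 = 0.0;
    for (int c = 0; c < 3; ++c) { d[c] = pos(i, c) - pos(j, c); r2 += d[c] * d[c]; }
    double r = std::sqrt(r2);
    if (r < 1e-12) stop("zero-length bond between nodes %d and %d", i + 1, j + 1);
    double dr = r - bond_r0[b];
    double e = bond_k[b] * dr * dr;
    total += e;
    if (per_node) { per_node[i] += 0.5 * e; per_node[j] += 0.5 * e; }
    if (F) {
      double fac = -2.0 * bond_k[b] * dr / r;  // force on i along d
      for (int c = 0; c < 3; ++c) {
        F[i + c * n] += fac * d[c];
        F[j + c * n] -= fac * d[c];
      }
    }
  }

  const int na = angles.nrow();
  for (int a = 0; a < na; ++a) {
    const int i = angles(a, 0), j = angles(a, 1), k = angles(a, 2);  // vertex j
    double v1[3], v2[3], r1 = 0.0, r2 = 0.0, dot = 0.0;
    for (int c = 0; c < 3; ++c) {
      v1[c] = pos(i, c) - pos(j, c);
      v2[c] = pos(k, c) - pos(j, c);
      r1 += v1[c] * v1[c]; r2 += v2[c] * v2[c];
      dot += v1[c] * v2[c];
    }
    r1 = std::sqrt(r1); r2 = std::sqrt(r2);
    if (r1 < 1e-12 || r2 < 1e-12)
      stop("degenerate angle (zero-length arm) at vertex %d", j + 1);
    double cth = clamp1(dot / (r1 * r2));
    double phi = std::acos(cth);
    double dphi = phi - angle_phi0[a];
    double e = angle_k[a] * dphi * dphi;
    total += e;
    if (per_node) {
      double e3 = e / 3.0;
      per_node[i] += e3; per_node[j] += e3; per_node[k] += e3;
    }
    if (F) {
      double s = std::sqrt(1.0 - cth * cth);
      if (s < 1e-8) s = 1e-8;  // colinear guard: torque ~ dphi -> 0 at rest
      double coef = 2.0 * angle_k[a] * dphi / s;
      for (int c = 0; c < 3; ++c) {
        // d cth / d v1 = v2/(r1 r2) - cth v1/r1^2 ; dphi/dv = -dcth/dv / s
        double g1 = (v2[c] / (r1 * r2) - cth * v1[c] / (r1 * r1));
        double g2 = (v1[c] / (r1 * r2) - cth * v2[c] / (r2 * r2));
        double fi = coef * g1;          // -dE/dpos_i
        double fk = coef * g2;
        F[i + c * n] += fi;
        F[k + c * n] += fk;
        F[j + c * n] -= (fi + fk);
      }
    }
  }
  return total;
}

// [[Rcpp::export]]
List lattice_energy_cpp(NumericMatrix pos, IntegerMatrix bonds,
                        NumericVector bond_k, NumericVector bond_r0,
                        IntegerMatrix angles, NumericVector angle_k,
                        NumericVector angle_phi0) {
  std::vector<double> pn(pos.nrow());
  double tot = eval_lattice(pos, bonds, bond_k, bond_r0, angles, angle_k,
                            angle_phi0, pn.data(), nullptr);
  return List::create(_["total"] = tot,
                      _["per_node"] = NumericVector(pn.begin(), pn.end()));
}

// [[Rcpp::export]]
NumericMatrix lattice_forces_cpp(NumericMatrix pos, IntegerMatrix bonds,
                                 NumericVector bond_k, NumericVector bond_r0,
                                 IntegerMatrix angles, NumericVector angle_k,
                                 NumericVector angle_phi0) {
  NumericMatrix F(pos.nrow(), 3);
  eval_lattice(pos, bonds, bond_k, bond_r0, angles, angle_k, angle_phi0,
               nullptr, F.begin());
  return F;
}

// Langevin dynamics by velocity Verlet with friction -gamma*m*v and Gaussian
// thermal kicks of variance 2*gamma*m*kT/dt per component (uses R's RNG, so
// set.seed() governs reproducibility).  Clamped nodes are pinned; an external
// force along `fdir` is applied to `forced` nodes, ramped linearly over
// `ramp_steps` then held.  Frames (positions, velocities, per-node energy)
// are recorded every `save_every` steps.
// [[Rcpp::export]]
List langevin_run_cpp(NumericMatrix pos0, NumericMatrix vel0,
                      IntegerMatrix bonds, NumericVector bond_k,
                      NumericVector bond_r0, IntegerMatrix angles,
                      NumericVector angle_k, NumericVector angle_phi0,
                      double mass, double dt, double gamma, double kT,
                      int total_steps, int ramp_steps, int step_offset,
                      int save_every, NumericVector fdir, double fmax,
                      IntegerVector clamped, IntegerVector forced) {
  const int n = pos0.nrow();
  NumericMatrix pos = clone(pos0), vel = clone(vel0);
  NumericMatrix F(n, 3), Fnew(n, 3);
  const double sig = (kT > 0.0) ? std::sqrt(2.0 * gamma * mass * kT / dt) : 0.0;

  std::vector<char> is_clamped(n, 0);
  for (int i = 0; i < clamped.size(); ++i) is_clamped[clamped[i]] = 1;

  List frames;
  RNGScope scope;

  // external + friction + noise, added onto conservative forces in Fd
  auto add_env_forces = [&](NumericMatrix& Fd, int step) {
    double scale = 1.0;
    if (ramp_steps > 0) {
      double g = (double)(step_offset + step) / ramp_steps;
      scale = g < 1.0 ? g : 1.0;
    }
    double fmag = fmax * scale;
    for (int t = 0; t < forced.size(); ++t) {
      int i = forced[t];
      for (int c = 0; c < 3; ++c) Fd(i, c) += fmag * fdir[c];
    }
    for (int i = 0; i < n; ++i) {
      if (is_clamped[i]) continue;
      for (int c = 0; c < 3; ++c) {
        Fd(i, c) -= gamma * mass * vel(i, c);
        if (sig > 0.0) Fd(i, c) += sig * norm_rand();
      }
    }
  };

  eval_lattice(pos, bonds, bond_k, bond_r0, angles, angle_k, angle_phi0,
               nullptr, F.begin());
  add_env_forces(F, 0);

  for (int step = 1; step <= total_steps; ++step) {
    for (int i = 0; i < n; ++i) {
      if (is_clamped[i]) continue;
      for (int c = 0; c < 3; ++c) {
        double acc = F(i, c) / mass;
        pos(i, c) += dt * vel(i, c) + 0.5 * dt * dt * acc;
      }
    }
    std::fill(Fnew.begin(), Fnew.end(), 0.0);
    eval_lattice(pos, bonds, bond_k, bond_r0, angles, angle_k, angle_phi0,
                 nullptr, Fnew.begin());
    add_env_forces(Fnew, step);
    for (int i = 0; i < n; ++i) {
      if (is_clamped[i]) { for (int c = 0; c < 3; ++c) vel(i, c) = 0.0; continue; }
      for (int c = 0; c < 3; ++c)
        vel(i, c) += 0.5 * dt * (F(i, c) + Fnew(i, c)) / mass;
    }
    F = clone(Fnew);

    bool finite = true;
    for (int i = 0; i < n && finite; ++i)
      for (int c = 0; c < 3; ++c)
        if (!std::isfinite(pos(i, c))) { finite = false; break; }
    if (!finite) stop("simulation diverged (non-finite positions) at step %d", step);

    if (save_every > 0 && step % save_every == 0) {
      std::vector<double> pn(n);
      double tot = eval_lattice(pos, bonds, bond_k, bond_r0, angles, angle_k,
                                angle_phi0, pn.data(), nullptr);
      frames.push_back(List::create(
          _["step"] = step,
          _["positions"] = clone(pos),
          _["velocities"] = clone(vel),
          _["forces"] = clone(F),
          _["energy_total"] = tot,
          _["energy_per_node"] = NumericVector(pn.begin(), pn.end())));
    }
  }
  return List::create(_["frames"] = frames, _["positions"] = pos,
                      _["velocities"] = vel);
}
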