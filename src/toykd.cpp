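#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic, platform-independent RNG: splitmix64 stream + polar-free
// Box-Muller. std::*_distribution is implementation-defined, so raw bit
// manipulation is used throughout to keep trajectories bit-reproducible.
struct ToyRng {
  uint64_t state;
  bool has_spare;
  double spare;
  explicit ToyRng(uint64_t seed) : state(seed), has_spare(false), spare(0.0) {}
  uint64_t next_u64() {
    uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  // uniform in (0, 1): never exactly 0 (log-safe)
  double unif() {
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 2.0 * M_PI * u2;
    spare = r * std::sin(th);
    has_spare = true;
    return r * std::cos(th);
  }
};

static const double KCOUL = 332.0636;  // kcal A / (mol e^2)
static const double R_ON = 7.5, R_OFF = 9.0;

// switching factor and its r-derivative; smoothstep 1 -> 0 over [R_ON, R_OFF]
static inline void switch_fn(double r, double &s, double &dsdr) {
  if (r <= R_ON) { s = 1.0; dsdr = 0.0; return; }
  if (r >= R_OFF) { s = 0.0; dsdr = 0.0; return; }
  double w = R_OFF - R_ON;
  double u = (r - R_ON) / w;
  s = 1.0 - u * u * (3.0 - 2.0 * u);
  dsdr = -6.0 * u * (1.0 - u) / w;
}

struct ToyField {
  NumericMatrix rec_xyz;     // n_rec x 3, fixed
  NumericVector rec_q, rec_eps, rec_sig;
  NumericVector lig_q, lig_eps, lig_sig, lig_m;
  IntegerMatrix bonds;       // n_bond x 2, 0-based ligand bead indices
  NumericVector bond_r0;
  double k_bond;
  double box_half;
};

// receptor-ligand nonbonded + intra-ligand restraint energy and forces.
// pos/frc are n_lig x 3. Returns total potential; fills ele/vdw if asked.
static double eval_force(const ToyField &ff, const NumericMatrix &pos,
                         NumericMatrix &frc, double *ele_out, double *vdw_out) {
  int n_lig = pos.nrow(), n_rec = ff.rec_xyz.nrow();
  double ele = 0.0, vdw = 0.0, bond = 0.0;
  std::fill(frc.begin(), frc.end(), 0.0);
  for (int i = 0; i < n_rec; ++i) {
    for (int j = 0; j < n_lig; ++j) {
      double dx = pos(j, 0) - ff.rec_xyz(i, 0);
      double dy = pos(j, 1) - ff.rec_xyz(i, 1);
      double dz = pos(j, 2) - ff.rec_xyz(i, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= R_OFF * R_OFF) continue;
      double r = std::sqrt(r2);
      double s, dsdr;
      switch_fn(r, s, dsdr);
      double qq = KCOUL * ff.rec_q[i] * ff.lig_q[j];
      double e_ele = qq / r, de_ele = -qq / r2;
      double sig = 0.5 * (ff.rec_sig[i] + ff.lig_sig[j]);
      double eps = std::sqrt(ff.rec_eps[i] * ff.lig_eps[j]);
      double sr2 = sig * sig / r2;
      double sr6 = sr2 * sr2 * sr2;
      double e_vdw = 4.0 * eps * (sr6 * sr6 - sr6);
      double de_vdw = 24.0 * eps * (sr6 - 2.0 * sr6 * sr6) / r;
      ele += e_ele * s;
      vdw += e_vdw * s;
      double dEdr = (de_ele + de_vdw) * s + (e_ele + e_vdw) * dsdr;
      double g = -dEdr / r;  // force on ligand bead j along (pos - rec)
      frc(j, 0) += g * dx;
      frc(j, 1) += g * dy;
      frc(j, 2) += g * dz;
    }
  }
  for (int b = 0; b < ff.bonds.nrow(); ++b) {
    int i = ff.bonds(b, 0), j = ff.bonds(b, 1);
    double dx = pos(j, 0) - pos(i, 0);
    double dy = pos(j, 1) - pos(i, 1);
    double dz = pos(j, 2) - pos(i, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - ff.bond_r0[b];
    bond += 0.5 * ff.k_bond * dr * dr;
    double g = -ff.k_bond * dr / r;
    frc(j, 0) += g * dx; frc(j, 1) += g * dy; frc(j, 2) += g * dz;
    frc(i, 0) -= g * dx; frc(i, 1) -= g * dy; frc(i, 2) -= g * dz;
  }
  if (ele_out) *ele_out = ele;
  if (vdw_out) *vdw_out = vdw;
  return ele + vdw + bond;
}

static ToyField make_field(List field) {
  ToyField ff;
  ff.rec_xyz = as<NumericMatrix>(field["rec_xyz"]);
  ff.rec_q = as<NumericVector>(field["rec_q"]);
  ff.rec_eps = as<NumericVector>(field["rec_eps"]);
  ff.rec_sig = as<NumericVector>(field["rec_sig"]);
  ff.lig_q = as<NumericVector>(field["lig_q"]);
  ff.lig_eps = as<NumericVector>(field["lig_eps"]);
  ff.lig_sig = as<NumericVector>(field["lig_sig"]);
  ff.lig_m = as<NumericVector>(field["lig_m"]);
  ff.bonds = as<IntegerMatrix>(field["bonds"]);
  ff.bond_r0 = as<NumericVector>(field["bond_r0"]);
  ff.k_bond = as<double>(field["k_bond"]);
  ff.box_half = as<double>(field["box_half"]);
  return ff;
}

// [[Rcpp::export(name = ".cpp_potential")]]
List cpp_potential(List field, NumericMatrix pos) {
  ToyField ff = make_field(field);
  NumericMatrix frc(pos.nrow(), 3);
  double ele, vdw;
  double tot = eval_force(ff, pos, frc, &ele, &vdw);
  return List::create(_["ele"] = ele, _["vdw"] = vdw,
                      _["bond"] = tot - ele - vdw, _["total"] = tot,
                      _["force"] = frc);
}

static inline void reflect(NumericMatrix &pos, NumericMatrix &vel, double L) {
  for (int j = 0; j < pos.nrow(); ++j)
    for (int k = 0; k < 3; ++k) {
      double x = pos(j, k);
      if (x > L) { pos(j, k) = 2.0 * L - x; vel(j, k) = -vel(j, k); }
      else if (x < -L) { pos(j, k) = -2.0 * L - x; vel(j, k) = -vel(j, k); }
    }
}

// BAOAB Langevin propagation of the ligand in the fixed receptor field.
// Saves frame 0 and every save_every-th step; returns per-frame positions.
// [[Rcpp::export(name = ".cpp_run_md")]]
List cpp_run_md(List field, NumericMatrix pos0, NumericMatrix vel0,
                int n_steps, double dt, double gamma, double temperature,
                double seed, int save_every) {
  ToyField ff = make_field(field);
  const double kB = 0.001987204259;
  int n_lig = pos0.nrow();
  NumericMatrix pos = clone(pos0), vel = clone(vel0), frc(n_lig, 3);
  ToyRng rng((uint64_t)seed);
  double c1 = std::exp(-gamma * dt);
  double c2 = std::sqrt(1.0 - c1 * c1);
  double kT = kB * temperature;
  int n_frames = n_steps / save_every + 1;
  NumericVector frames(Dimension(n_frames, n_lig, 3));
  NumericVector ke(n_frames);
  auto save_frame = [&](int f) {
    double k = 0.0;
    for (int j = 0; j < n_lig; ++j)
      for (int d = 0; d < 3; ++d) {
        frames[f + n_frames * (j + n_lig * d)] = pos(j, d);
        k += 0.5 * ff.lig_m[j] * vel(j, d) * vel(j, d);
      }
    ke[f] = k;
  };
  eval_force(ff, pos, frc, nullptr, nullptr);
  save_frame(0);
  int f = 1;
  for (int step = 1; step <= n_steps; ++step) {
    for (int j = 0; j < n_lig; ++j)
      for (int d = 0; d < 3; ++d)
        vel(j, d) += 0.5 * dt * frc(j, d) / ff.lig_m[j];
    for (int j = 0; j < n_lig; ++j)
      for (int d = 0; d < 3; ++d)
        pos(j, d) += 0.5 * dt * vel(j, d);
    for (int j = 0; j < n_lig; ++j) {
      double sd = std::sqrt(kT / ff.lig_m[j]);
      for (int d = 0; d < 3; ++d)
        vel(j, d) = c1 * vel(j, d) + c2 * sd * rng.norm();
    }
    for (int j = 0; j < n_lig; ++j)
      for (int d = 0; d < 3; ++d)
        pos(j, d) += 0.5 * dt * vel(j, d);
    reflect(pos, vel, ff.box_half);
    eval_force(ff, pos, frc, nullptr, nullptr);
    for (int j = 0; j < n_lig; ++j)
      for (int d = 0; d < 3; ++d) {
        vel(j, d) += 0.5 * dt * frc(j, d) / ff.lig_m[j];
        if (!std::isfinite(pos(j, d)) || !std::isfinite(vel(j, d)))
          stop("integration blow-up at step %d (bead %d)", step, j + 1);
      }
    if (step % save_every == 0) save_frame(f++);
  }
  return List::create(_["frames"] = frames, _["kinetic"] = ke,
                      _["pos"] = pos, _["vel"] = vel);
}

// FIRE relaxation (fast inertial relaxation engine); used to settle
// generated native poses into a bona fide local minimum of the toy field.
// Per-step displacement is capped at 0.1 A so the descent stays in the
// basin of the starting arrangement.
// [[Rcpp::export(name = ".cpp_minimize")]]
List cpp_minimize(List field, NumericMatrix pos0, int max_iter, double tol,
                  Nullable<LogicalVector> free_beads = R_NilValue) {
  ToyField ff = make_field(field);
  int n = pos0.nrow();
  LogicalVector freeb = free_beads.isNull() ? LogicalVector(n, true)
                                            : LogicalVector(free_beads);
  NumericMatrix pos = clone(pos0), frc(n, 3);
  NumericMatrix vel(n, 3);
  double e = eval_force(ff, pos, frc, nullptr, nullptr);
  const double dt_max = 0.05, f_inc = 1.1, f_dec = 0.5, a_start = 0.1;
  double dt = 0.005, alpha = a_start;
  int n_pos = 0;
  for (int it = 0; it < max_iter; ++it) {
    double gmax = 0.0, p = 0.0, vnorm = 0.0, fnorm = 0.0;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        if (!freeb[i]) { vel(i, d) = 0.0; continue; }
        gmax = std::max(gmax, std::fabs(frc(i, d)));
        p += vel(i, d) * frc(i, d);
        vnorm += vel(i, d) * vel(i, d);
        fnorm += frc(i, d) * frc(i, d);
      }
    if (gmax < tol) break;
    vnorm = std::sqrt(vnorm); fnorm = std::sqrt(fnorm);
    if (p > 0.0) {
      if (++n_pos > 5) { dt = std::min(dt * f_inc, dt_max); alpha *= 0.99; }
      if (fnorm > 0.0)
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d)
            if (freeb[i])
              vel(i, d) = (1.0 - alpha) * vel(i, d) +
                          alpha * vnorm * frc(i, d) / fnorm;
    } else {
      n_pos = 0; dt *= f_dec; alpha = a_start;
      std::fill(vel.begin(), vel.end(), 0.0);
    }
    double dmax = 0.0;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        if (freeb[i]) {
          vel(i, d) += dt * frc(i, d);
          dmax = std::max(dmax, std::fabs(dt * vel(i, d)));
        }
    double scale = dmax > 0.1 ? 0.1 / dmax : 1.0;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d)
        if (freeb[i]) pos(i, d) += scale * dt * vel(i, d);
    e = eval_force(ff, pos, frc, nullptr, nullptr);
  }
  return List::create(_["pos"] = pos, _["energy"] = e);
}
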