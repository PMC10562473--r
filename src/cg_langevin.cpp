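// One-bead-per-residue Langevin dynamics: harmonic bonds, screened Coulomb,
// and a hydrophobicity-scaled short-range pair potential (plain LJ as the
// default, Ashbaugh-Hatch split as an option). BAOAB discretisation.
// Units: nm, ps, kJ/mol, g/mol; charges in e.
#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

struct Params {
  double kbond, r0;          // bond constant (kJ/mol/nm^2), length (nm)
  double coul_k;             // Coulomb prefactor incl. dielectric (kJ nm/mol)
  double debye;              // screening length (nm)
  double rc_coul;            // Coulomb cutoff (nm)
  double eps_lj;             // LJ well depth (kJ/mol)
  double lj_cut_sigmas;      // pair cutoff in units of sigma_ij
  bool use_lj, use_coul, ashbaugh;
};

static inline double lj_pair(double r2, double sig, double lam, double eps,
                             bool ashbaugh, double rc, double &dVdr_over_r) {
  // returns V(r) (unshifted) and dV/dr / r
  double sr2 = sig * sig / r2;
  double sr6 = sr2 * sr2 * sr2;
  double sr12 = sr6 * sr6;
  double v = 4.0 * eps * (sr12 - sr6);
  double dv = 4.0 * eps * (-12.0 * sr12 + 6.0 * sr6) / r2; // dV/dr / r
  if (!ashbaugh) {
    dVdr_over_r = lam * dv;
    return lam * v;
  }
  double rmin2 = std::pow(2.0, 1.0 / 3.0) * sig * sig;
  if (r2 <= rmin2) {
    dVdr_over_r = dv;
    return v + (1.0 - lam) * eps;
  }
  dVdr_over_r = lam * dv;
  return lam * v;
}

static void compute_forces(const std::vector<double> &x,
                           const std::vector<double> &q,
                           const NumericMatrix &lam,
                           const NumericMatrix &sig,
                           const NumericMatrix &restraints,
                           const Params &P, int N,
                           std::vector<double> &f,
                           double *ebond, double *ecoul, double *elj) {
  std::fill(f.begin(), f.end(), 0.0);
  double eb = 0, ec = 0, el = 0;
  // bonds
  for (int i = 0; i + 1 < N; ++i) {
    double dx = x[3 * i] - x[3 * (i + 1)];
    double dy = x[3 * i + 1] - x[3 * (i + 1) + 1];
    double dz = x[3 * i + 2] - x[3 * (i + 1) + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - P.r0;
    eb += 0.5 * P.kbond * dr * dr;
    double fr = -P.kbond * dr / r;
    f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
    f[3 * (i + 1)] -= fr * dx; f[3 * (i + 1) + 1] -= fr * dy;
    f[3 * (i + 1) + 2] -= fr * dz;
  }
  // elastic-network restraints (optional): rows (i, j, r0, k), 1-based idx
  for (int r_ = 0; r_ < restraints.nrow(); ++r_) {
    int i = (int)restraints(r_, 0) - 1, j = (int)restraints(r_, 1) - 1;
    double rr0 = restraints(r_, 2), kk = restraints(r_, 3);
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - rr0;
    eb += 0.5 * kk * dr * dr;
    double fr = -kk * dr / r;
    f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
    f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
  }
  if (!P.use_lj && !P.use_coul) { *ebond = eb; *ecoul = ec; *elj = el; return; }
  double rc_coul2 = P.rc_coul * P.rc_coul;
  // shifted potentials: subtract V(rc)
  double coul_shift_base = std::exp(-P.rc_coul / P.debye) / P.rc_coul;
  double sig_max = 0.0;
  if (P.use_lj) {
    for (int i = 0; i < N; ++i)
      for (int j = i + 2; j < N; ++j)
        if (sig(i, j) > sig_max) sig_max = sig(i, j);
  }
  double rc_max = P.use_coul ? P.rc_coul : 0.0;
  if (P.use_lj && P.lj_cut_sigmas * sig_max > rc_max)
    rc_max = P.lj_cut_sigmas * sig_max;
  double rc_max2 = rc_max * rc_max;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 2; j < N; ++j) {   // 1-2 pairs excluded
      double dx = x[3 * i] - x[3 * j];
      double dy = x[3 * i + 1] - x[3 * j + 1];
      double dz = x[3 * i + 2] - x[3 * j + 2];
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 > rc_max2) continue;
      double fr = 0.0;
      if (P.use_coul) {
        double qq = q[i] * q[j];
        if (qq != 0.0 && r2 < rc_coul2) {
          double r = std::sqrt(r2);
          double scr = std::exp(-r / P.debye);
          ec += P.coul_k * qq * (scr / r - coul_shift_base);
          // dV/dr = -k qq scr (1/r^2 + 1/(debye r))
          fr += P.coul_k * qq * scr * (1.0 / r2 + 1.0 / (P.debye * r)) / r;
        }
      }
      if (P.use_lj) {
        double s = sig(i, j);
        double rc = P.lj_cut_sigmas * s;
        if (r2 < rc * rc) {
          double dvr;
          double v = lj_pair(r2, s, lam(i, j), P.eps_lj, P.ashbaugh, rc, dvr);
          double dvr_c;
          double vc = lj_pair(rc * rc, s, lam(i, j), P.eps_lj, P.ashbaugh,
                              rc, dvr_c);
          el += v - vc;
          fr += -dvr;
        }
      }
      if (fr != 0.0) {
        f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
        f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
      }
    }
  }
  *ebond = eb; *ecoul = ec; *elj = el;
}

static Params make_params(List opt) {
  Params P;
  P.kbond = as<double>(opt["kbond"]);
  P.r0 = as<double>(opt["r0"]);
  P.coul_k = as<double>(opt["coul_k"]);
  P.debye = as<double>(opt["debye"]);
  P.rc_coul = as<double>(opt["rc_coul"]);
  P.eps_lj = as<double>(opt["eps_lj"]);
  P.lj_cut_sigmas = as<double>(opt["lj_cut_sigmas"]);
  P.use_lj = as<bool>(opt["use_lj"]);
  P.use_coul = as<bool>(opt["use_coul"]);
  P.ashbaugh = as<bool>(opt["ashbaugh"]);
  return P;
}

// [[Rcpp::export(name = ".cg_energy")]]
List cg_energy_cpp(NumericMatrix coords, NumericVector charge,
                   NumericMatrix lam, NumericMatrix sig,
                   NumericMatrix restraints, List opt) {
  int N = coords.nrow();
  Params P = make_params(opt);
  std::vector<double> x(3 * N), f(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  std::vector<double> q(charge.begin(), charge.end());
  double eb, ec, el;
  compute_forces(x, q, lam, sig, restraints, P, N, f, &eb, &ec, &el);
  NumericMatrix force(N, 3);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) force(i, d) = f[3 * i + d];
  return List::create(_["bond"] = eb, _["coulomb"] = ec, _["pair"] = el,
                      _["total"] = eb + ec + el, _["force"] = force);
}

// [[Rcpp::export(name = ".cg_run")]]
List cg_run_cpp(NumericMatrix coords, NumericVector charge,
                NumericMatrix lam, NumericMatrix sig,
                NumericMatrix restraints, List opt,
                double temperature, double dt, double friction,
                double n_steps_d, int save_every, int seed,
                NumericVector mass, double cap_steps_d, double fmax) {
  int N = coords.nrow();
  long n_steps = (long)n_steps_d;
  Params P = make_params(opt);
  const double kB = 0.00831446261815324; // kJ/mol/K
  double kT = kB * temperature;
  std::vector<double> x(3 * N), v(3 * N), f(3 * N);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = coords(i, d);
  std::vector<double> q(charge.begin(), charge.end());
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  // Maxwell-Boltzmann start velocities
  for (int i = 0; i < N; ++i) {
    double s = std::sqrt(kT / mass[i]);
    for (int d = 0; d < 3; ++d) v[3 * i + d] = s * gauss(rng);
  }
  double a = std::exp(-friction * dt);
  double b = std::sqrt(1.0 - a * a);
  long cap_steps = (long)cap_steps_d;
  double eb, ec, el;
  compute_forces(x, q, lam, sig, restraints, P, N, f, &eb, &ec, &el);
  if (cap_steps > 0) {
    for (int i = 0; i < 3 * N; ++i) {
      if (f[i] > fmax) f[i] = fmax;
      else if (f[i] < -fmax) f[i] = -fmax;
    }
  }
  long n_frames = n_steps / save_every;
  NumericVector frames((R_xlen_t)n_frames * N * 3);
  NumericVector ke_out(n_frames), epot_out(n_frames);
  long fi = 0;
  double h2 = 0.5 * dt;
  for (long step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < N; ++i) {
      double im = h2 / mass[i];
      for (int d = 0; d < 3; ++d) {
        v[3 * i + d] += im * f[3 * i + d];
        x[3 * i + d] += h2 * v[3 * i + d];
      }
    }
    for (int i = 0; i < N; ++i) {
      double s = b * std::sqrt(kT / mass[i]);
      for (int d = 0; d < 3; ++d)
        v[3 * i + d] = a * v[3 * i + d] + s * gauss(rng);
    }
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d) x[3 * i + d] += h2 * v[3 * i + d];
    compute_forces(x, q, lam, sig, restraints, P, N, f, &eb, &ec, &el);
    if (step <= cap_steps) {
      // soft push-off: clamp forces while initial overlaps relax
      for (int i = 0; i < 3 * N; ++i) {
        if (f[i] > fmax) f[i] = fmax;
        else if (f[i] < -fmax) f[i] = -fmax;
      }
    }
    for (int i = 0; i < N; ++i) {
      double im = h2 / mass[i];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += im * f[3 * i + d];
    }
    if (step % save_every == 0) {
      double ke = 0;
      for (int i = 0; i < N; ++i) {
        double vv = v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                    v[3 * i + 2] * v[3 * i + 2];
        ke += 0.5 * mass[i] * vv;
        if (std::abs(x[3 * i]) > 1e5 || std::abs(x[3 * i + 1]) > 1e5 ||
            std::abs(x[3 * i + 2]) > 1e5) {
          stop("numerical blow-up at step %ld", step);
        }
        for (int d = 0; d < 3; ++d)
          frames[(R_xlen_t)fi * N * 3 + (R_xlen_t)i * 3 + d] = x[3 * i + d];
      }
      ke_out[fi] = ke;
      epot_out[fi] = eb + ec + el;
      ++fi;
    }
    if (step % 100000 == 0) Rcpp::checkUserInterrupt();
  }
  frames.attr("dim") = IntegerVector::create(3, N, (int)n_frames);
  return List::create(_["frames"] = frames, _["kinetic"] = ke_out,
                      _["potential"] = epot_out);
}
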