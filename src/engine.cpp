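// Langevin-dynamics engine for the toy dual-level systems.
//
// Two system kinds are handled here:
//   * a 1-D particle in a pair of harmonic wells (closed-form free energy),
//   * a rigid multi-site solute in a bath of dipolar rotors at fixed
//     positions, where either level may carry fixed or environment-responsive
//     partial charges.
//
// Units: kcal/mol, Angstrom, elementary charge e, fs, amu (amu*A^2 for rotor
// inertia).  1 kcal/mol = 0.4184 amu*A^2/fs^2.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double E2MD = 0.4184;       // kcal/mol -> amu*A^2/fs^2
static const double COULOMB = 332.0637;  // kcal*A/(mol*e^2)

// ---------------------------------------------------------------------------
// Deterministic, seed-splittable RNG (xoshiro256++ seeded via splitmix64).
// Independent of R's RNG so that identical integer seeds give bit-identical
// trajectories regardless of the caller's RNG state.
// ---------------------------------------------------------------------------

struct Rng {
  uint64_t s[4];
  bool have_spare;
  double spare;

  explicit Rng(uint64_t seed) : have_spare(false), spare(0.0) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }

  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  inline uint64_t next_u64() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  inline double unif() {  // (0, 1)
    return ((next_u64() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  inline double norm() {  // standard normal, Box-Muller with cached spare
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// Harmonic pair: U_low = 1/2 k_l (x - x0_l)^2, U_high = 1/2 k_h (x - x0_h)^2.
// ---------------------------------------------------------------------------

struct Harm {
  double k_low, k_high, x0_low, x0_high, mass, beta, gamma, dt;

  inline double u_low(double x) const {
    double d = x - x0_low; return 0.5 * k_low * d * d;
  }
  inline double u_high(double x) const {
    double d = x - x0_high; return 0.5 * k_high * d * d;
  }
  inline double force(double x, double lam) const {
    return -((1.0 - lam) * k_low * (x - x0_low) +
             lam * k_high * (x - x0_high));
  }

  // one BAOAB step at fixed lambda
  inline void step(double &x, double &v, double lam, Rng &rng) const {
    const double kT_md = E2MD / beta;
    const double c = std::exp(-gamma * dt);
    const double sig = std::sqrt((1.0 - c * c) * kT_md / mass);
    v += 0.5 * dt * force(x, lam) * E2MD / mass;
    x += 0.5 * dt * v;
    v = c * v + sig * rng.norm();
    x += 0.5 * dt * v;
    v += 0.5 * dt * force(x, lam) * E2MD / mass;
  }

  inline double draw_velocity(Rng &rng) const {
    return std::sqrt(E2MD / (beta * mass)) * rng.norm();
  }
};

static Harm harm_from_list(const List &sys) {
  Harm h;
  h.k_low = as<double>(sys["k_low"]);
  h.k_high = as<double>(sys["k_high"]);
  h.x0_low = as<double>(sys["x0_low"]);
  h.x0_high = as<double>(sys["x0_high"]);
  h.mass = as<double>(sys["mass"]);
  h.beta = as<double>(sys["beta"]);
  h.gamma = as<double>(sys["gamma_fs"]);
  h.dt = as<double>(sys["dt"]);
  return h;
}

// Equilibrium sampling of the harmonic hybrid U(lambda); the velocity is
// drawn from Maxwell-Boltzmann at the stated temperature.
// [[Rcpp::export]]
List harm_sample_cpp(List sys, double lambda_value, int n_equil, int n_prod,
                     int save_every, double x_init, double seed) {
  Harm h = harm_from_list(sys);
  Rng rng(static_cast<uint64_t>(seed));
  double x = x_init;
  double v = h.draw_velocity(rng);

  int n_save = n_prod / save_every;
  NumericVector xs(n_save), vs(n_save), ul(n_save), uh(n_save);
  for (int i = 0; i < n_equil; ++i) h.step(x, v, lambda_value, rng);
  int k = 0;
  for (int i = 1; i <= n_prod; ++i) {
    h.step(x, v, lambda_value, rng);
    if (i % save_every == 0 && k < n_save) {
      xs[k] = x; vs[k] = v; ul[k] = h.u_low(x); uh[k] = h.u_high(x);
      ++k;
    }
  }
  if (!std::isfinite(x))
    stop("integration failure: non-finite coordinate in harmonic sampler");
  return List::create(_["x"] = xs, _["v"] = vs,
                      _["u_low"] = ul, _["u_high"] = uh);
}

// Non-equilibrium switches on the harmonic pair.  `lambdas` has length
// n_steps + 1 with lambdas[0] the value at the starting configuration; after
// each dynamics step (run at the pre-step lambda) the work increment
// U(x_new, lam_new) - U(x_new, lam_old) is accumulated, i.e. both energies
// are evaluated at the post-step coordinates.
// [[Rcpp::export]]
List harm_switch_cpp(List sys, NumericVector x0, NumericVector v0,
                     NumericVector lambdas, NumericVector seeds,
                     bool keep_trace) {
  Harm h = harm_from_list(sys);
  const int n_start = x0.size();
  const int n_steps = lambdas.size() - 1;
  NumericVector works(n_start), xf(n_start), vf(n_start);
  NumericMatrix trace(keep_trace ? n_steps + 1 : 0,
                      keep_trace ? n_start : 0);

  for (int s = 0; s < n_start; ++s) {
    Rng rng(static_cast<uint64_t>(seeds[s]));
    double x = x0[s], v = v0[s], w = 0.0;
    if (keep_trace) trace(0, s) = 0.0;
    for (int i = 1; i <= n_steps; ++i) {
      h.step(x, v, lambdas[i - 1], rng);
      w += (lambdas[i] - lambdas[i - 1]) * (h.u_high(x) - h.u_low(x));
      if (keep_trace) trace(i, s) = w;
    }
    if (!std::isfinite(w))
      stop("switch failure: non-finite work at start %d", s + 1);
    works[s] = w; xf[s] = x; vf[s] = v;
  }
  List out = List::create(_["work"] = works, _["x"] = xf, _["v"] = vf);
  if (keep_trace) out["trace"] = trace;
  return out;
}

// ---------------------------------------------------------------------------
// Dipole bath.  Each level carries per-atom baseline charges q, response
// coefficients kappa, and a constant offset:
//
//   phi_i(u)   = sum_j a_ij . u_j,  a_ij = COULOMB * mu * (r_i - R_j)/|.|^3
//   q_i(u)     = q_i + kappa_i phi_i - mean_k(kappa_k phi_k)  (re-neutralized)
//   U_level(u) = sum_i q_i(u) phi_i(u) + offset
//   U(lambda)  = (1-lambda) U_low + lambda U_high
//
// kappa = 0 gives a fixed-charge (force-field-like) level; nonzero kappa a
// Mulliken-like level whose charges fluctuate with the solvent field.
// ---------------------------------------------------------------------------

struct Level {
  std::vector<double> q, kappa;
  double offset;
};

struct Bath {
  int n_atoms, n_sites;
  Level low, high;
  std::vector<double> a;  // a[(i*n_sites + j)*3 + d]
  double inertia, gamma, beta, dt;

  void precompute(const NumericMatrix &coords, const NumericMatrix &sites,
                  double mu) {
    a.assign(static_cast<size_t>(std::max(n_atoms * n_sites, 1)) * 3, 0.0);
    for (int i = 0; i < n_atoms; ++i) {
      for (int j = 0; j < n_sites; ++j) {
        double dx = coords(0, i) - sites(0, j);
        double dy = coords(1, i) - sites(1, j);
        double dz = coords(2, i) - sites(2, j);
        double r2 = dx * dx + dy * dy + dz * dz;
        double r3 = r2 * std::sqrt(r2);
        double f = COULOMB * mu / r3;
        size_t o = (static_cast<size_t>(i) * n_sites + j) * 3;
        a[o] = f * dx; a[o + 1] = f * dy; a[o + 2] = f * dz;
      }
    }
  }

  inline void phi(const double *u, double *out) const {
    for (int i = 0; i < n_atoms; ++i) {
      double acc = 0.0;
      const double *ai = &a[static_cast<size_t>(i) * n_sites * 3];
      for (int j = 0; j < n_sites; ++j) {
        const double *uj = u + 3 * j;
        acc += ai[3 * j] * uj[0] + ai[3 * j + 1] * uj[1] +
               ai[3 * j + 2] * uj[2];
      }
      out[i] = acc;
    }
  }

  inline double level_energy(const Level &lv, const double *ph) const {
    double kbar = 0.0;
    for (int i = 0; i < n_atoms; ++i) kbar += lv.kappa[i] * ph[i];
    kbar /= n_atoms;
    double e = 0.0;
    for (int i = 0; i < n_atoms; ++i)
      e += (lv.q[i] + lv.kappa[i] * ph[i] - kbar) * ph[i];
    return e + lv.offset;
  }

  // dU_level/dphi_m = q_m(phi) + kappa_m (phi_m - mean(phi))
  inline void level_grad(const Level &lv, const double *ph, double *g) const {
    double kbar = 0.0, pbar = 0.0;
    for (int i = 0; i < n_atoms; ++i) {
      kbar += lv.kappa[i] * ph[i]; pbar += ph[i];
    }
    kbar /= n_atoms; pbar /= n_atoms;
    for (int i = 0; i < n_atoms; ++i) {
      double qi = lv.q[i] + lv.kappa[i] * ph[i] - kbar;
      g[i] = qi + lv.kappa[i] * (ph[i] - pbar);
    }
  }

  // torque on each rotor: tau_j = u_j x (-dU/du_j), dU/du_j = sum_i g_i a_ij
  inline void torques(const double *u, double lam, double *tau,
                      double *ph_buf, double *g_buf, double *g2_buf) const {
    phi(u, ph_buf);
    level_grad(low, ph_buf, g_buf);
    level_grad(high, ph_buf, g2_buf);
    for (int i = 0; i < n_atoms; ++i)
      g_buf[i] = (1.0 - lam) * g_buf[i] + lam * g2_buf[i];
    for (int j = 0; j < n_sites; ++j) {
      double fx = 0.0, fy = 0.0, fz = 0.0;
      for (int i = 0; i < n_atoms; ++i) {
        size_t o = (static_cast<size_t>(i) * n_sites + j) * 3;
        fx -= g_buf[i] * a[o];
        fy -= g_buf[i] * a[o + 1];
        fz -= g_buf[i] * a[o + 2];
      }
      const double *uj = u + 3 * j;
      tau[3 * j]     = uj[1] * fz - uj[2] * fy;
      tau[3 * j + 1] = uj[2] * fx - uj[0] * fz;
      tau[3 * j + 2] = uj[0] * fy - uj[1] * fx;
    }
  }
};

static Bath bath_from_list(const List &sys) {
  Bath b;
  NumericMatrix coords = sys["coords"];
  NumericMatrix sites = sys["sites"];
  b.n_atoms = coords.ncol();
  b.n_sites = sites.ncol();
  NumericVector ql = sys["q_low"], kl = sys["kappa_low"];
  NumericVector qh = sys["q_high"], kh = sys["kappa_high"];
  b.low.q.assign(ql.begin(), ql.end());
  b.low.kappa.assign(kl.begin(), kl.end());
  b.low.offset = as<double>(sys["offset_low"]);
  b.high.q.assign(qh.begin(), qh.end());
  b.high.kappa.assign(kh.begin(), kh.end());
  b.high.offset = as<double>(sys["offset_high"]);
  b.inertia = as<double>(sys["inertia"]);
  b.gamma = as<double>(sys["gamma_fs"]);
  b.beta = as<double>(sys["beta"]);
  b.dt = as<double>(sys["dt"]);
  b.precompute(coords, sites, as<double>(sys["mu"]));
  return b;
}

// rotate u about unit axis w by angle th (Rodrigues)
static inline void rotate(double *u, const double *w, double th) {
  double c = std::cos(th), s = std::sin(th);
  double dot = w[0] * u[0] + w[1] * u[1] + w[2] * u[2];
  double cx = w[1] * u[2] - w[2] * u[1];
  double cy = w[2] * u[0] - w[0] * u[2];
  double cz = w[0] * u[1] - w[1] * u[0];
  u[0] = u[0] * c + cx * s + w[0] * dot * (1.0 - c);
  u[1] = u[1] * c + cy * s + w[1] * dot * (1.0 - c);
  u[2] = u[2] * c + cz * s + w[2] * dot * (1.0 - c);
}

struct BathState {
  std::vector<double> u;   // 3 * n_sites orientations (unit)
  std::vector<double> w;   // 3 * n_sites angular velocities (perp to u)
};

// project w perpendicular to u, renormalize u
static inline void clean_state(BathState &st, int n_sites) {
  for (int j = 0; j < n_sites; ++j) {
    double *u = &st.u[3 * j], *w = &st.w[3 * j];
    double n = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    u[0] /= n; u[1] /= n; u[2] /= n;
    double d = u[0] * w[0] + u[1] * w[1] + u[2] * w[2];
    w[0] -= d * u[0]; w[1] -= d * u[1]; w[2] -= d * u[2];
  }
}

struct BathBuf {
  std::vector<double> tau, ph, g, g2;
  explicit BathBuf(const Bath &b)
      : tau(3 * std::max(b.n_sites, 1)), ph(b.n_atoms), g(b.n_atoms),
        g2(b.n_atoms) {}
};

// one BAOAB step of rotational Langevin dynamics at fixed lambda
static void bath_step(const Bath &b, BathState &st, double lam, Rng &rng,
                      BathBuf &buf) {
  const int S = b.n_sites;
  const double kT_md = E2MD / b.beta;
  const double c = std::exp(-b.gamma * b.dt);
  const double sig = std::sqrt((1.0 - c * c) * kT_md / b.inertia);
  const double half = 0.5 * b.dt * E2MD / b.inertia;

  b.torques(st.u.data(), lam, buf.tau.data(), buf.ph.data(), buf.g.data(),
            buf.g2.data());
  for (int j = 0; j < 3 * S; ++j) st.w[j] += half * buf.tau[j];

  for (int j = 0; j < S; ++j) {               // A (dt/2)
    double *u = &st.u[3 * j], *w = &st.w[3 * j];
    double wm = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
    if (wm > 1e-14) {
      double ax[3] = {w[0] / wm, w[1] / wm, w[2] / wm};
      rotate(u, ax, wm * 0.5 * b.dt);
    }
  }
  for (int j = 0; j < S; ++j) {               // O
    double *u = &st.u[3 * j], *w = &st.w[3 * j];
    double xi[3] = {rng.norm(), rng.norm(), rng.norm()};
    double d = xi[0] * u[0] + xi[1] * u[1] + xi[2] * u[2];
    for (int k = 0; k < 3; ++k) w[k] = c * w[k] + sig * (xi[k] - d * u[k]);
    d = w[0] * u[0] + w[1] * u[1] + w[2] * u[2];
    for (int k = 0; k < 3; ++k) w[k] -= d * u[k];
  }
  for (int j = 0; j < S; ++j) {               // A (dt/2)
    double *u = &st.u[3 * j], *w = &st.w[3 * j];
    double wm = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
    if (wm > 1e-14) {
      double ax[3] = {w[0] / wm, w[1] / wm, w[2] / wm};
      rotate(u, ax, wm * 0.5 * b.dt);
    }
  }
  b.torques(st.u.data(), lam, buf.tau.data(), buf.ph.data(), buf.g.data(),
            buf.g2.data());
  for (int j = 0; j < 3 * S; ++j) st.w[j] += half * buf.tau[j];
  clean_state(st, S);
}

static BathState bath_random_state(const Bath &b, Rng &rng) {
  BathState st;
  const int S = b.n_sites;
  st.u.resize(3 * S); st.w.resize(3 * S);
  const double wth = std::sqrt(E2MD / (b.beta * b.inertia));
  for (int j = 0; j < S; ++j) {
    double n;
    double *u = &st.u[3 * j];
    do {
      u[0] = rng.norm(); u[1] = rng.norm(); u[2] = rng.norm();
      n = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
    } while (n < 1e-12);
    u[0] /= n; u[1] /= n; u[2] /= n;
    double *w = &st.w[3 * j];
    for (int k = 0; k < 3; ++k) w[k] = wth * rng.norm();
  }
  clean_state(st, S);
  return st;
}

// Equilibrium sampling of the dipole bath on U(lambda).  If `u_init` is NULL
// orientations start uniform on the sphere; angular velocities are always
// redrawn from Maxwell-Boltzmann.
// [[Rcpp::export]]
List bath_sample_cpp(List sys, double lambda_value, int n_equil, int n_prod,
                     int save_every, double seed,
                     Nullable<NumericMatrix> u_init = R_NilValue) {
  Bath b = bath_from_list(sys);
  Rng rng(static_cast<uint64_t>(seed));
  BathState st;
  if (u_init.isNotNull()) {
    NumericMatrix u0(u_init);
    st.u.assign(u0.begin(), u0.end());
    st.w.resize(st.u.size());
    const double wth = std::sqrt(E2MD / (b.beta * b.inertia));
    for (size_t k = 0; k < st.w.size(); ++k) st.w[k] = wth * rng.norm();
    clean_state(st, b.n_sites);
  } else {
    st = bath_random_state(b, rng);
  }
  BathBuf buf(b);

  int n_save = n_prod / save_every;
  NumericVector ul(n_save), uh(n_save);
  NumericVector uarr(Dimension(3, std::max(b.n_sites, 1), std::max(n_save, 1)));
  NumericVector warr(Dimension(3, std::max(b.n_sites, 1), std::max(n_save, 1)));

  for (int i = 0; i < n_equil; ++i) bath_step(b, st, lambda_value, rng, buf);
  int k = 0;
  for (int i = 1; i <= n_prod; ++i) {
    bath_step(b, st, lambda_value, rng, buf);
    if (i % save_every == 0 && k < n_save) {
      b.phi(st.u.data(), buf.ph.data());
      ul[k] = b.level_energy(b.low, buf.ph.data());
      uh[k] = b.level_energy(b.high, buf.ph.data());
      std::copy(st.u.begin(), st.u.end(),
                uarr.begin() + static_cast<size_t>(k) * 3 * b.n_sites);
      std::copy(st.w.begin(), st.w.end(),
                warr.begin() + static_cast<size_t>(k) * 3 * b.n_sites);
      ++k;
    }
  }
  for (double x : st.u)
    if (!std::isfinite(x))
      stop("integration failure: non-finite orientation in bath sampler");
  return List::create(_["orientations"] = uarr, _["angvel"] = warr,
                      _["u_low"] = ul, _["u_high"] = uh);
}

// Non-equilibrium switches on the dipole bath (same work-accumulation
// convention as harm_switch_cpp).
// [[Rcpp::export]]
List bath_switch_cpp(List sys, NumericVector u0, NumericVector w0,
                     NumericVector lambdas, NumericVector seeds,
                     bool keep_trace) {
  Bath b = bath_from_list(sys);
  IntegerVector dims = u0.attr("dim");
  const int S = dims[1], n_start = dims[2];
  const int n_steps = lambdas.size() - 1;
  if (S != b.n_sites) stop("start pool does not match system site count");

  NumericVector works(n_start);
  NumericVector ufin(Dimension(3, std::max(S, 1), n_start));
  NumericVector wfin(Dimension(3, std::max(S, 1), n_start));
  NumericMatrix trace(keep_trace ? n_steps + 1 : 0,
                      keep_trace ? n_start : 0);
  BathBuf buf(b);

  for (int s = 0; s < n_start; ++s) {
    Rng rng(static_cast<uint64_t>(seeds[s]));
    BathState st;
    size_t off = static_cast<size_t>(s) * 3 * S;
    st.u.assign(u0.begin() + off, u0.begin() + off + 3 * S);
    st.w.assign(w0.begin() + off, w0.begin() + off + 3 * S);
    double w = 0.0;
    if (keep_trace) trace(0, s) = 0.0;
    for (int i = 1; i <= n_steps; ++i) {
      bath_step(b, st, lambdas[i - 1], rng, buf);
      b.phi(st.u.data(), buf.ph.data());
      w += (lambdas[i] - lambdas[i - 1]) *
           (b.level_energy(b.high, buf.ph.data()) -
            b.level_energy(b.low, buf.ph.data()));
      if (keep_trace) trace(i, s) = w;
    }
    if (!std::isfinite(w))
      stop("switch failure: non-finite work at start %d", s + 1);
    works[s] = w;
    std::copy(st.u.begin(), st.u.end(), ufin.begin() + off);
    std::copy(st.w.begin(), st.w.end(), wfin.begin() + off);
  }
  List out = List::create(_["work"] = works, _["orientations"] = ufin,
                          _["angvel"] = wfin);
  if (keep_trace) out["trace"] = trace;
  return out;
}

// Relaxation runs for Stokes-shift analysis: propagate each start at the
// high level (lambda = 1) and record the energy gap
// dU(t) = U_high(x_t) - U_low(x_t) every `record_every` steps (t = 0
// included).  The system's low level carries the charges of the state the
// trajectories were started from.
// [[Rcpp::export]]
NumericMatrix bath_relax_cpp(List sys, NumericVector u0, NumericVector w0,
                             int n_steps, int record_every,
                             NumericVector seeds) {
  Bath b = bath_from_list(sys);
  IntegerVector dims = u0.attr("dim");
  const int S = dims[1], n_traj = dims[2];
  if (S != b.n_sites) stop("start pool does not match system site count");
  const int n_rec = n_steps / record_every + 1;
  NumericMatrix gaps(n_rec, n_traj);
  BathBuf buf(b);

  for (int s = 0; s < n_traj; ++s) {
    Rng rng(static_cast<uint64_t>(seeds[s]));
    BathState st;
    size_t off = static_cast<size_t>(s) * 3 * S;
    st.u.assign(u0.begin() + off, u0.begin() + off + 3 * S);
    st.w.assign(w0.begin() + off, w0.begin() + off + 3 * S);
    b.phi(st.u.data(), buf.ph.data());
    gaps(0, s) = b.level_energy(b.high, buf.ph.data()) -
                 b.level_energy(b.low, buf.ph.data());
    int k = 1;
    for (int i = 1; i <= n_steps; ++i) {
      bath_step(b, st, 1.0, rng, buf);
      if (i % record_every == 0 && k < n_rec) {
        b.phi(st.u.data(), buf.ph.data());
        gaps(k, s) = b.level_energy(b.high, buf.ph.data()) -
                     b.level_energy(b.low, buf.ph.data());
        ++k;
      }
    }
  }
  return gaps;
}

// Electrostatic potential at each solute atom from the rotor dipoles.
// [[Rcpp::export]]
NumericVector bath_phi_cpp(List sys, NumericMatrix u) {
  Bath b = bath_from_list(sys);
  NumericVector out(b.n_atoms);
  if (b.n_sites == 0) return out;
  std::vector<double> uu(u.begin(), u.end());
  b.phi(uu.data(), REAL(out));
  return out;
}

// Hybrid energy U(lambda) for one configuration.
// [[Rcpp::export]]
double bath_energy_cpp(List sys, NumericMatrix u, double lambda_value) {
  Bath b = bath_from_list(sys);
  std::vector<double> ph(b.n_atoms, 0.0);
  if (b.n_sites > 0) {
    std::vector<double> uu(u.begin(), u.end());
    b.phi(uu.data(), ph.data());
  }
  return (1.0 - lambda_value) * b.level_energy(b.low, ph.data()) +
         lambda_value * b.level_energy(b.high, ph.data());
}
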