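// Langevin dynamics core for the charged bead-spring ring model.
//
// Reduced units throughout: sigma_mon = 1, k_B T = 1, m = 1, tau = 1.
// Pair excluded volume: WCA with Lorentz-Berthelot mixing on per-particle
// sigma. Bonds: FENE (plus the WCA pair term, Kremer-Grest style; bonded
// pairs are NOT excluded from the nonbonded loop). Angles: harmonic cosine
// U = (K/2)(1 - cos phi)^2 with phi the angle between consecutive bond
// vectors (phi = 0 for a straight continuation). Electrostatics: explicit
// Ewald (tinfoil boundary), Debye-Hueckel screened pair term, or off.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <complex>
#include <cstdint>
#include <random>
#include <string>
#include <climits>

using namespace Rcpp;

static inline double min_image(double d, double L) {
  return d - L * std::round(d / L);
}

struct EwaldPlan {
  double alpha = 0.0;
  double rcut = 0.0;
  int nmax = 0;
  // half-space k vectors and prefactors 4*pi/(V k^2) exp(-k^2/(4 alpha^2))
  std::vector<double> kx, ky, kz, ak;
  std::vector<int> nx, ny, nz;
  void build(double L, double accuracy, double rcut_in) {
    rcut = rcut_in;
    const double p = std::sqrt(-std::log(accuracy));
    alpha = p / rcut;
    const double kcut = 2.0 * alpha * p;
    nmax = (int)std::ceil(kcut * L / (2.0 * M_PI));
    if (nmax < 1) nmax = 1;
    const double V = L * L * L;
    const double twopiL = 2.0 * M_PI / L;
    kx.clear(); ky.clear(); kz.clear(); ak.clear();
    nx.clear(); ny.clear(); nz.clear();
    for (int ix = 0; ix <= nmax; ++ix) {
      int jy0 = (ix == 0) ? 0 : -nmax;
      for (int iy = jy0; iy <= nmax; ++iy) {
        int jz0 = (ix == 0 && iy == 0) ? 1 : -nmax;
        for (int iz = jz0; iz <= nmax; ++iz) {
          double gx = twopiL * ix, gy = twopiL * iy, gz = twopiL * iz;
          double k2 = gx * gx + gy * gy + gz * gz;
          if (k2 > kcut * kcut) continue;
          kx.push_back(gx); ky.push_back(gy); kz.push_back(gz);
          nx.push_back(ix); ny.push_back(iy); nz.push_back(iz);
          ak.push_back(4.0 * M_PI / (V * k2) * std::exp(-k2 / (4.0 * alpha * alpha)));
        }
      }
    }
  }
};

struct System {
  int n = 0;
  std::vector<double> x, y, z;     // positions (unwrapped)
  std::vector<double> sig;         // per-particle WCA sigma
  std::vector<double> q;           // charge numbers
  std::vector<int> b0, b1;         // FENE bonds
  std::vector<int> a0, a1, a2;     // angle triplets (consecutive bonds)
  double L = 0.0;
  // parameters
  double epsilon = 1.0, K_fene = 30.0, R0 = 1.5, K_bend = 30.0, bjerrum = 0.71;
  int electro = 0;                 // 0 off, 1 explicit Ewald, 2 Debye-Hueckel
  double kappa = 1.0;              // DH inverse screening length
  double rcut_elec = 4.0;
  double accuracy = 1e-3;
  EwaldPlan ewald;
  double qsum = 0.0, q2sum = 0.0;
  bool any_charge = false;

  // neighbour list
  double skin = 0.4;
  double r_list = 0.0;
  std::vector<std::vector<int>> nbr;
  std::vector<double> x0, y0, z0;  // positions at last build

  double max_wca_cut() const {
    double smax = 0.0;
    for (double s : sig) smax = std::max(smax, s);
    return std::pow(2.0, 1.0 / 6.0) * smax;
  }

  void init_cuts() {
    qsum = 0.0; q2sum = 0.0; any_charge = false;
    for (double c : q) { qsum += c; q2sum += c * c; if (c != 0.0) any_charge = true; }
    double rc = max_wca_cut();
    if (any_charge && electro != 0) {
      rcut_elec = std::min(rcut_elec, 0.5 * L);
      rc = std::max(rc, rcut_elec);
      if (electro == 1) ewald.build(L, accuracy, rcut_elec);
    }
    r_list = rc + skin;
    if (r_list > 0.5 * L) r_list = 0.5 * L;  // min-image safe
  }

  void build_nbr() {
    nbr.assign(n, {});
    const double rl2 = r_list * r_list;
    const int nc = std::max(1, (int)std::floor(L / r_list));
    if (nc < 3) {  // too few cells for the 27-stencil: plain O(N^2)
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) {
          double dx = min_image(x[i] - x[j], L);
          double dy = min_image(y[i] - y[j], L);
          double dz = min_image(z[i] - z[j], L);
          if (dx * dx + dy * dy + dz * dz < rl2) nbr[i].push_back(j);
        }
    } else {
      auto cidx = [&](double u) {
        double w = u - L * std::floor(u / L);  // wrap into [0, L)
        int c = (int)(w / L * nc);
        return c >= nc ? nc - 1 : c;
      };
      std::vector<int> head(nc * nc * nc, -1), nxt(n, -1), cell(n);
      for (int i = 0; i < n; ++i) {
        int c = (cidx(x[i]) * nc + cidx(y[i])) * nc + cidx(z[i]);
        cell[i] = c;
        nxt[i] = head[c];
        head[c] = i;
      }
      for (int i = 0; i < n; ++i) {
        int cxi = cell[i] / (nc * nc), cyi = (cell[i] / nc) % nc,
            czi = cell[i] % nc;
        for (int ox = -1; ox <= 1; ++ox)
          for (int oy = -1; oy <= 1; ++oy)
            for (int oz = -1; oz <= 1; ++oz) {
              int cx = (cxi + ox + nc) % nc, cy = (cyi + oy + nc) % nc,
                  cz = (czi + oz + nc) % nc;
              for (int j = head[(cx * nc + cy) * nc + cz]; j >= 0;
                   j = nxt[j]) {
                if (j <= i) continue;
                double dx = min_image(x[i] - x[j], L);
                double dy = min_image(y[i] - y[j], L);
                double dz = min_image(z[i] - z[j], L);
                if (dx * dx + dy * dy + dz * dz < rl2) nbr[i].push_back(j);
              }
            }
      }
    }
    x0 = x; y0 = y; z0 = z;
  }

  bool nbr_stale() const {
    const double lim = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double dx = x[i] - x0[i], dy = y[i] - y0[i], dz = z[i] - z0[i];
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }

  // Accumulate forces and energies. Returns false on overstretched bond.
  bool energy_forces(std::vector<double> &fx, std::vector<double> &fy,
                     std::vector<double> &fz, double &e_wca, double &e_fene,
                     double &e_bend, double &e_elec, std::string &err) {
    fx.assign(n, 0.0); fy.assign(n, 0.0); fz.assign(n, 0.0);
    e_wca = e_fene = e_bend = e_elec = 0.0;
    const bool do_elec = any_charge && electro != 0;
    const double rce2 = rcut_elec * rcut_elec;
    const double alpha = ewald.alpha;
    const double two_over_sqrtpi = 2.0 / std::sqrt(M_PI);

    // pair loop (WCA + electro real-space / DH)
    for (int i = 0; i < n; ++i) {
      for (int j : nbr[i]) {
        double dx = min_image(x[i] - x[j], L);
        double dy = min_image(y[i] - y[j], L);
        double dz = min_image(z[i] - z[j], L);
        double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 <= 1e-12) { err = "coincident particles"; return false; }
        double sp = 0.5 * (sig[i] + sig[j]);
        double wca_cut2 = std::pow(2.0, 1.0 / 3.0) * sp * sp;
        double fpair = 0.0;  // (1/r) dU/dr accumulated with sign for force
        if (r2 < wca_cut2) {
          double s2 = sp * sp / r2, s6 = s2 * s2 * s2, s12 = s6 * s6;
          e_wca += 4.0 * epsilon * (s12 - s6) + epsilon;
          fpair += 24.0 * epsilon * (2.0 * s12 - s6) / r2;
        }
        if (do_elec && q[i] != 0.0 && q[j] != 0.0 && r2 < rce2) {
          double r = std::sqrt(r2);
          double qq = bjerrum * q[i] * q[j];
          if (electro == 1) {
            double er = std::erfc(alpha * r);
            e_elec += qq * er / r;
            fpair += qq * (er / r + two_over_sqrtpi * alpha * std::exp(-alpha * alpha * r2)) / r2;
          } else {
            double ex = std::exp(-kappa * r);
            e_elec += qq * ex / r;
            fpair += qq * ex * (1.0 / r + kappa) / r2;
          }
        }
        if (fpair != 0.0) {
          fx[i] += fpair * dx; fy[i] += fpair * dy; fz[i] += fpair * dz;
          fx[j] -= fpair * dx; fy[j] -= fpair * dy; fz[j] -= fpair * dz;
        }
      }
    }

    // FENE bonds
    for (size_t m = 0; m < b0.size(); ++m) {
      int i = b0[m], j = b1[m];
      double dx = min_image(x[i] - x[j], L);
      double dy = min_image(y[i] - y[j], L);
      double dz = min_image(z[i] - z[j], L);
      double r2 = dx * dx + dy * dy + dz * dz;
      double r = std::sqrt(r2);
      if (r >= R0) {
        err = "overstretched bond (b >= R0) between particles " +
              std::to_string(i + 1) + " and " + std::to_string(j + 1);
        return false;
      }
      double u = r2 / (R0 * R0);
      e_fene += -0.5 * K_fene * R0 * R0 * std::log(1.0 - u);
      double fpair = -K_fene / (1.0 - u);  // attractive: dU/dr = K r/(1-u)
      fx[i] += fpair * dx; fy[i] += fpair * dy; fz[i] += fpair * dz;
      fx[j] -= fpair * dx; fy[j] -= fpair * dy; fz[j] -= fpair * dz;
    }

    // harmonic cosine bending: U = (K/2)(1 - cos phi)^2
    for (size_t m = 0; m < a0.size(); ++m) {
      int i = a0[m], j = a1[m], k = a2[m];
      double ux = min_image(x[j] - x[i], L), uy = min_image(y[j] - y[i], L),
             uz = min_image(z[j] - z[i], L);
      double vx = min_image(x[k] - x[j], L), vy = min_image(y[k] - y[j], L),
             vz = min_image(z[k] - z[j], L);
      double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
      double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
      double c = (ux * vx + uy * vy + uz * vz) / (nu * nv);
      c = std::max(-1.0, std::min(1.0, c));
      e_bend += 0.5 * K_bend * (1.0 - c) * (1.0 - c);
      double dEdc = -K_bend * (1.0 - c);
      // dc/du and dc/dv
      double dcux = vx / (nu * nv) - c * ux / (nu * nu);
      double dcuy = vy / (nu * nv) - c * uy / (nu * nu);
      double dcuz = vz / (nu * nv) - c * uz / (nu * nu);
      double dcvx = ux / (nu * nv) - c * vx / (nv * nv);
      double dcvy = uy / (nu * nv) - c * vy / (nv * nv);
      double dcvz = uz / (nu * nv) - c * vz / (nv * nv);
      // r_i: du = -d r_i ; r_k: dv = +d r_k ; r_j: du = +, dv = -
      fx[i] += dEdc * dcux; fy[i] += dEdc * dcuy; fz[i] += dEdc * dcuz;
      fx[k] -= dEdc * dcvx; fy[k] -= dEdc * dcvy; fz[k] -= dEdc * dcvz;
      fx[j] -= dEdc * (dcux - dcvx);
      fy[j] -= dEdc * (dcuy - dcvy);
      fz[j] -= dEdc * (dcuz - dcvz);
    }

    // Ewald reciprocal + self + neutralising background
    if (do_elec && electro == 1) {
      const int nmax = ewald.nmax;
      // phase tables e^{i 2 pi m u / L}, m = 0..nmax, split into re/im
      const int stride = nmax + 1;
      std::vector<double> exr(stride * n), exi(stride * n), eyr(stride * n),
          eyi(stride * n), ezr(stride * n), ezi(stride * n);
      const double twopiL = 2.0 * M_PI / L;
      for (int i = 0; i < n; ++i) {
        exr[i] = eyr[i] = ezr[i] = 1.0;
        exi[i] = eyi[i] = ezi[i] = 0.0;
        double cx = std::cos(twopiL * x[i]), sx = std::sin(twopiL * x[i]);
        double cy = std::cos(twopiL * y[i]), sy = std::sin(twopiL * y[i]);
        double cz = std::cos(twopiL * z[i]), sz = std::sin(twopiL * z[i]);
        for (int m = 1; m <= nmax; ++m) {
          int a = m * n + i, b = (m - 1) * n + i;
          exr[a] = exr[b] * cx - exi[b] * sx;
          exi[a] = exr[b] * sx + exi[b] * cx;
          eyr[a] = eyr[b] * cy - eyi[b] * sy;
          eyi[a] = eyr[b] * sy + eyi[b] * cy;
          ezr[a] = ezr[b] * cz - ezi[b] * sz;
          ezi[a] = ezr[b] * sz + ezi[b] * cz;
        }
      }
      std::vector<double> xyr(n), xyi(n), er(n), ei(n);
      int last_ix = INT_MIN, last_iy = INT_MIN;
      for (size_t kv = 0; kv < ewald.ak.size(); ++kv) {
        const int ix = ewald.nx[kv], iy = ewald.ny[kv], iz = ewald.nz[kv];
        if (ix != last_ix || iy != last_iy) {
          const int ax = std::abs(ix) * n, ay = std::abs(iy) * n;
          const double sy = iy >= 0 ? 1.0 : -1.0;
          for (int i = 0; i < n; ++i) {
            // ix >= 0 always in the half-space enumeration
            double xr = exr[ax + i], xi = exi[ax + i];
            double yr = eyr[ay + i], yi = sy * eyi[ay + i];
            xyr[i] = xr * yr - xi * yi;
            xyi[i] = xr * yi + xi * yr;
          }
          last_ix = ix; last_iy = iy;
        }
        const int az = std::abs(iz) * n;
        const double sz = iz >= 0 ? 1.0 : -1.0;
        double Sr = 0.0, Si = 0.0;
        for (int i = 0; i < n; ++i) {
          double zr = ezr[az + i], zi = sz * ezi[az + i];
          er[i] = xyr[i] * zr - xyi[i] * zi;
          ei[i] = xyr[i] * zi + xyi[i] * zr;
          Sr += q[i] * er[i];
          Si += q[i] * ei[i];
        }
        double ak = ewald.ak[kv];
        e_elec += bjerrum * ak * (Sr * Sr + Si * Si);  // half-space: 2 * 1/2
        double pref = 2.0 * bjerrum * ak;
        const double gx = ewald.kx[kv], gy = ewald.ky[kv], gz = ewald.kz[kv];
        for (int i = 0; i < n; ++i) {
          if (q[i] == 0.0) continue;
          // F_i = 2 lB ak q_i k (sin(k r_i) Re S - cos(k r_i) Im S)
          double f = pref * q[i] * (ei[i] * Sr - er[i] * Si);
          fx[i] += f * gx;
          fy[i] += f * gy;
          fz[i] += f * gz;
        }
      }
      e_elec -= bjerrum * alpha / std::sqrt(M_PI) * q2sum;
      e_elec -= bjerrum * M_PI / (2.0 * alpha * alpha * L * L * L) * qsum * qsum;
    }
    return true;
  }
};

static System make_system(NumericMatrix pos, NumericVector sigma,
                          NumericVector charges, IntegerMatrix bonds,
                          IntegerMatrix angles, double L, List params) {
  System s;
  s.n = pos.nrow();
  s.x.resize(s.n); s.y.resize(s.n); s.z.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
  }
  s.sig.assign(sigma.begin(), sigma.end());
  s.q.assign(charges.begin(), charges.end());
  for (int m = 0; m < bonds.nrow(); ++m) {
    s.b0.push_back(bonds(m, 0)); s.b1.push_back(bonds(m, 1));
  }
  for (int m = 0; m < angles.nrow(); ++m) {
    s.a0.push_back(angles(m, 0)); s.a1.push_back(angles(m, 1));
    s.a2.push_back(angles(m, 2));
  }
  s.L = L;
  s.epsilon = as<double>(params["epsilon"]);
  s.K_fene = as<double>(params["K_fene"]);
  s.R0 = as<double>(params["R0"]);
  s.K_bend = as<double>(params["K_bend"]);
  s.bjerrum = as<double>(params["bjerrum"]);
  s.electro = as<int>(params["electro"]);
  s.kappa = as<double>(params["kappa"]);
  s.rcut_elec = as<double>(params["rcut_elec"]);
  s.accuracy = as<double>(params["accuracy"]);
  s.init_cuts();
  return s;
}

// [[Rcpp::export]]
List rs_energy_forces(NumericMatrix pos, NumericVector sigma,
                      NumericVector charges, IntegerMatrix bonds,
                      IntegerMatrix angles, double L, List params) {
  System s = make_system(pos, sigma, charges, bonds, angles, L, params);
  s.build_nbr();
  std::vector<double> fx, fy, fz;
  double ew, ef, eb, ee;
  std::string err;
  if (!s.energy_forces(fx, fy, fz, ew, ef, eb, ee, err)) stop(err);
  NumericMatrix F(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    F(i, 0) = fx[i]; F(i, 1) = fy[i]; F(i, 2) = fz[i];
  }
  return List::create(_["wca"] = ew, _["fene"] = ef, _["bend"] = eb,
                      _["electrostatic"] = ee, _["forces"] = F);
}

// Deterministic Gaussian stream: mt19937_64 + Box-Muller (platform stable).
struct Gauss {
  std::mt19937_64 eng;
  bool have = false;
  double spare = 0.0;
  explicit Gauss(uint64_t seed) : eng(seed) {}
  double unif() {
    return (eng() >> 11) * (1.0 / 9007199254740992.0);  // [0,1)
  }
  double operator()() {
    if (have) { have = false; return spare; }
    double u1 = 0.0;
    while (u1 <= 1e-300) u1 = unif();
    double u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// [[Rcpp::export]]
List rs_run_langevin(NumericMatrix pos, NumericMatrix vel, NumericVector sigma,
                     NumericVector charges, IntegerMatrix bonds,
                     IntegerMatrix angles, double L, List params, int nsteps,
                     double dt, double gamma, double temp, double mass,
                     double seed, int dump_every) {
  System s = make_system(pos, sigma, charges, bonds, angles, L, params);
  const int n = s.n;
  std::vector<double> vx(n), vy(n), vz(n);
  for (int i = 0; i < n; ++i) {
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  Gauss rng((uint64_t)seed);
  s.build_nbr();
  std::vector<double> fx, fy, fz;
  double ew, ef, eb, ee;
  std::string err;
  if (!s.energy_forces(fx, fy, fz, ew, ef, eb, ee, err)) stop(err);

  const double noise_amp =
      (temp > 0.0 && gamma > 0.0) ? std::sqrt(2.0 * gamma * mass * temp / dt) : 0.0;
  const double hdtm = 0.5 * dt / mass;
  const double fric_den = 1.0 + 0.5 * gamma * dt;

  int ndump = (dump_every > 0) ? nsteps / dump_every : 0;
  List snaps(ndump);
  IntegerVector snap_steps(ndump);
  NumericVector ke_trace(ndump);
  int isnap = 0;
  std::vector<double> rfx(n), rfy(n), rfz(n);

  for (int step = 1; step <= nsteps; ++step) {
    if (noise_amp > 0.0)
      for (int i = 0; i < n; ++i) {
        rfx[i] = noise_amp * rng(); rfy[i] = noise_amp * rng();
        rfz[i] = noise_amp * rng();
      }
    else
      for (int i = 0; i < n; ++i) rfx[i] = rfy[i] = rfz[i] = 0.0;

    for (int i = 0; i < n; ++i) {
      vx[i] += hdtm * (fx[i] + rfx[i] - gamma * mass * vx[i]);
      vy[i] += hdtm * (fy[i] + rfy[i] - gamma * mass * vy[i]);
      vz[i] += hdtm * (fz[i] + rfz[i] - gamma * mass * vz[i]);
      s.x[i] += dt * vx[i]; s.y[i] += dt * vy[i]; s.z[i] += dt * vz[i];
    }
    if (s.nbr_stale()) s.build_nbr();
    if (!s.energy_forces(fx, fy, fz, ew, ef, eb, ee, err)) stop(err);
    for (int i = 0; i < n; ++i) {
      vx[i] = (vx[i] + hdtm * (fx[i] + rfx[i])) / fric_den;
      vy[i] = (vy[i] + hdtm * (fy[i] + rfy[i])) / fric_den;
      vz[i] = (vz[i] + hdtm * (fz[i] + rfz[i])) / fric_den;
    }

    if (dump_every > 0 && step % dump_every == 0 && isnap < ndump) {
      NumericMatrix snap(n, 3);
      double ke = 0.0;
      for (int i = 0; i < n; ++i) {
        snap(i, 0) = s.x[i]; snap(i, 1) = s.y[i]; snap(i, 2) = s.z[i];
        ke += 0.5 * mass * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      }
      if (!std::isfinite(ke)) stop("energy divergence (non-finite kinetic energy) at step %d", step);
      snaps[isnap] = snap;
      snap_steps[isnap] = step;
      ke_trace[isnap] = ke;
      ++isnap;
    }
    if (step % 1000 == 0) {
      if (!std::isfinite(s.x[0])) stop("energy divergence (NaN position) at step %d", step);
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix fpos(n, 3), fvel(n, 3);
  for (int i = 0; i < n; ++i) {
    fpos(i, 0) = s.x[i]; fpos(i, 1) = s.y[i]; fpos(i, 2) = s.z[i];
    fvel(i, 0) = vx[i]; fvel(i, 1) = vy[i]; fvel(i, 2) = vz[i];
  }
  return List::create(_["snapshots"] = snaps, _["snap_steps"] = snap_steps,
                      _["kinetic"] = ke_trace, _["positions"] = fpos,
                      _["velocities"] = fvel);
}
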