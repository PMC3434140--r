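// Analog / track-length Monte Carlo photon transport for an Ir-192 HDR line
// source in homogeneous and two-region slab phantoms.
//
// Physics model: delta (Woodcock) tracking against the per-energy majorant
// attenuation coefficient; photoelectric absorption (full local deposit),
// incoherent scattering sampled from the free-electron Klein-Nishina
// distribution (Kahn's rejection method), coherent scattering with a
// screened-form-factor angular law and no energy loss.  Secondary electrons
// are not transported: energy transferred to electrons is deposited at the
// interaction point (collision-kerma approximation).  Photons falling below
// the transport cutoff deposit their remaining energy locally.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const double MEC2 = 510.99895;   // electron rest energy, keV
static const double HC_KEV_A = 12.39842; // hc, keV * Angstrom

// ---------------------------------------------------------------------------
// xoshiro256++ with splitmix64 seeding: reproducible independently of R's RNG
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double u() { return (next() >> 11) * 0x1.0p-53; }        // [0,1)
  inline double u_open() { return 1.0 - ((next() >> 11) * 0x1.0p-53); } // (0,1]
};

// ---------------------------------------------------------------------------
// per-material coefficient tables, log-log interpolated
struct MatTable {
  std::vector<double> logE, log_tot, log_pe, log_incoh, log_coh, log_muen;
  double density, zeff;
  inline int bracket(double le) const {
    int n = (int)logE.size();
    int i = (int)(std::upper_bound(logE.begin(), logE.end(), le) - logE.begin());
    if (i < 1) i = 1;
    if (i > n - 1) i = n - 1;
    return i;
  }
  inline double at(const std::vector<double>& y, double e_kev) const {
    double le = std::log(e_kev);
    int i = bracket(le);
    double t = (le - logE[i - 1]) / (logE[i] - logE[i - 1]);
    return std::exp(y[i - 1] + t * (y[i] - y[i - 1]));
  }
  inline double mu_tot(double e) const { return at(log_tot, e); }      // 1/cm
  inline double mu_pe(double e) const { return at(log_pe, e); }        // 1/cm
  inline double mu_incoh(double e) const { return at(log_incoh, e); }  // 1/cm
  inline double mu_coh(double e) const { return at(log_coh, e); }      // 1/cm
  inline double muen_rho(double e) const { return at(log_muen, e); }   // cm^2/g
};

static MatTable make_mat(const List& m) {
  MatTable t;
  NumericVector e = m["energy_keV"], tot = m["mu_lin_total"], pe = m["mu_lin_pe"],
                ic = m["mu_lin_incoh"], co = m["mu_lin_coh"], en = m["mu_en_over_rho"];
  int n = e.size();
  t.logE.resize(n); t.log_tot.resize(n); t.log_pe.resize(n);
  t.log_incoh.resize(n); t.log_coh.resize(n); t.log_muen.resize(n);
  for (int i = 0; i < n; ++i) {
    t.logE[i] = std::log(e[i]);
    t.log_tot[i] = std::log(tot[i]);
    t.log_pe[i] = std::log(std::max(pe[i], 1e-300));
    t.log_incoh[i] = std::log(std::max(ic[i], 1e-300));
    t.log_coh[i] = std::log(std::max(co[i], 1e-300));
    t.log_muen[i] = std::log(en[i]);
  }
  t.density = as<double>(m["density"]);
  t.zeff = as<double>(m["zeff"]);
  return t;
}

// ---------------------------------------------------------------------------
// geometry: cube of half-size h centred on the source; optional single plane
// interface with normal +x at offset d (points with x >= d are region 2)
struct Geom {
  double half;
  bool two_region;
  double d;
  inline bool outside(double x, double y, double z) const {
    return std::fabs(x) > half || std::fabs(y) > half || std::fabs(z) > half;
  }
  inline int region(double x) const {
    return (two_region && x >= d) ? 1 : 0;
  }
};

// rotate unit vector (ux,uy,uz) by polar angle with cosine mu and azimuth phi
static inline void rotate_direction(double& ux, double& uy, double& uz,
                                    double mu, double phi) {
  double sm = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  double cp = std::cos(phi), sp = std::sin(phi);
  double a = std::sqrt(std::max(0.0, 1.0 - uz * uz));
  double nx, ny, nz;
  if (a > 1e-10) {
    nx = mu * ux + sm * (ux * uz * cp - uy * sp) / a;
    ny = mu * uy + sm * (uy * uz * cp + ux * sp) / a;
    nz = mu * uz - sm * a * cp;
  } else {                       // travelling along +-z
    nx = sm * cp;
    ny = sm * sp;
    nz = mu * (uz > 0 ? 1.0 : -1.0);
  }
  double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
  ux = nx / norm; uy = ny / norm; uz = nz / norm;
}

// Kahn's rejection method for the Klein-Nishina distribution.
// Returns x = E/E'; sets cos_theta.
static inline double sample_kn(Xoshiro& rng, double e_kev, double& cos_theta) {
  double a = e_kev / MEC2;
  for (;;) {
    double r1 = rng.u(), r2 = rng.u(), r3 = rng.u();
    if (r1 <= (2.0 * a + 1.0) / (2.0 * a + 9.0)) {
      double x = 1.0 + 2.0 * a * r2;
      if (r3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) {
        cos_theta = 1.0 - (x - 1.0) / a;
        return x;
      }
    } else {
      double x = (2.0 * a + 1.0) / (2.0 * a * r2 + 1.0);
      double c = 1.0 - (x - 1.0) / a;
      if (r3 <= 0.5 * (c * c + 1.0 / x)) {
        cos_theta = c;
        return x;
      }
    }
  }
}

// Coherent (Rayleigh) scattering angle: screened hydrogen-like form factor
// F(q)/Z = (1 + (q/qc)^2)^-2 with qc = 0.47 * Zeff^(1/3) inverse Angstrom;
// sample q^2 from the FF^2-weighted density (analytic inverse CDF), then
// accept with the Thomson factor (1 + cos^2)/2.
static inline double sample_coherent(Xoshiro& rng, double e_kev, double zeff) {
  double qmax = e_kev / HC_KEV_A;                 // q at theta = 180 deg
  double qc = 0.47 * std::cbrt(zeff);
  double umax = (qmax / qc) * (qmax / qc);
  double tail = 1.0 - std::pow(1.0 + umax, -3.0);
  for (;;) {
    double xi = rng.u();
    double u = std::pow(1.0 - xi * tail, -1.0 / 3.0) - 1.0;
    double c = 1.0 - 2.0 * (u * qc * qc) / (qmax * qmax);
    if (rng.u() <= 0.5 * (1.0 + c * c)) return c;
  }
}

// ---------------------------------------------------------------------------
struct Tally {
  // cylindrical (r, theta)
  std::vector<double> r_edges, th_edges;          // th in degrees
  // transverse-axis profile: cylinder of radius prof_rad around x axis
  std::vector<double> prof_edges;
  double prof_rad2;
  // plane slab |y| <= slab_half, pixels in (x, z)
  std::vector<double> plane_edges;
  double slab_half;
  // "film" slab x in [film_x0, film_x1), annular bins in rho = sqrt(y^2+z^2)
  std::vector<double> film_rho_edges;
  double film_x0, film_x1;

  std::vector<double> cyl, prof, plane, film;     // batch buffers
  std::vector<double> cyl_s, cyl_s2, prof_s, prof_s2, plane_s, plane_s2,
    film_s, film_s2;

  int nr, nth, npx, npl, nfm;

  void init() {
    nr = (int)r_edges.size() - 1;
    nth = (int)th_edges.size() - 1;
    npx = (int)prof_edges.size() - 1;
    npl = (int)plane_edges.size() - 1;
    nfm = (int)film_rho_edges.size() - 1;
    cyl.assign(nr * nth, 0.0); prof.assign(npx, 0.0);
    plane.assign(npl * npl, 0.0); film.assign(nfm, 0.0);
    cyl_s = cyl; cyl_s2 = cyl; prof_s = prof; prof_s2 = prof;
    plane_s = plane; plane_s2 = plane; film_s = film; film_s2 = film;
  }
  inline int find_bin(const std::vector<double>& edges, double v) const {
    if (v < edges.front() || v >= edges.back()) return -1;
    return (int)(std::upper_bound(edges.begin(), edges.end(), v) -
                 edges.begin()) - 1;
  }
  inline void score(double x, double y, double z, double w) {
    double r = std::sqrt(x * x + y * y + z * z);
    int ir = find_bin(r_edges, r);
    if (ir >= 0) {
      double th = std::acos(std::min(1.0, std::max(-1.0, z / r))) * 180.0 / M_PI;
      int it = find_bin(th_edges, th);
      if (it >= 0) cyl[ir * nth + it] += w;
    }
    if (y * y + z * z <= prof_rad2) {
      int ip = find_bin(prof_edges, x);
      if (ip >= 0) prof[ip] += w;
    }
    if (std::fabs(y) <= slab_half) {
      int ix = find_bin(plane_edges, x);
      int iz = find_bin(plane_edges, z);
      if (ix >= 0 && iz >= 0) plane[ix * npl + iz] += w;
    }
    if (x >= film_x0 && x < film_x1) {
      int im = find_bin(film_rho_edges, std::sqrt(y * y + z * z));
      if (im >= 0) film[im] += w;
    }
  }
  // Track-length estimator: deposit expected collision kerma along a flight
  // segment by adaptive sub-stepping (step length ~ 5% of the local radius,
  // matching the log-spaced radial grid).  Each sub-step is scored at a
  // uniformly random point within it, which makes the line-integral
  // estimate unbiased for any partition (a deterministic evaluation point
  // would alias against the geometric bin structure, since all primary
  // flights start at the source).  w_per_len[region] is
  // E * mu_en/rho * rho per unit track length.
  template <class RNG>
  inline void score_segment(const Geom& g, RNG& rng, double x, double y,
                            double z, double ux, double uy, double uz,
                            double s, const double* w_per_len) {
    double t = 0.0;
    while (t < s) {
      double px = x + t * ux, py = y + t * uy, pz = z + t * uz;
      double r = std::sqrt(px * px + py * py + pz * pz);
      double dl = 0.05 * r;
      if (dl < 0.02) dl = 0.02;
      if (dl > s - t) dl = s - t;
      double h = t + rng.u() * dl;
      double mx = x + h * ux, my = y + h * uy, mz = z + h * uz;
      score(mx, my, mz, w_per_len[g.region(mx)] * dl);
      t += dl;
    }
  }
  void flush() {
    for (size_t i = 0; i < cyl.size(); ++i) {
      cyl_s[i] += cyl[i]; cyl_s2[i] += cyl[i] * cyl[i]; cyl[i] = 0.0;
    }
    for (size_t i = 0; i < prof.size(); ++i) {
      prof_s[i] += prof[i]; prof_s2[i] += prof[i] * prof[i]; prof[i] = 0.0;
    }
    for (size_t i = 0; i < plane.size(); ++i) {
      plane_s[i] += plane[i]; plane_s2[i] += plane[i] * plane[i]; plane[i] = 0.0;
    }
    for (size_t i = 0; i < film.size(); ++i) {
      film_s[i] += film[i]; film_s2[i] += film[i] * film[i]; film[i] = 0.0;
    }
  }
};

struct Source {
  std::vector<double> cum_prob, energy, mu_ir;   // mu_ir: pellet attenuation
  double half_len, radius;
  bool self_abs;
  inline int sample_line(Xoshiro& rng) const {
    double xi = rng.u();
    for (size_t i = 0; i < cum_prob.size(); ++i)
      if (xi < cum_prob[i]) return (int)i;
    return (int)cum_prob.size() - 1;
  }
  inline void sample_position(Xoshiro& rng, double& x, double& y, double& z) const {
    double rho = radius * std::sqrt(rng.u());
    double phi = 2.0 * M_PI * rng.u();
    x = rho * std::cos(phi); y = rho * std::sin(phi);
    z = half_len * (2.0 * rng.u() - 1.0);
  }
  // chord from an interior point along (ux,uy,uz) to the pellet surface
  inline double exit_path(double x, double y, double z,
                          double ux, double uy, double uz) const {
    double c2 = ux * ux + uy * uy;
    double t_r = 1e30;
    if (c2 > 1e-20) {
      double c1 = x * ux + y * uy;
      double c0 = x * x + y * y - radius * radius;
      double disc = c1 * c1 - c2 * c0;
      t_r = (-c1 + std::sqrt(std::max(0.0, disc))) / c2;
    }
    double t_z = 1e30;
    if (uz > 1e-20) t_z = (half_len - z) / uz;
    else if (uz < -1e-20) t_z = (-half_len - z) / uz;
    return std::min(t_r, t_z);
  }
};

static inline void sample_isotropic(Xoshiro& rng, double& ux, double& uy, double& uz) {
  uz = 2.0 * rng.u() - 1.0;
  double phi = 2.0 * M_PI * rng.u();
  double s = std::sqrt(std::max(0.0, 1.0 - uz * uz));
  ux = s * std::cos(phi); uy = s * std::sin(phi);
}

// majorant lookup across the phantom's materials
static inline double majorant(const std::vector<MatTable>& mats,
                              const std::vector<int>& region_mat,
                              double e) {
  double m = 0.0;
  for (size_t i = 0; i < region_mat.size(); ++i)
    m = std::max(m, mats[region_mat[i]].mu_tot(e));
  return m;
}

// [[Rcpp::export(name = "cpp_run_simulation")]]
List cpp_run_simulation(List source_cfg, List geom_cfg, List mats_cfg,
                        IntegerVector region_mat_r,
                        List grids, double n_histories, int batches,
                        double seed, double cutoff_kev, int estimator,
                        bool include_coherent, bool disable_interactions) {
  Source src;
  NumericVector en = source_cfg["energy_keV"], pr = source_cfg["probability"];
  NumericVector mu_ir = source_cfg["mu_ir_lines"];
  double c = 0.0;
  for (int i = 0; i < en.size(); ++i) {
    c += pr[i];
    src.cum_prob.push_back(c);
    src.energy.push_back(en[i]);
    src.mu_ir.push_back(mu_ir[i]);
  }
  src.half_len = as<double>(source_cfg["half_length"]);
  src.radius = as<double>(source_cfg["radius"]);
  src.self_abs = as<bool>(source_cfg["self_absorption"]);

  Geom g;
  g.half = as<double>(geom_cfg["half_size"]);
  g.two_region = as<bool>(geom_cfg["two_region"]);
  g.d = g.two_region ? as<double>(geom_cfg["interface_offset"]) : 0.0;

  std::vector<MatTable> mats;
  for (int i = 0; i < mats_cfg.size(); ++i)
    mats.push_back(make_mat(mats_cfg[i]));
  std::vector<int> region_mat(region_mat_r.begin(), region_mat_r.end());

  Tally tl;
  tl.r_edges = as<std::vector<double> >(grids["r_edges"]);
  tl.th_edges = as<std::vector<double> >(grids["theta_edges"]);
  tl.prof_edges = as<std::vector<double> >(grids["profile_edges"]);
  double pr_rad = as<double>(grids["profile_radius"]);
  tl.prof_rad2 = pr_rad * pr_rad;
  tl.plane_edges = as<std::vector<double> >(grids["plane_edges"]);
  tl.slab_half = as<double>(grids["slab_half"]);
  tl.film_rho_edges = as<std::vector<double> >(grids["film_rho_edges"]);
  NumericVector fx = grids["film_x_range"];
  tl.film_x0 = fx[0]; tl.film_x1 = fx[1];
  tl.init();

  Xoshiro rng((uint64_t)seed * 0x9E3779B97f4A7C15ULL + 1ULL);

  const bool track_length = (estimator == 0);
  double n_per_batch = std::floor(n_histories / batches);
  if (n_per_batch < 1) { n_per_batch = 1; batches = (int)n_histories; }
  double n_total = n_per_batch * batches;

  double e_emitted = 0.0, e_deposited = 0.0, e_escaped = 0.0;
  double n_escaped_photons = 0.0;

  for (int b = 0; b < batches; ++b) {
    for (double h = 0; h < n_per_batch; ++h) {
      int line = src.sample_line(rng);
      double E = src.energy[line];
      double x, y, z, ux, uy, uz;
      src.sample_position(rng, x, y, z);
      sample_isotropic(rng, ux, uy, uz);
      e_emitted += E;

      if (src.self_abs) {
        // primary self-absorption in the iridium pellet: reject with the
        // attenuation over the chord to the pellet surface (absorbed
        // photons deposit inside the source, outside every scoring bin)
        double chord = src.exit_path(x, y, z, ux, uy, uz);
        if (rng.u() > std::exp(-src.mu_ir[line] * chord)) {
          e_deposited += E;
          continue;
        }
      }

      double e_cur = E;
      double mu_maj = disable_interactions ? 0.05 :
        majorant(mats, region_mat, e_cur);
      double w_per_len[2] = {0.0, 0.0};
      if (track_length)
        for (size_t k = 0; k < region_mat.size(); ++k) {
          const MatTable& mk = mats[region_mat[k]];
          w_per_len[k] = e_cur * mk.muen_rho(e_cur) * mk.density;
        }
      bool alive = true;
      while (alive) {
        double s = -std::log(rng.u_open()) / mu_maj;
        // clip the scored segment to the cube exit
        double tx = ((ux > 0 ? g.half : -g.half) - x) / (ux != 0 ? ux : 1e-300);
        double ty = ((uy > 0 ? g.half : -g.half) - y) / (uy != 0 ? uy : 1e-300);
        double tz = ((uz > 0 ? g.half : -g.half) - z) / (uz != 0 ? uz : 1e-300);
        double t_exit = std::min(tx, std::min(ty, tz));
        if (track_length)
          tl.score_segment(g, rng, x, y, z, ux, uy, uz, std::min(s, t_exit),
                           w_per_len);
        x += s * ux; y += s * uy; z += s * uz;
        if (g.outside(x, y, z)) {
          e_escaped += e_cur;
          n_escaped_photons += 1.0;
          break;
        }
        const MatTable& m = mats[region_mat[g.region(x)]];
        if (disable_interactions) continue;
        double mu_loc = m.mu_tot(e_cur);
        if (rng.u() * mu_maj > mu_loc) continue;    // virtual collision
        // real collision: select channel
        double xi = rng.u() * mu_loc;
        double p_pe = m.mu_pe(e_cur);
        double p_ic = m.mu_incoh(e_cur);
        if (!include_coherent) {
          // renormalise onto pe + incoherent only
          xi = rng.u() * (p_pe + p_ic);
        }
        if (xi < p_pe) {                            // photoelectric
          if (!track_length) tl.score(x, y, z, e_cur);
          e_deposited += e_cur;
          alive = false;
        } else if (xi < p_pe + p_ic) {              // incoherent (Compton)
          double ct;
          double ratio = sample_kn(rng, e_cur, ct);
          double e_new = e_cur / ratio;
          double edep = e_cur - e_new;
          if (!track_length && edep > 0.0) tl.score(x, y, z, edep);
          e_deposited += edep;
          rotate_direction(ux, uy, uz, ct, 2.0 * M_PI * rng.u());
          e_cur = e_new;
          if (e_cur < cutoff_kev) {                 // local deposit, stop
            if (!track_length) tl.score(x, y, z, e_cur);
            e_deposited += e_cur;
            alive = false;
          } else {
            mu_maj = majorant(mats, region_mat, e_cur);
            if (track_length)
              for (size_t k = 0; k < region_mat.size(); ++k) {
                const MatTable& mk = mats[region_mat[k]];
                w_per_len[k] = e_cur * mk.muen_rho(e_cur) * mk.density;
              }
          }
        } else {                                    // coherent (Rayleigh)
          double ct = sample_coherent(rng, e_cur, m.zeff);
          rotate_direction(ux, uy, uz, ct, 2.0 * M_PI * rng.u());
        }
      }
    }
    tl.flush();
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix cyl_s(tl.nth, tl.nr), cyl_s2(tl.nth, tl.nr);
  for (int ir = 0; ir < tl.nr; ++ir)
    for (int it = 0; it < tl.nth; ++it) {
      cyl_s(it, ir) = tl.cyl_s[ir * tl.nth + it];
      cyl_s2(it, ir) = tl.cyl_s2[ir * tl.nth + it];
    }
  NumericMatrix pl_s(tl.npl, tl.npl), pl_s2(tl.npl, tl.npl);
  for (int ix = 0; ix < tl.npl; ++ix)
    for (int iz = 0; iz < tl.npl; ++iz) {
      pl_s(iz, ix) = tl.plane_s[ix * tl.npl + iz];
      pl_s2(iz, ix) = tl.plane_s2[ix * tl.npl + iz];
    }

  return List::create(
    _["cyl_sum"] = cyl_s, _["cyl_sumsq"] = cyl_s2,
    _["profile_sum"] = NumericVector(tl.prof_s.begin(), tl.prof_s.end()),
    _["profile_sumsq"] = NumericVector(tl.prof_s2.begin(), tl.prof_s2.end()),
    _["plane_sum"] = pl_s, _["plane_sumsq"] = pl_s2,
    _["film_sum"] = NumericVector(tl.film_s.begin(), tl.film_s.end()),
    _["film_sumsq"] = NumericVector(tl.film_s2.begin(), tl.film_s2.end()),
    _["n_histories"] = n_total, _["n_per_batch"] = n_per_batch,
    _["batches"] = batches,
    _["total_emitted_energy"] = e_emitted,
    _["total_deposited_energy"] = e_deposited,
    _["total_escaped_energy"] = e_escaped,
    _["n_escaped_photons"] = n_escaped_photons);
}

// Event-by-event transport of n photons launched from a common initial state.
// channel codes: 1 photoelectric, 2 incoherent, 3 coherent, 4 cutoff deposit,
// 5 escape.
// [[Rcpp::export(name = "cpp_transport_events")]]
DataFrame cpp_transport_events(double energy_kev, NumericVector position,
                               NumericVector direction, List geom_cfg,
                               List mats_cfg, IntegerVector region_mat_r,
                               double n, double seed, double cutoff_kev,
                               bool include_coherent,
                               bool disable_interactions) {
  Geom g;
  g.half = as<double>(geom_cfg["half_size"]);
  g.two_region = as<bool>(geom_cfg["two_region"]);
  g.d = g.two_region ? as<double>(geom_cfg["interface_offset"]) : 0.0;
  std::vector<MatTable> mats;
  for (int i = 0; i < mats_cfg.size(); ++i) mats.push_back(make_mat(mats_cfg[i]));
  std::vector<int> region_mat(region_mat_r.begin(), region_mat_r.end());

  Xoshiro rng((uint64_t)seed * 0x9E3779B97f4A7C15ULL + 2ULL);

  std::vector<double> out_id, out_x, out_y, out_z, out_edep, out_energy;
  std::vector<int> out_ch;
  auto rec = [&](double id, double x, double y, double z, int ch,
                 double edep, double e) {
    out_id.push_back(id); out_x.push_back(x); out_y.push_back(y);
    out_z.push_back(z); out_ch.push_back(ch); out_edep.push_back(edep);
    out_energy.push_back(e);
  };

  for (double id = 1; id <= n; ++id) {
    double x = position[0], y = position[1], z = position[2];
    double ux = direction[0], uy = direction[1], uz = direction[2];
    double e_cur = energy_kev;
    double mu_maj = disable_interactions ? 0.1 :
      majorant(mats, region_mat, e_cur);
    bool alive = true;
    int guard = 0;
    while (alive && ++guard < 100000) {
      double s = -std::log(rng.u_open()) / mu_maj;
      x += s * ux; y += s * uy; z += s * uz;
      if (g.outside(x, y, z)) { rec(id, x, y, z, 5, 0.0, e_cur); break; }
      if (disable_interactions) continue;
      const MatTable& m = mats[region_mat[g.region(x)]];
      double mu_loc = m.mu_tot(e_cur);
      if (rng.u() * mu_maj > mu_loc) continue;
      double xi = rng.u() * mu_loc;
      double p_pe = m.mu_pe(e_cur);
      double p_ic = m.mu_incoh(e_cur);
      if (!include_coherent) xi = rng.u() * (p_pe + p_ic);
      if (xi < p_pe) {
        rec(id, x, y, z, 1, e_cur, 0.0);
        alive = false;
      } else if (xi < p_pe + p_ic) {
        double ct;
        double ratio = sample_kn(rng, e_cur, ct);
        double e_new = e_cur / ratio;
        rec(id, x, y, z, 2, e_cur - e_new, e_new);
        rotate_direction(ux, uy, uz, ct, 2.0 * M_PI * rng.u());
        e_cur = e_new;
        if (e_cur < cutoff_kev) {
          rec(id, x, y, z, 4, e_cur, 0.0);
          alive = false;
        } else {
          mu_maj = majorant(mats, region_mat, e_cur);
        }
      } else {
        double ct = sample_coherent(rng, e_cur, m.zeff);
        rec(id, x, y, z, 3, 0.0, e_cur);
        rotate_direction(ux, uy, uz, ct, 2.0 * M_PI * rng.u());
      }
    }
  }
  return DataFrame::create(
    _["id"] = out_id, _["x"] = out_x, _["y"] = out_y, _["z"] = out_z,
    _["channel"] = out_ch, _["energy_transferred_keV"] = out_edep,
    _["energy_after_keV"] = out_energy);
}
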