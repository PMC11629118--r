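// Layered-slab photon transport (hop-drop-spin with photon weights), the
// forward model behind the double-integrating-sphere inverse problem.
//
// Geometry: z is depth, z = 0 the illuminated surface, layers stacked in
// order of incidence.  Non-scattering, non-absorbing layers (glass slides)
// carry only refraction/Fresnel events.  The collimated specular reflection
// of the leading transparent stack is computed analytically at launch and
// excluded from Rd; diffuse photons re-exiting within a small axial cone are
// also booked as specular (background-subtracted measurement convention).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

// xoshiro256++, seeded through splitmix64.  Self-contained so that runs are
// bitwise reproducible independently of R's RNG state.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97F4A7C15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t v, int k) {
    return (v << k) | (v >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
  inline double unif_open() {  // (0, 1]
    return 1.0 - unif();
  }
};

// Unpolarized Fresnel reflectance; 1 beyond the critical angle.
inline double fresnel_R(double ni, double nt, double cosi) {
  if (cosi > 1.0) cosi = 1.0;
  if (cosi < 0.0) cosi = 0.0;
  if (ni == nt) return 0.0;
  const double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  const double sint = ni * sini / nt;
  if (sint >= 1.0) return 1.0;
  const double cost = std::sqrt(1.0 - sint * sint);
  const double rs = (ni * cosi - nt * cost) / (ni * cosi + nt * cost);
  const double rp = (ni * cost - nt * cosi) / (ni * cost + nt * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

// Collimated reflectance of a pile of interfaces at normal incidence with
// incoherent multiple internal reflections:
//   R_k = r_k + (1 - r_k)^2 R_{k+1} / (1 - r_k R_{k+1})
double stack_reflectance(const std::vector<double>& r) {
  double R = 0.0;
  for (int k = static_cast<int>(r.size()) - 1; k >= 0; --k) {
    const double rk = r[k];
    R = rk + (1.0 - rk) * (1.0 - rk) * R / (1.0 - rk * R);
  }
  return R;
}

inline double hg_cosine(double u, double g) {
  if (g == 0.0) return 2.0 * u - 1.0;
  const double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - f * f) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

}  // namespace

// [[Rcpp::export(name = ".mc_kernel")]]
List mc_kernel(NumericMatrix layers, double ambient_n, double beam_radius,
               double port_radius, double cone_cos, double max_radius,
               double n_photons, double seed, double w_threshold,
               double roulette_p) {
  const int L = layers.nrow();
  if (L < 1) stop("empty layer stack");
  const R_xlen_t N = static_cast<R_xlen_t>(n_photons);
  if (N < 1) stop("n_photons must be >= 1");

  std::vector<double> d(L), nn(L), mua(L), mus(L), g(L), mut(L);
  std::vector<double> ztop(L), zbot(L), inv_mut(L), albedo_a(L);
  std::vector<double> hg_sum(L), hg_dif(L), hg_den(L), hg_inv2g(L);
  double z0 = 0.0;
  for (int k = 0; k < L; ++k) {
    d[k] = layers(k, 0);
    nn[k] = layers(k, 1);
    mua[k] = layers(k, 2);
    mus[k] = layers(k, 3);
    g[k] = layers(k, 4);
    mut[k] = mua[k] + mus[k];
    if (d[k] <= 0) stop("layer thickness must be positive");
    ztop[k] = z0;
    z0 += d[k];
    zbot[k] = z0;
    inv_mut[k] = mut[k] > 0 ? 1.0 / mut[k] : 0.0;
    albedo_a[k] = mut[k] > 0 ? mua[k] / mut[k] : 0.0;
    hg_sum[k] = 1.0 + g[k] * g[k];
    hg_dif[k] = 1.0 - g[k] * g[k];
    hg_den[k] = 1.0 - g[k];
    hg_inv2g[k] = g[k] != 0.0 ? 1.0 / (2.0 * g[k]) : 0.0;
  }

  // first interacting layer (mu_t > 0); leading transparent layers are
  // folded into the analytic collimated launch.
  int k0 = -1;
  for (int k = 0; k < L; ++k) {
    if (mut[k] > 0) { k0 = k; break; }
  }

  double tally_spec_diff = 0.0, tally_Rd = 0.0, tally_Tt = 0.0;
  double tally_abs = 0.0, tally_lost = 0.0;
  double sumRd = 0.0, sumRd2 = 0.0, sumTt = 0.0, sumTt2 = 0.0;

  if (k0 < 0) {
    // fully transparent stack: purely collimated, handled analytically.
    std::vector<double> r;
    double nprev = ambient_n;
    for (int k = 0; k < L; ++k) {
      r.push_back(fresnel_R(nprev, nn[k], 1.0));
      nprev = nn[k];
    }
    r.push_back(fresnel_R(nprev, ambient_n, 1.0));
    const double Rtot = stack_reflectance(r);
    return List::create(
        _["specular"] = Rtot, _["Rd"] = 0.0, _["Tt"] = 1.0 - Rtot,
        _["absorbed"] = 0.0, _["lost"] = 0.0, _["se_Rd"] = 0.0,
        _["se_Tt"] = 0.0, _["n_photons"] = static_cast<double>(N));
  }

  // analytic specular of the leading stack (ambient | L_0..L_{k0-1} | L_k0)
  std::vector<double> r_lead;
  {
    double nprev = ambient_n;
    for (int k = 0; k < k0; ++k) {
      r_lead.push_back(fresnel_R(nprev, nn[k], 1.0));
      nprev = nn[k];
    }
    r_lead.push_back(fresnel_R(nprev, nn[k0], 1.0));
  }
  const double R_spec = stack_reflectance(r_lead);  // zero-variance term

  const double w0 = 1.0 - R_spec;
  const double maxr2 =
      std::isfinite(max_radius) ? max_radius * max_radius : R_PosInf;
  const double port2 =
      std::isfinite(port_radius) ? port_radius * port_radius : R_PosInf;

  Xoshiro rng(static_cast<uint64_t>(seed));
  const double TWO_PI = 6.283185307179586476925286766559;

  for (R_xlen_t i = 0; i < N; ++i) {
    double x = 0.0, y = 0.0;
    if (beam_radius > 0) {
      const double rr = beam_radius * std::sqrt(rng.unif());
      const double ph = TWO_PI * rng.unif();
      x = rr * std::cos(ph);
      y = rr * std::sin(ph);
    }
    double z = ztop[k0];
    double ux = 0.0, uy = 0.0, uz = 1.0;
    double w = w0;
    int lay = k0;
    double s_ = 0.0;  // dimensionless optical path remaining
    bool alive = true;
    long guard = 0;

    while (alive) {
      if (++guard > 100000000L) {  // unreachable in practice
        tally_lost += w;
        break;
      }
      if (s_ <= 0.0) s_ = -std::log(rng.unif_open());

      const double mt = mut[lay];
      bool hit_boundary;
      double db;
      if (uz > 0.0)
        db = (zbot[lay] - z) / uz;
      else if (uz < 0.0)
        db = (ztop[lay] - z) / uz;
      else
        db = R_PosInf;

      if (mt <= 0.0) {
        if (!std::isfinite(db)) {  // horizontal flight in transparent layer
          tally_lost += w;
          break;
        }
        hit_boundary = true;
      } else {
        hit_boundary = (db * mt <= s_);
      }

      double step = hit_boundary ? db : s_ * inv_mut[lay];
      x += ux * step;
      y += uy * step;
      z += uz * step;
      if (hit_boundary)
        s_ -= (mt > 0.0) ? db * mt : 0.0;
      else
        s_ = 0.0;

      if (x * x + y * y > maxr2) {  // beyond the physical sample edge
        tally_lost += w;
        break;
      }

      if (hit_boundary) {
        const bool going_down = (uz > 0.0);
        const int next = going_down ? lay + 1 : lay - 1;
        const double ni = nn[lay];
        const double nt =
            (next < 0 || next >= L) ? ambient_n : nn[next];
        const double cosi = std::fabs(uz);
        const double R = fresnel_R(ni, nt, cosi);
        if (rng.unif() < R) {
          uz = -uz;  // internal reflection
          z = going_down ? zbot[lay] : ztop[lay];
        } else {
          const double ratio = ni / nt;
          const double sint2 = ratio * ratio * (1.0 - cosi * cosi);
          const double cost = std::sqrt(std::max(0.0, 1.0 - sint2));
          ux *= ratio;
          uy *= ratio;
          uz = going_down ? cost : -cost;
          if (next >= 0 && next < L) {
            lay = next;
            z = going_down ? ztop[lay] : zbot[lay];
          } else {
            const double r2 = x * x + y * y;
            if (!going_down) {  // re-emitted on the illuminated side
              if (cost >= cone_cos)
                tally_spec_diff += w;  // near-axial: booked with specular
              else if (r2 <= port2) {
                tally_Rd += w;
                sumRd += w;
                sumRd2 += w * w;
              } else
                tally_lost += w;
            } else {  // transmitted side
              if (r2 <= port2) {
                tally_Tt += w;
                sumTt += w;
                sumTt2 += w * w;
              } else
                tally_lost += w;
            }
            alive = false;
          }
        }
        continue;
      }

      // interaction: absorb, then scatter
      const double dw = w * albedo_a[lay];
      tally_abs += dw;
      w -= dw;
      if (w <= 0.0) break;  // fully absorbed (pure absorber)

      double ct;
      {
        const double u = rng.unif();
        if (g[lay] == 0.0) {
          ct = 2.0 * u - 1.0;
        } else {
          const double f = hg_dif[lay] / (hg_den[lay] + 2.0 * g[lay] * u);
          ct = (hg_sum[lay] - f * f) * hg_inv2g[lay];
          if (ct > 1.0) ct = 1.0;
          if (ct < -1.0) ct = -1.0;
        }
      }
      const double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      // uniform azimuth via the polar rejection method (no trig calls)
      double cp, sp;
      for (;;) {
        const double v1 = 2.0 * rng.unif() - 1.0;
        const double v2 = 2.0 * rng.unif() - 1.0;
        const double ss = v1 * v1 + v2 * v2;
        if (ss > 0.0 && ss < 1.0) {
          cp = (v1 * v1 - v2 * v2) / ss;
          sp = 2.0 * v1 * v2 / ss;
          break;
        }
      }
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp;
        uy = st * sp;
        uz = (uz >= 0.0) ? ct : -ct;
      } else {
        const double den = std::sqrt(1.0 - uz * uz);
        const double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        const double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        const double nuz = -den * st * cp + uz * ct;
        ux = nux;
        uy = nuy;
        uz = nuz;
      }

      if (w < w_threshold) {  // Russian roulette, ledger-exact
        if (rng.unif() < roulette_p) {
          tally_abs -= w * (1.0 / roulette_p - 1.0);
          w /= roulette_p;
        } else {
          tally_abs += w;
          alive = false;
        }
      }
    }
  }

  const double dN = static_cast<double>(N);
  const double Rd = tally_Rd / dN;
  const double Tt = tally_Tt / dN;
  double se_Rd = 0.0, se_Tt = 0.0;
  if (N > 1) {
    const double vR = (sumRd2 - sumRd * sumRd / dN) / (dN - 1.0);
    const double vT = (sumTt2 - sumTt * sumTt / dN) / (dN - 1.0);
    se_Rd = std::sqrt(std::max(0.0, vR) / dN);
    se_Tt = std::sqrt(std::max(0.0, vT) / dN);
  }

  return List::create(
      _["specular"] = R_spec + tally_spec_diff / dN,
      _["Rd"] = Rd, _["Tt"] = Tt, _["absorbed"] = tally_abs / dN,
      _["lost"] = tally_lost / dN, _["se_Rd"] = se_Rd, _["se_Tt"] = se_Tt,
      _["n_photons"] = dN);
}
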