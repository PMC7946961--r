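// Weighted-photon Monte Carlo transport through a laterally infinite layered
// slab (MCML-style hop/drop/spin), scoring the weight reaching an internal
// implant plane. Self-contained xoshiro256+ RNG so wavelength substreams are
// reproducible and independent of R's RNG state.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

namespace {

struct Rng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t r = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  // uniform in (0, 1]
  double unif() {
    return ((next() >> 11) + 1.0) * 0x1.0p-53;
  }
};

// Unpolarized Fresnel reflectance for incidence cosine ci, indices ni -> nt.
// Returns 1 for total internal reflection; *ct gets the transmission cosine.
double fresnel(double ni, double nt, double ci, double *ct) {
  if (ci > 1.0) ci = 1.0;
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = ni / nt * si;
  if (st >= 1.0) { *ct = 0.0; return 1.0; }
  double c_t = std::sqrt(std::max(0.0, 1.0 - st * st));
  *ct = c_t;
  if (ci > 0.999999) {  // normal incidence limit
    double r = (ni - nt) / (ni + nt);
    return r * r;
  }
  double rs = (ni * ci - nt * c_t) / (ni * ci + nt * c_t);
  double rp = (ni * c_t - nt * ci) / (ni * c_t + nt * ci);
  return 0.5 * (rs * rs + rp * rp);
}

} // namespace

// [[Rcpp::export(name = "mc_slab_transmission")]]
Rcpp::List mc_slab_transmission(Rcpp::NumericVector thickness,
                                Rcpp::NumericVector mua,
                                Rcpp::NumericVector mus,
                                Rcpp::NumericVector g,
                                Rcpp::NumericVector n_layer,
                                double n_ambient,
                                double scd,
                                int n_photons,
                                double seed,
                                bool plane_absorbing,
                                double w_threshold,
                                double p_survive) {
  const int nl = thickness.size();
  std::vector<double> zb(nl + 1, 0.0);
  for (int i = 0; i < nl; ++i) zb[i + 1] = zb[i] + thickness[i];
  const double z_bottom = zb[nl];
  if (scd <= 0.0 || scd > z_bottom + 1e-12)
    Rcpp::stop("implant plane lies outside the layer stack");

  Rng rng(static_cast<uint64_t>(seed) * 0x9e3779b97f4a7c15ULL + 0x243f6a8885a308d3ULL);

  double specular = 0.0, reflected = 0.0, absorbed_tissue = 0.0,
         absorbed_plane = 0.0, transmitted = 0.0, roulette_net = 0.0;
  double sum_plane = 0.0, sumsq_plane = 0.0;

  // specular reflection of the collimated normal beam at the top interface
  double r0 = (n_ambient - n_layer[0]) / (n_ambient + n_layer[0]);
  const double rsp = r0 * r0;

  for (int ip = 0; ip < n_photons; ++ip) {
    double w = 1.0 - rsp;
    specular += rsp;
    double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0;
    int layer = 0;
    bool alive = true, plane_hit = false;
    double photon_plane = 0.0;

    double sleft = -std::log(rng.unif()); // dimensionless optical path budget

    while (alive) {
      const double mut = mua[layer] + mus[layer];
      // geometric distance to the nearest z-limit along uz
      double db = R_PosInf;
      bool to_plane = false;
      if (uz > 0.0) {
        double zlim = zb[layer + 1];
        // the implant plane is an extra boundary inside (or at the bottom of)
        // its layer; only relevant before it has been handled
        if (scd > zb[layer] && scd <= zb[layer + 1] && z < scd &&
            (plane_absorbing || !plane_hit)) {
          if (scd < zlim) { zlim = scd; to_plane = true; }
          else if (scd == zlim) { to_plane = true; }
        }
        db = (zlim - z) / uz;
      } else if (uz < 0.0) {
        db = (zb[layer] - z) / uz;
      }

      double step = (mut > 0.0) ? sleft / mut : R_PosInf;

      if (db <= step && std::isfinite(db)) {
        // move to the boundary
        z += db * uz; // lateral position is irrelevant in the 1-D slab
        if (mut > 0.0) sleft -= db * mut;

        if (to_plane && uz > 0.0 && z >= scd - 1e-15) {
          if (plane_absorbing) {
            absorbed_plane += w;
            photon_plane += w;
            alive = false;
            continue;
          }
          // transparent plane: score first passage, keep going
          photon_plane += w;
          plane_hit = true;
          z = scd;
          // nudge across so the plane is not re-detected at zero distance
          z = std::nextafter(scd, z_bottom + 1.0);
          if (z >= zb[layer + 1]) { /* fall through to interface handling below */ }
          else continue;
        }

        // layer interface / top / bottom
        int next_layer = (uz > 0.0) ? layer + 1 : layer - 1;
        double ni = n_layer[layer];
        double nt = (next_layer < 0) ? n_ambient
                    : (next_layer >= nl) ? n_layer[nl - 1] // matched exit below
                                         : n_layer[next_layer];
        double ci = std::fabs(uz), ct;
        double R = (ni == nt) ? 0.0 : fresnel(ni, nt, ci, &ct);
        if (ni == nt) ct = ci;
        if (rng.unif() < R) {
          uz = -uz; // reflect, stay in layer
        } else {
          if (next_layer < 0) { reflected += w; alive = false; continue; }
          if (next_layer >= nl) { transmitted += w; alive = false; continue; }
          double scale = ni / nt;
          ux *= scale; uy *= scale;
          uz = (uz > 0.0) ? ct : -ct;
          layer = next_layer;
        }
        continue;
      }

      if (!std::isfinite(step)) {
        // vacuum-like layer with uz == 0: photon travels laterally forever;
        // cannot reach any plane, treat as lost to the tissue ledger
        absorbed_tissue += w;
        alive = false;
        continue;
      }

      // interaction inside the layer
      z += step * uz;
      double dw = w * mua[layer] / mut;
      absorbed_tissue += dw;
      w -= dw;

      // spin: Henyey-Greenstein polar angle, uniform azimuth
      double gg = g[layer], cost;
      double r1 = rng.unif();
      if (std::fabs(gg) < 1e-9) {
        cost = 2.0 * r1 - 1.0;
      } else {
        double f = (1.0 - gg * gg) / (1.0 - gg + 2.0 * gg * r1);
        cost = (1.0 + gg * gg - f * f) / (2.0 * gg);
        if (cost > 1.0) cost = 1.0;
        if (cost < -1.0) cost = -1.0;
      }
      double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
      double phi = 2.0 * M_PI * rng.unif();
      double cosp = std::cos(phi), sinp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = sint * cosp;
        uy = sint * sinp;
        uz = (uz >= 0.0) ? cost : -cost;
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = sint * (ux * uz * cosp - uy * sinp) / den + ux * cost;
        double nuy = sint * (uy * uz * cosp + ux * sinp) / den + uy * cost;
        double nuz = -sint * cosp * den + uz * cost;
        double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
        ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
      }

      if (w <= 0.0) { alive = false; continue; }
      if (w < w_threshold) {
        if (rng.unif() < p_survive) {
          roulette_net += w / p_survive - w;
          w /= p_survive;
        } else {
          roulette_net -= w;
          alive = false;
          continue;
        }
      }
      sleft = -std::log(rng.unif());
    }
    sum_plane += photon_plane;
    sumsq_plane += photon_plane * photon_plane;
  }

  const double np = static_cast<double>(n_photons);
  double zeta = sum_plane / np;
  double var = (sumsq_plane / np - zeta * zeta) / np;
  double se = std::sqrt(std::max(0.0, var));

  return Rcpp::List::create(
    Rcpp::Named("zeta") = zeta,
    Rcpp::Named("stderr") = se,
    Rcpp::Named("ledger") = Rcpp::NumericVector::create(
      Rcpp::Named("specular") = specular / np,
      Rcpp::Named("reflected") = reflected / np,
      Rcpp::Named("absorbed_tissue") = absorbed_tissue / np,
      Rcpp::Named("absorbed_plane") = absorbed_plane / np,
      Rcpp::Named("transmitted") = transmitted / np,
      Rcpp::Named("roulette_net") = -roulette_net / np)
  );
}
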