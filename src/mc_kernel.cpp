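// Monte Carlo photon transport in a semi-infinite turbid medium with
// oblique illumination and NA-constrained detection at the z = 0 surface.
// Lengths in mm; z grows with depth.
//
// Random numbers come from a local xoshiro256++ generator whose state is
// seeded from R's RNG, so runs are fully reproducible under set.seed()
// while keeping the per-draw cost low. Absorption is applied lazily as
// exp(-mua * accumulated path length), evaluated only at termination and
// at Russian-roulette events; the weight bookkeeping still closes exactly.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct Xoshiro256pp {
  uint64_t s[4];

  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }

  // expand a 64-bit value into the full state via splitmix64
  void seed(uint64_t x) {
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }

  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in (0, 1): 53-bit resolution, never exactly 0 or 1
  double runif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

struct PfSampler {
  int family;           // 0 = henyey-greenstein, 1 = gegenbauer kernel
  double g, sigma;
  double A, B, inv_sigma;
  bool sigma_is_one;

  void init(int fam, double g_, double sigma_) {
    family = fam;
    g = g_;
    sigma = sigma_;
    A = std::pow(1.0 + g, 2.0 * sigma);
    B = std::pow(1.0 - g, 2.0 * sigma);
    inv_sigma = 1.0 / sigma;
    sigma_is_one = std::fabs(sigma - 1.0) < 1e-12;
  }

  double sample(double u) const {
    double mu;
    if (family == 0) {
      double t = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
      mu = (1.0 + g * g - t * t) / (2.0 * g);
    } else {
      double base = A * B / (B + u * (A - B));
      double t = sigma_is_one ? base : std::pow(base, inv_sigma);
      mu = (1.0 + g * g - t) / (2.0 * g);
    }
    if (mu > 1.0) mu = 1.0;
    if (mu < -1.0) mu = -1.0;
    return mu;
  }
};

inline void spin(double &ux, double &uy, double &uz, double mu, double phi) {
  double sint = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  double cosp = std::cos(phi), sinp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = sint * cosp;
    uy = sint * sinp;
    uz = (uz >= 0.0 ? mu : -mu);
  } else {
    double tmp = std::sqrt(1.0 - uz * uz);
    double nx = sint * (ux * uz * cosp - uy * sinp) / tmp + ux * mu;
    double ny = sint * (uy * uz * cosp + ux * sinp) / tmp + uy * mu;
    double nz = -sint * cosp * tmp + uz * mu;
    ux = nx; uy = ny; uz = nz;
  }
  // renormalise to curb round-off drift
  double n = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= n; uy /= n; uz /= n;
}

} // namespace

// [[Rcpp::export]]
List mc_propagate(int n_photons, double mus, double mua,
                  int pf_family, double g_R, double sigma,
                  NumericVector launch_dir,
                  double n_medium, double n_upper,
                  NumericVector det_axis, double cos_accept,
                  double depth_cutoff, double w_min,
                  double roulette_survive,
                  int record_paths, bool keep_all,
                  double max_events) {
  const double lx = launch_dir[0], ly = launch_dir[1], lz = launch_dir[2];
  const double ax = det_axis[0], ay = det_axis[1], az = det_axis[2];
  const double rn = n_medium / n_upper;
  const double inv_mus = 1.0 / mus;

  // seed the local generator from R's RNG stream
  uint64_t seed64;
  {
    RNGScope scope;
    double a = unif_rand(), b = unif_rand();
    seed64 = (uint64_t)(a * 4294967296.0) << 32 |
             (uint64_t)(b * 4294967296.0);
  }
  Xoshiro256pp rng;
  rng.seed(seed64);

  PfSampler pf;
  pf.init(pf_family, g_R, sigma);

  std::vector<double> rec_x, rec_w, rec_depth;
  std::vector<int> rec_acc;

  double w_detected = 0.0, w_exit_rejected = 0.0, w_absorbed = 0.0;
  double w_cutoff = 0.0, w_roulette_net = 0.0;

  // optional full-path capture for the first `record_paths` accepted photons
  List paths(record_paths);
  int n_paths_kept = 0;
  std::vector<double> pvx, pvy, pvz;

  for (int i = 0; i < n_photons; ++i) {
    double x = 0.0, y = 0.0, z = 0.0;
    double ux = lx, uy = ly, uz = lz;
    double path = 0.0;        // accumulated path length inside the medium
    double boost = 1.0;       // roulette survival factor
    double last_e = 1.0;      // exp(-mua*path) at the last bookkeeping point
    // path length at which boost * exp(-mua*path) crosses w_min
    double path_thresh =
      (mua > 0.0) ? (std::log(boost) - std::log(w_min)) / mua : R_PosInf;
    double max_depth = 0.0;
    bool capture = (n_paths_kept < record_paths);
    if (capture) {
      pvx.clear(); pvy.clear(); pvz.clear();
      pvx.push_back(x); pvy.push_back(y); pvz.push_back(z);
    }
    double events = 0.0;

    // settle the absorbed weight for the segment since the last roulette
    // event and return the current weight
    auto settle = [&](void) -> double {
      double e = (mua > 0.0) ? std::exp(-mua * path) : 1.0;
      w_absorbed += boost * (last_e - e);
      last_e = e;
      return boost * e;
    };

    for (;;) {
      if (++events > max_events) { w_cutoff += settle(); break; }
      double s = -std::log(rng.runif()) * inv_mus;

      if (uz < 0.0 && z + uz * s < 0.0) {
        // exits through the surface before the next interaction
        double t = -z / uz;
        path += t;
        double w = settle();
        double exit_x = x + ux * t;
        if (capture) {
          pvx.push_back(exit_x); pvy.push_back(y + uy * t); pvz.push_back(0.0);
        }
        // refract into the upper medium and test the acceptance cone
        bool accepted = false;
        double sin2t = rn * rn * (ux * ux + uy * uy);
        if (sin2t < 1.0) {
          double dx = rn * ux, dy = rn * uy, dz = -std::sqrt(1.0 - sin2t);
          accepted = (dx * ax + dy * ay + dz * az) >= cos_accept;
        }
        if (accepted) {
          w_detected += w;
          if (capture) {
            NumericMatrix pm(pvx.size(), 3);
            for (size_t k = 0; k < pvx.size(); ++k) {
              pm(k, 0) = pvx[k]; pm(k, 1) = pvy[k]; pm(k, 2) = pvz[k];
            }
            paths[n_paths_kept++] = pm;
          }
        } else {
          w_exit_rejected += w;
        }
        if (accepted || keep_all) {
          rec_x.push_back(exit_x);
          rec_w.push_back(w);
          rec_depth.push_back(max_depth);
          rec_acc.push_back(accepted ? 1 : 0);
        }
        break;
      }

      // full step inside the medium
      x += ux * s; y += uy * s; z += uz * s;
      path += s;
      if (z > max_depth) max_depth = z;
      if (!(std::isfinite(x) && std::isfinite(y) && std::isfinite(z))) {
        stop("non-finite photon position (photon %d, event %.0f)", i + 1,
             events);
      }
      if (z > depth_cutoff) { w_cutoff += settle(); break; }
      if (capture) { pvx.push_back(x); pvy.push_back(y); pvz.push_back(z); }

      if (path > path_thresh) {
        double w = settle();
        if (rng.runif() < roulette_survive) {
          w_roulette_net -= w * (1.0 / roulette_survive - 1.0);
          boost /= roulette_survive;
          path_thresh = (std::log(boost) - std::log(w_min)) / mua;
        } else {
          w_roulette_net += w;
          break;
        }
      }

      double mu = pf.sample(rng.runif());
      double phi = 2.0 * M_PI * rng.runif();
      spin(ux, uy, uz, mu, phi);
    }
  }

  NumericMatrix rec(rec_x.size(), 4);
  for (size_t k = 0; k < rec_x.size(); ++k) {
    rec(k, 0) = rec_x[k];
    rec(k, 1) = rec_w[k];
    rec(k, 2) = rec_depth[k];
    rec(k, 3) = rec_acc[k];
  }

  return List::create(
    _["records"] = rec,
    _["tallies"] = NumericVector::create(
      _["detected"] = w_detected,
      _["undetected_exit"] = w_exit_rejected,
      _["absorbed"] = w_absorbed,
      _["cutoff_killed"] = w_cutoff,
      _["roulette_net"] = w_roulette_net),
    _["paths"] = paths,
    _["n_paths"] = n_paths_kept);
}
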