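#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Fast RNG stack for the photon loop. R's generic RNG (notably the
// inversion-method normal) costs ~100 ns per photon, which dominates
// dataset generation. Here: xoshiro256++ (seeded via splitmix64 from a
// seed drawn off R's RNG stream, so set.seed() reproducibility is
// preserved) driving Marsaglia-Tsang ziggurat samplers for the normal
// and exponential deviates.
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) {  // splitmix64 state expansion
      seed += 0x9E3779B97f4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  uint32_t next32() { return (uint32_t)(next() >> 32); }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
};

// Ziggurat tables (Marsaglia & Tsang 2000): 128 layers for the normal,
// 256 for the exponential.
struct Ziggurat {
  uint32_t kn[128], ke[256];
  double wn[128], fn[128], we[256], fe[256];
  Ziggurat() {
    const double m1 = 2147483648.0, m2 = 4294967296.0;
    double dn = 3.442619855899, tn = dn, vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = (uint32_t)((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = (uint32_t)((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
    double de = 7.697117470131487, te = de, ve = 3.949659822581572e-3;
    q = ve / std::exp(-de);
    ke[0] = (uint32_t)((de / q) * m2);
    ke[1] = 0;
    we[0] = q / m2;
    we[255] = de / m2;
    fe[0] = 1.0;
    fe[255] = std::exp(-de);
    for (int i = 254; i >= 1; i--) {
      de = -std::log(ve / de + std::exp(-de));
      ke[i + 1] = (uint32_t)((de / te) * m2);
      te = de;
      fe[i] = std::exp(-de);
      we[i] = de / m2;
    }
  }

  double normal(Xoshiro &rng) const {
    for (;;) {
      int32_t hz = (int32_t)rng.next32();
      uint32_t iz = hz & 127;
      if ((uint32_t)std::abs(hz) < kn[iz]) return hz * wn[iz];
      // edge/tail handling
      const double r = 3.442619855899;
      double x = hz * wn[iz];
      if (iz == 0) {
        double y;
        do {
          x = -std::log(rng.unif()) / r;
          y = -std::log(rng.unif());
        } while (y + y < x * x);
        return hz > 0 ? r + x : -r - x;
      }
      if (fn[iz] + rng.unif() * (fn[iz - 1] - fn[iz]) <
          std::exp(-0.5 * x * x)) {
        return x;
      }
    }
  }

  double exponential(Xoshiro &rng) const {
    for (;;) {
      uint32_t jz = rng.next32();
      uint32_t iz = jz & 255;
      if (jz < ke[iz]) return jz * we[iz];
      if (iz == 0) return 7.697117470131487 - std::log(rng.unif());
      double x = jz * we[iz];
      if (fe[iz] + rng.unif() * (fe[iz - 1] - fe[iz]) < std::exp(-x)) {
        return x;
      }
    }
  }
};

const Ziggurat zig;

}  // namespace

// Photon-level Monte-Carlo sampling of one TCSPC decay histogram.
// Each photon: pick the emitting component with probability equal to its
// fractional contribution, draw the fluorescence delay from Exp(tau),
// add the laser turn-off delay Exp(theta) and a Gaussian offset for the
// laser pulse core plus detector jitter, then bin the arrival time.
// Photons outside [0, window) are dropped.
// [[Rcpp::export]]
IntegerVector photon_mc(int n_photons, NumericVector fractions,
                        NumericVector lifetimes, double gauss_sigma,
                        double turnoff_ns, double bin_width_ns, int n_bins,
                        double seed) {
  int k = fractions.size();
  if (lifetimes.size() != k) stop("fractions/lifetimes length mismatch");
  std::vector<double> cum(k);
  double acc = 0.0;
  for (int i = 0; i < k; ++i) { acc += fractions[i]; cum[i] = acc; }
  double window = bin_width_ns * n_bins;
  double inv_bw = 1.0 / bin_width_ns;
  Xoshiro rng((uint64_t)seed);
  IntegerVector counts(n_bins);
  for (int p = 0; p < n_photons; ++p) {
    double u = rng.unif() * acc;
    int comp = 0;
    while (comp < k - 1 && u > cum[comp]) ++comp;
    double t = zig.exponential(rng) * lifetimes[comp];
    if (turnoff_ns > 0.0) t += zig.exponential(rng) * turnoff_ns;
    if (gauss_sigma > 0.0) t += zig.normal(rng) * gauss_sigma;
    if (t >= 0.0 && t < window) {
      counts[(int)(t * inv_bw)] += 1;
    }
  }
  return counts;
}
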