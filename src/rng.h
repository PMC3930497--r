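#pragma once
#include <cstdint>
#include <cmath>

// Deterministic RNG for the simulation engine: xoshiro256++ seeded through
// splitmix64, polar Box-Muller normals, Marsaglia-Tsang gamma deviates.
// One stream per run, draw order fixed by body index, so a run is a pure
// function of (configuration, seed).
struct EngineRng {
  uint64_t s[4];
  bool have_spare = false;
  double spare = 0.0;

  explicit EngineRng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      // splitmix64
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

  // uniform on (0, 1)
  inline double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double f = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * f;
    have_spare = true;
    return u * f;
  }

  // Gamma(shape a >= 1, scale 1), Marsaglia & Tsang (2000)
  double gamma_ge1(double a) {
    double d = a - 1.0 / 3.0;
    double c = 1.0 / std::sqrt(9.0 * d);
    for (;;) {
      double x, v;
      do { x = norm(); v = 1.0 + c * x; } while (v <= 0.0);
      v = v * v * v;
      double u = unif();
      if (u < 1.0 - 0.0331 * x * x * x * x) return d * v;
      if (std::log(u) < 0.5 * x * x + d * (1.0 - v + std::log(v))) return d * v;
    }
  }

  double gamma(double a) {
    if (a >= 1.0) return gamma_ge1(a);
    // boost for a < 1
    double g = gamma_ge1(a + 1.0);
    return g * std::pow(unif(), 1.0 / a);
  }

  inline double chisq(double df) { return 2.0 * gamma(df / 2.0); }
};
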