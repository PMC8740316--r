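#ifndef PERAFR_RNG_H
#define PERAFR_RNG_H

#include <cstdint>
#include <cmath>

// Deterministic, seedable RNG independent of R's global stream so that large
// Monte-Carlo runs (millions of normal draws) stay fast and reproducible.
// xoshiro256++ seeded through splitmix64; normals via a 128-layer ziggurat.

namespace perafr_rng {


struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed into the full state
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t v, int k) { return (v << k) | (v >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0,1): 53-bit mantissa, shifted away from 0 for log()
  double unif() {
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// 128-layer ziggurat for the standard normal (layer geometry computed once)
struct Ziggurat {
  double x[129];   // layer right edges, x[0] widest pseudo-layer
  double ratio[128];
  static constexpr double R = 3.442619855899;
  static constexpr double V = 9.91256303526217e-3;
  Ziggurat() {
    double f = std::exp(-0.5 * R * R);
    x[0] = V / f;
    x[1] = R;
    x[128] = 0.0;
    for (int i = 2; i < 128; ++i) {
      x[i] = std::sqrt(-2.0 * std::log(V / x[i - 1] + f));
      f = std::exp(-0.5 * x[i] * x[i]);
    }
    for (int i = 0; i < 128; ++i) ratio[i] = x[i + 1] / x[i];
  }
};

const Ziggurat zig;

struct NormalGen {
  Xoshiro rng;
  explicit NormalGen(uint64_t seed) : rng(seed) {}
  double tail(bool negative) {
    double a, b;
    do {
      a = std::log(rng.unif()) / Ziggurat::R;
      b = std::log(rng.unif());
    } while (-2.0 * b < a * a);
    return negative ? a - Ziggurat::R : Ziggurat::R - a;
  }
  double next() {
    for (;;) {
      uint64_t bits = rng.next();
      int i = (int)(bits & 127);
      double u = 2.0 * (((bits >> 11) + 0.5) * (1.0 / 9007199254740992.0)) - 1.0;
      if (std::fabs(u) < zig.ratio[i]) return u * zig.x[i];
      if (i == 0) return tail(u < 0);
      double xx = u * zig.x[i];
      double f0 = std::exp(-0.5 * (zig.x[i] * zig.x[i] - xx * xx));
      double f1 = std::exp(-0.5 * (zig.x[i + 1] * zig.x[i + 1] - xx * xx));
      if (f1 + rng.unif() * (f0 - f1) < 1.0) return xx;
    }
  }
};

// combine a user seed with a stream id so each subject / stage gets an
// independent, reproducible stream
inline uint64_t mix_seed(double seed, double stream) {
  uint64_t a = (uint64_t)(int64_t)seed;
  uint64_t b = (uint64_t)(int64_t)stream;
  uint64_t x = a * 0x9e3779b97f4a7c15ULL + b + 0x632be59bd9b4e019ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

}  // namespace perafr_rng

#endif
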