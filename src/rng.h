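#ifndef CASPATIAL_RNG_H
#define CASPATIAL_RNG_H

#include <cstdint>
#include <cmath>

// splitmix64: used only to expand a (seed, stream id) key into xoshiro state.
inline uint64_t splitmix64_next(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// xoshiro256++ — one independent stream per dyad plus one global stream.
struct Xoshiro {
  uint64_t s[4];

  void seed(uint64_t key, uint64_t stream_id) {
    uint64_t x = key ^ (0xA3C59AC2ULL + stream_id * 0x9E3779B97F4A7C15ULL);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64_next(x);
    // avoid the all-zero state (splitmix64 makes this essentially impossible,
    // but guard anyway)
    if (!(s[0] | s[1] | s[2] | s[3])) s[0] = 1;
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
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

  // uniform on (0,1), 53-bit resolution
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

// Binomial(n, p) by geometric waiting-time skipping: O(np + 1) uniforms.
// Exact for 0 <= p <= 1; suitable here because transition probabilities are
// bounded by the rate*dt <= 0.2 contract.
inline int rbinom_stream(Xoshiro &rng, int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  const double l1mp = std::log1p(-p);
  int k = 0;
  double pos = 0.0;
  for (;;) {
    pos += std::floor(std::log(rng.unif()) / l1mp) + 1.0;
    if (pos > n) break;
    ++k;
  }
  return k;
}

#endif
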