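#ifndef VASCTREE_RNG_H
#define VASCTREE_RNG_H

#include <cstdint>

// Self-contained counter-free PRNG (xoshiro256++ seeded via splitmix64) so
// that growth is bit-reproducible and independent per subdomain stream,
// without touching R's global RNG state from compiled code.

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

class Xoshiro256pp {
public:
  explicit Xoshiro256pp(uint64_t seed, uint64_t stream = 0) {
    // mix the stream id into the seed so (seed, i) streams are decorrelated
    uint64_t sm = seed ^ (0x9e3779b97f4a7c15ULL * (stream + 1));
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
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
  // uniform in [0, 1)
  double runif() { return (next() >> 11) * 0x1.0p-53; }

private:
  uint64_t s[4];
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
};

#endif
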