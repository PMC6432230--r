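// Fast counter-free RNG for the simulation engine.
//
// Four independent xoshiro256++ streams are kept per run (thermostat,
// reaction clocks, reservoir clocks, initial placement), all seeded from a
// single master seed via splitmix64, so that any one subsystem draws the
// same numbers regardless of whether the others are active.
//
// Normal deviates use the Marsaglia-Tsang ziggurat (128 layers); the layer
// tables are built once at load time.

#ifndef ACTINOTRAP_RNG_H
#define ACTINOTRAP_RNG_H

#include <cstdint>
#include <cstdlib>
#include <cmath>
#include <cstring>

namespace atrng {

inline uint64_t rotl(uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

inline uint64_t splitmix64(uint64_t &x) {
  x += 0x9E3779B97f4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Stream {
  uint64_t s[4];

  void seed(uint64_t master, uint64_t label) {
    uint64_t x = master ^ (0xA3C59AC2ULL + label * 0x9E3779B97f4A7C15ULL);
    // burn a few splitmix outputs so nearby seeds decorrelate
    splitmix64(x);
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }

  // uniform on the open interval (0,1)
  inline double unif() {
    return (static_cast<double>(next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }

  inline double expdev(double rate) {
    return -std::log(unif()) / rate;
  }

  inline int32_t int32() {
    return static_cast<int32_t>(static_cast<uint32_t>(next() >> 32));
  }

  double normal();  // defined after the ziggurat tables
};

// ---- ziggurat tables (Marsaglia & Tsang 2000, 128 layers) ----
struct ZigTables {
  int32_t kn[128];
  double wn[128], fn[128];
  ZigTables() {
    const double m1 = 2147483648.0;
    double dn = 3.442619855899, tn = dn;
    const double vn = 9.91256303526217e-3;
    double q = vn / std::exp(-0.5 * dn * dn);
    kn[0] = static_cast<int32_t>((dn / q) * m1);
    kn[1] = 0;
    wn[0] = q / m1;
    wn[127] = dn / m1;
    fn[0] = 1.0;
    fn[127] = std::exp(-0.5 * dn * dn);
    for (int i = 126; i >= 1; i--) {
      dn = std::sqrt(-2.0 * std::log(vn / dn + std::exp(-0.5 * dn * dn)));
      kn[i + 1] = static_cast<int32_t>((dn / tn) * m1);
      tn = dn;
      fn[i] = std::exp(-0.5 * dn * dn);
      wn[i] = dn / m1;
    }
  }
};

inline const ZigTables &zig() {
  static const ZigTables tables;
  return tables;
}

inline double Stream::normal() {
  const ZigTables &zt = zig();
  const double r = 3.442619855899;
  for (;;) {
    int32_t hz = int32();
    int iz = hz & 127;
    if (std::abs(hz) < zt.kn[iz]) return hz * zt.wn[iz];
    // slow path
    double xv = hz * zt.wn[iz];
    if (iz == 0) {
      double xx, yy;
      do {
        xx = -std::log(unif()) / r;
        yy = -std::log(unif());
      } while (yy + yy < xx * xx);
      return (hz > 0) ? r + xx : -(r + xx);
    }
    if (zt.fn[iz] + unif() * (zt.fn[iz - 1] - zt.fn[iz]) <
        std::exp(-0.5 * xv * xv))
      return xv;
    // else resample from the top of the loop
  }
}

// ---- the four labelled streams of a run ----
enum StreamLabel { THERMOSTAT = 0, REACTION = 1, RESERVOIR = 2, PLACEMENT = 3 };

struct RngSet {
  Stream st[4];

  void seed(uint64_t master) {
    for (int i = 0; i < 4; ++i) st[i].seed(master, static_cast<uint64_t>(i));
  }
  // raw (de)serialization: 4 streams x 4 x uint64 = 128 bytes
  void save(unsigned char *buf) const {
    for (int i = 0; i < 4; ++i)
      std::memcpy(buf + 32 * i, st[i].s, 32);
  }
  void load(const unsigned char *buf) {
    for (int i = 0; i < 4; ++i)
      std::memcpy(st[i].s, buf + 32 * i, 32);
  }
};

}  // namespace atrng

#endif
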