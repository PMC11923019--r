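#pragma once
#include <Rcpp.h>
#include <cmath>
#include <cstdint>

// Reduced two-dimensional Hodgkin-Huxley membrane model.
// Sodium activation is instantaneous (m = m_inf(V)) and inactivation is
// slaved to the gating variable as h = 0.8 - n.

struct HHParams {
  double gNa, gK, gL, VNa, VK, VL, c, Ib, K;
};

inline HHParams as_hh_params(const Rcpp::NumericVector& p) {
  HHParams q;
  q.gNa = p["gNa"]; q.gK = p["gK"]; q.gL = p["gL"];
  q.VNa = p["VNa"]; q.VK = p["VK"]; q.VL = p["VL"];
  q.c = p["c"]; q.Ib = p["Ib"]; q.K = p["K"];
  return q;
}

// Gating rates; removable singularities evaluated by their limits to avoid
// catastrophic cancellation near V = -40 and V = -55.
inline double rate_am(double V) {
  double d = V + 40.0;
  if (std::fabs(d) < 1e-7) return 1.0;
  return 0.1 * d / (1.0 - std::exp(-d / 10.0));
}
inline double rate_bm(double V) { return 4.0 * std::exp(-(V + 65.0) / 18.0); }
inline double rate_an(double V) {
  double d = V + 55.0;
  if (std::fabs(d) < 1e-7) return 0.1;
  return 0.01 * d / (1.0 - std::exp(-d / 10.0));
}
inline double rate_bn(double V) { return 0.125 * std::exp(-(V + 65.0) / 80.0); }
inline double hh_minf(double V) {
  double a = rate_am(V), b = rate_bm(V);
  return a / (a + b);
}

inline double hh_fV(double V, double n, const HHParams& p) {
  double m = hh_minf(V);
  return (p.Ib
          - p.gNa * m * m * m * (0.8 - n) * (V - p.VNa)
          - p.gK * n * n * n * n * (V - p.VK)
          - p.gL * (V - p.VL)) / p.c;
}
inline double hh_fn(double V, double n) {
  return rate_an(V) * (1.0 - n) - rate_bn(V) * n;
}

// Tabulated voltage-dependent factors (m_inf^3, a_n, b_n) with linear
// interpolation at 0.01 mV resolution: the SDE integrators evaluate the
// vector field hundreds of millions of times per ensemble and the gating
// exponentials dominate that cost. Interpolation error is O(1e-8), far
// below the SDE discretization error; queries outside the table fall back
// to the exact expressions.
struct RateTab {
  static constexpr double Vlo = -150.0, Vhi = 100.0, step = 0.01;
  int n;
  std::vector<double> m3, an, bn;
  RateTab() {
    n = (int)((Vhi - Vlo) / step) + 2;
    m3.resize(n); an.resize(n); bn.resize(n);
    for (int i = 0; i < n; ++i) {
      double V = Vlo + i * step;
      double m = rate_am(V) / (rate_am(V) + rate_bm(V));
      m3[i] = m * m * m;
      an[i] = rate_an(V);
      bn[i] = rate_bn(V);
    }
  }
};
inline const RateTab& ratetab() {
  static RateTab t;
  return t;
}

inline double hh_fV_fast(double V, double n, const HHParams& p) {
  const RateTab& T = ratetab();
  double m3;
  if (V >= RateTab::Vlo && V <= RateTab::Vhi) {
    double f = (V - RateTab::Vlo) / RateTab::step;
    int i = (int)f;
    double a = f - i;
    m3 = (1.0 - a) * T.m3[i] + a * T.m3[i + 1];
  } else {
    double m = hh_minf(V);
    m3 = m * m * m;
  }
  return (p.Ib
          - p.gNa * m3 * (0.8 - n) * (V - p.VNa)
          - p.gK * n * n * n * n * (V - p.VK)
          - p.gL * (V - p.VL)) / p.c;
}
inline double hh_fn_fast(double V, double n) {
  const RateTab& T = ratetab();
  if (V >= RateTab::Vlo && V <= RateTab::Vhi) {
    double f = (V - RateTab::Vlo) / RateTab::step;
    int i = (int)f;
    double a = f - i;
    double an = (1.0 - a) * T.an[i] + a * T.an[i + 1];
    double bn = (1.0 - a) * T.bn[i] + a * T.bn[i + 1];
    return an * (1.0 - n) - bn * n;
  }
  return hh_fn(V, n);
}

// Deterministic counter-based seed splitting plus a self-contained normal
// generator (xorshift64* + Box-Muller), so that realization i of an ensemble
// is reproducible bit-for-bit from (master_seed, i) on any platform.
inline std::uint64_t splitmix64(std::uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct NormalStream {
  std::uint64_t s;
  bool have_spare;
  double spare;
  NormalStream(std::uint64_t master, std::uint64_t stream)
      : have_spare(false), spare(0.0) {
    s = splitmix64(splitmix64(master) ^ splitmix64(stream + 0x51F15EEDULL));
    if (s == 0) s = 0x106689D45497FDB5ULL;
  }
  inline double u01() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    std::uint64_t r = s * 0x2545F4914F6CDD1DULL;
    // strictly inside (0,1) so log() below is safe
    return ((r >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double normal() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = u01(), u2 = u01();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(th);
    have_spare = true;
    return r * std::cos(th);
  }
};
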