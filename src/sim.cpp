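#include <Rcpp.h>
using namespace Rcpp;

// Fast local RNG: xorshift64* uniforms with Marsaglia-polar normals,
// (re)seeded from R's RNG stream at every exported entry point so that
// set.seed() in R still fully determines all output.
namespace {

struct FastRng {
  uint64_t s;
  double cached;
  bool has_cached;
  explicit FastRng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ULL),
                                    cached(0.0), has_cached(false) {}
  inline uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  inline double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  inline double norm() {
    if (has_cached) { has_cached = false; return cached; }
    double u, v, r2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(r2) / r2);
    cached = v * f; has_cached = true;
    return u * f;
  }
};

inline FastRng make_rng() {
  // two draws from R's stream -> 64-bit seed
  uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
  uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
  return FastRng((hi << 32) ^ lo);
}

// One LBA race between two accumulators sharing drift-rate SD s.
// Accumulator k draws start ~ U(0, A), rate ~ N(v_k, s); finishing time
// (b_k - start)/rate for positive rates. Trials where both sampled rates
// are non-positive are resampled (bounded retry), matching a task with a
// response deadline and no modelled non-responses.
inline double race2(FastRng &rng, double A1, double A2, double b1, double b2,
                    double v1, double v2, double s, int *winner) {
  for (int tries = 0; tries < 10000; ++tries) {
    double d1 = v1 + s * rng.norm();
    double d2 = v2 + s * rng.norm();
    if (d1 <= 0.0 && d2 <= 0.0) continue;
    double t1 = R_PosInf, t2 = R_PosInf;
    // a start point drawn above threshold means the accumulator is already
    // resolved: finishing time 0
    if (d1 > 0.0) { t1 = (b1 - A1 * rng.unif()) / d1; if (t1 < 0.0) t1 = 0.0; }
    if (d2 > 0.0) { t2 = (b2 - A2 * rng.unif()) / d2; if (t2 < 0.0) t2 = 0.0; }
    if (t1 <= t2) { *winner = 1; return t1; }
    *winner = 2; return t2;
  }
  stop("LBA race failed to terminate: both drift rates non-positive after 10000 resamples");
  return NA_REAL; // not reached
}

// A processing channel for one stimulus dimension: target accumulator
// (drift v, threshold bT) races the contrast accumulator (drift 1-v,
// threshold bC). winner: 1 = target resolution, 2 = contrast resolution.
inline double channel(FastRng &rng, double v, double A, double bT, double bC,
                      double s, int *winner) {
  return race2(rng, A, A, bT, bC, v, 1.0 - v, s, winner);
}

} // namespace

// n independent two-accumulator races with arbitrary drifts/thresholds.
// [[Rcpp::export]]
List cpp_race(int n, double A1, double A2, double b1, double b2,
              double v1, double v2, double s) {
  RNGScope scope;
  FastRng rng = make_rng();
  NumericVector t(n);
  IntegerVector w(n);
  for (int i = 0; i < n; ++i) {
    int wi;
    t[i] = race2(rng, A1, A2, b1, b2, v1, v2, s, &wi);
    w[i] = wi;
  }
  return List::create(_["time"] = t, _["winner"] = w);
}

// Simulate n decision trials from one architecture for a single stimulus.
//
// arch: 1 serial self-terminating (order: lips first with prob px)
//       2 parallel self-terminating
//       3 single-channel race (coactive or free-drift; drift v_single)
//       4 serial/parallel mixture (serial with prob p_serial; the parallel
//         component uses vx_par/vy_par and start range A_par)
//
// Returns decision times (without non-decision time) and responses
// (1 = target, 0 = contrast).
// [[Rcpp::export]]
List cpp_sim_arch(int arch, int n, double vx, double vy,
                  double A, double bT, double bC, double s,
                  double px, double p_serial,
                  double vx_par, double vy_par, double A_par,
                  double v_single) {
  RNGScope scope;
  FastRng rng = make_rng();
  NumericVector dt(n);
  IntegerVector resp(n);
  for (int i = 0; i < n; ++i) {
    int a = arch;
    double cvx = vx, cvy = vy, cA = A;
    if (arch == 4) {
      if (rng.unif() < p_serial) {
        a = 1;
      } else {
        a = 2; cvx = vx_par; cvy = vy_par; cA = A_par;
      }
    }
    if (a == 1) {
      bool lips_first = rng.unif() < px;
      double v1 = lips_first ? cvx : cvy;
      double v2 = lips_first ? cvy : cvx;
      int w1; double t1 = channel(rng, v1, cA, bT, bC, s, &w1);
      if (w1 == 2) { resp[i] = 0; dt[i] = t1; continue; }
      int w2; double t2 = channel(rng, v2, cA, bT, bC, s, &w2);
      resp[i] = (w2 == 1) ? 1 : 0;
      dt[i] = t1 + t2;
    } else if (a == 2) {
      int wx, wy;
      double tx = channel(rng, cvx, cA, bT, bC, s, &wx);
      double ty = channel(rng, cvy, cA, bT, bC, s, &wy);
      if (wx == 1 && wy == 1) { resp[i] = 1; dt[i] = tx > ty ? tx : ty; }
      else if (wx == 2 && wy == 2) { resp[i] = 0; dt[i] = tx < ty ? tx : ty; }
      else if (wx == 2) { resp[i] = 0; dt[i] = tx; }
      else { resp[i] = 0; dt[i] = ty; }
    } else if (a == 3) {
      int w; double t = channel(rng, v_single, cA, bT, bC, s, &w);
      resp[i] = (w == 1) ? 1 : 0;
      dt[i] = t;
    } else {
      stop("unknown architecture code");
    }
  }
  return List::create(_["dt"] = dt, _["resp"] = resp);
}

// Binned Gaussian kernel density estimate of `sims`, evaluated at `eval`.
// Linear binning onto a 512-point grid spanning the simulant range plus
// 4 bandwidths, kernel truncated at 4 bandwidths, linear interpolation at
// the evaluation points; points outside the grid get density 0.
// [[Rcpp::export]]
NumericVector cpp_kde_dens(NumericVector sims, NumericVector eval, double bw) {
  const int G = 512;
  int n = sims.size();
  if (n < 2 || bw <= 0.0) return NumericVector(eval.size(), 0.0);
  double lo = min(sims) - 4.0 * bw, hi = max(sims) + 4.0 * bw;
  double dx = (hi - lo) / (G - 1);
  std::vector<double> cnt(G, 0.0);
  for (int i = 0; i < n; ++i) {
    double pos = (sims[i] - lo) / dx;
    int j = (int)pos;
    if (j < 0) j = 0;
    if (j >= G - 1) j = G - 2;
    double w = pos - j;
    cnt[j] += 1.0 - w;
    cnt[j + 1] += w;
  }
  int taps = (int)(4.0 * bw / dx) + 1;
  std::vector<double> kern(taps + 1);
  double norm = 1.0 / (bw * M_SQRT2 * sqrt(M_PI));
  for (int k = 0; k <= taps; ++k) {
    double u = k * dx / bw;
    kern[k] = norm * exp(-0.5 * u * u);
  }
  std::vector<double> dens(G, 0.0);
  for (int g = 0; g < G; ++g) {
    if (cnt[g] == 0.0) continue;
    double c = cnt[g];
    dens[g] += c * kern[0];
    for (int k = 1; k <= taps; ++k) {
      if (g - k >= 0) dens[g - k] += c * kern[k];
      if (g + k < G) dens[g + k] += c * kern[k];
    }
  }
  for (int g = 0; g < G; ++g) dens[g] /= n;
  int m = eval.size();
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    double pos = (eval[i] - lo) / dx;
    if (pos < 0.0 || pos > G - 1) { out[i] = 0.0; continue; }
    int j = (int)pos;
    if (j >= G - 1) { out[i] = dens[G - 1]; continue; }
    double w = pos - j;
    out[i] = (1.0 - w) * dens[j] + w * dens[j + 1];
  }
  return out;
}
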