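#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Reaction-channel layout shared by all model variants:
//   0 gene activation   (D += 1, or G_off -> G_on)
//   1 gene deactivation (D -= 1, or G_on -> G_off)
//   2 transcription     (R += 1)
//   3 mRNA decay        (R -= 1)
//   4 translation       (P += 1)
//   5 protein decay     (P -= 1)
//
// Parameter vector layout (see R/rates.R params_vector, keep in sync):
//   0 k_G, 1 gamma_G, 2 k_R, 3 gamma_R, 4 k_P, 5 gamma_P,
//   6 eta_G, 7 eta_R, 8 eta_P, 9 hill_H, 10 hill_half_max, 11 allele_bound
//
// Variant codes: 0 linear, 1 gene-copy-bounded, 2 Hill.

// Counter-based per-trajectory RNG: a xoshiro256+ stream whose state is
// filled by splitmix64 from (master seed, stream index).  Every
// trajectory owns an independent, reproducible stream, so ensembles are
// deterministic under the master seed and safe to resume or parallelize.
struct XoRng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  XoRng(uint64_t seed, uint64_t stream) {
    uint64_t x = seed * 0x9E3779B97F4A7C15ULL + stream * 0xD1B54A32D192ED03ULL;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1): never 0, so -log() is finite
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

static inline void channel_rates(const int variant, const double *p,
                                 const double stim,
                                 const double D, const double R,
                                 const double P, double *a) {
  const double kG = p[0] + p[6];
  const double kR = p[2] + p[7];
  const double kP = p[4] + p[8];
  switch (variant) {
  case 0: // linear: unbounded activated-DNA deviation
    a[0] = kG * stim;
    a[1] = p[1] * D;
    a[2] = kR * D;
    break;
  case 1: { // bounded: D is G_on, G_off = allele_bound - G_on
    const double Goff = p[11] - D;
    a[0] = kG * stim * Goff;
    a[1] = p[1] * D;
    a[2] = kR * D;
    break;
  }
  default: { // Hill: transcription driven directly by the stimulus
    double drive = 0.0;
    if (stim > 0.0) {
      const double sh = std::pow(stim, p[9]);
      drive = sh / (sh + std::pow(p[10], p[9]));
    }
    a[0] = 0.0;
    a[1] = 0.0;
    a[2] = kR * drive;
    break;
  }
  }
  a[3] = p[3] * R;
  a[4] = kP * R;
  a[5] = p[5] * P;
}

// Exact Poisson sampler on the trajectory's own RNG stream: product
// inversion for small means, Hormann's PTRS transformed rejection for
// lambda >= 10.  Both are exact (no normal approximation).
static double rpois_x(XoRng &rng, const double lam) {
  if (lam <= 0.0) return 0.0;
  if (lam < 10.0) {
    const double L = std::exp(-lam);
    double prod = rng.unif(), k = 0.0;
    while (prod > L) { prod *= rng.unif(); k += 1.0; }
    return k;
  }
  const double b = 0.931 + 2.53 * std::sqrt(lam);
  const double a = -0.059 + 0.02483 * b;
  const double inv_alpha = 1.1239 + 1.1328 / (b - 3.4);
  const double vr = 0.9277 - 3.6224 / (b - 2.0);
  for (;;) {
    const double U = rng.unif() - 0.5;
    const double V = rng.unif();
    const double us = 0.5 - std::fabs(U);
    const double k = std::floor((2.0 * a / us + b) * U + lam + 0.43);
    if (us >= 0.07 && V <= vr) return k;
    if (k < 0.0 || (us < 0.013 && V > us)) continue;
    if (std::log(V * inv_alpha / (a / (us * us) + b)) <=
        k * std::log(lam) - lam - std::lgamma(k + 1.0)) return k;
  }
}

// Exact binomial sampler: BINV inversion when n*min(p,q) < 10, else
// Hormann's BTRS transformed rejection (squeeze step, then the exact
// log-density ratio via lgamma).
static double rbinom_x(XoRng &rng, const double n, const double p) {
  if (n <= 0.0 || p <= 0.0) return 0.0;
  if (p >= 1.0) return n;
  const bool flip = p > 0.5;
  const double q = flip ? 1.0 - p : p; // q = min(p, 1 - p) <= 0.5
  double k = 0.0;
  if (n * q < 10.0) {
    const double s = q / (1.0 - q);
    double f = std::exp(n * std::log1p(-q));
    double u = rng.unif();
    while (u > f && k < n) {
      u -= f;
      k += 1.0;
      f *= s * (n - k + 1.0) / k;
      if (f <= 0.0) break; // underflow guard, tail mass < 2^-53
    }
  } else {
    const double sd = std::sqrt(n * q * (1.0 - q));
    const double b = 1.15 + 2.53 * sd;
    const double a = -0.0873 + 0.0248 * b + 0.01 * q;
    const double c = n * q + 0.5;
    const double vr = 0.92 - 4.2 / b;
    const double alpha = (2.83 + 5.1 / b) * sd;
    const double lr = std::log(q / (1.0 - q));
    const double m = std::floor((n + 1.0) * q);
    for (;;) {
      const double U = rng.unif() - 0.5;
      const double V = rng.unif();
      const double us = 0.5 - std::fabs(U);
      k = std::floor((2.0 * a / us + b) * U + c);
      if (us >= 0.07 && V <= vr) break;
      if (k < 0.0 || k > n) continue;
      if (std::log(V * alpha / (a / (us * us) + b)) <=
          std::lgamma(m + 1.0) + std::lgamma(n - m + 1.0) -
          std::lgamma(k + 1.0) - std::lgamma(n - k + 1.0) +
          (k - m) * lr) break;
    }
  }
  return flip ? n - k : k;
}

static inline void apply_event(const int ch, double &D, double &R, double &P) {
  switch (ch) {
  case 0: D += 1; break;
  case 1: D -= 1; break;
  case 2: R += 1; break;
  case 3: R -= 1; break;
  case 4: P += 1; break;
  case 5: P -= 1; break;
  }
}

// Simulate one trajectory, writing last-value-interpolated states into
// row `row` of the (possibly NULL) output matrices.  The stimulus is
// piecewise constant (basal outside [onset, onset + duration),
// amplitude inside); the exponential waiting-time clock restarts at the
// discontinuities, which is exact for a memoryless process.
static void run_one(const int variant, const double *p,
                    const double onset, const double duration,
                    const double amplitude, const double basal,
                    const double *grid, const int G,
                    const int *init, XoRng &rng,
                    double *rowD, double *rowR, double *rowP,
                    const int row, const int nrow) {
  double D = init[0], R = init[1], P = init[2];
  const double horizon = grid[G - 1];
  const double t_on = onset, t_off = onset + duration;
  double t = grid[0];
  int g = 0;
  double a[6];
  while (t < horizon) {
    const double stim = (t >= t_on && t < t_off) ? amplitude : basal;
    double t_break = horizon;
    if (t < t_on) t_break = t_on; else if (t < t_off) t_break = t_off;

    channel_rates(variant, p, stim, D, R, P, a);
    double a0 = 0.0;
    for (int i = 0; i < 6; ++i) a0 += a[i];

    double t_next;
    int ch = -1;
    if (a0 <= 0.0) {
      t_next = t_break;
    } else {
      const double dt = -std::log(rng.unif()) / a0;
      if (t + dt >= t_break) {
        t_next = t_break;
      } else {
        t_next = t + dt;
        double u = rng.unif() * a0;
        for (ch = 0; ch < 5; ++ch) {
          u -= a[ch];
          if (u <= 0.0) break;
        }
      }
    }
    while (g < G && grid[g] < t_next) {
      if (rowD) rowD[row + (R_xlen_t)g * nrow] = D;
      if (rowR) rowR[row + (R_xlen_t)g * nrow] = R;
      rowP[row + (R_xlen_t)g * nrow] = P;
      ++g;
    }
    if (ch >= 0) apply_event(ch, D, R, P);
    t = t_next;
  }
  while (g < G) {
    if (rowD) rowD[row + (R_xlen_t)g * nrow] = D;
    if (rowR) rowR[row + (R_xlen_t)g * nrow] = R;
    rowP[row + (R_xlen_t)g * nrow] = P;
    ++g;
  }
}

// Exact conditional variant of run_one: D and R evolve by event-driven
// SSA, while the protein count is advanced from grid point to grid
// point by its exact conditional law given the mRNA path.  Protein
// never feeds back into the other channels, so conditional on R(t)
// (piecewise constant) the protein is an immigration-death process:
// over one grid interval, survivors of the previous count are
// Binomial(P, exp(-gamma_P * dt)) and the surviving influx is Poisson
// with intensity k_P * integral R(s) exp(-gamma_P (t_grid - s)) ds,
// accumulated in closed form over the R-constant segments.  The joint
// law of (D, R, P) at the grid times is identical to full SSA; only
// unobserved between-grid protein fluctuations are not realized.
static void run_one_cond(const int variant, const double *p,
                         const double onset, const double duration,
                         const double amplitude, const double basal,
                         const double *grid, const int G,
                         const int *init, XoRng &rng,
                         double *rowD, double *rowR, double *rowP,
                         const int row, const int nrow) {
  double D = init[0], R = init[1], P = init[2];
  const double gP = p[5];
  const double kPtot = p[4] + p[8];
  const double t_on = onset, t_off = onset + duration;
  double t = grid[0];
  double a[6];
  if (rowD) rowD[row] = D;
  if (rowR) rowR[row] = R;
  rowP[row] = P;
  for (int g = 1; g < G; ++g) {
    const double gnext = grid[g];
    double lam = 0.0;
    while (t < gnext) {
      const double stim = (t >= t_on && t < t_off) ? amplitude : basal;
      double t_break = gnext;
      if (t < t_on) { if (t_on < t_break) t_break = t_on; }
      else if (t < t_off) { if (t_off < t_break) t_break = t_off; }

      channel_rates(variant, p, stim, D, R, P, a);
      const double a0 = a[0] + a[1] + a[2] + a[3];

      double t_next;
      int ch = -1;
      if (a0 <= 0.0) {
        t_next = t_break;
      } else {
        const double dt = -std::log(rng.unif()) / a0;
        if (t + dt >= t_break) {
          t_next = t_break;
        } else {
          t_next = t + dt;
          double u = rng.unif() * a0;
          for (ch = 0; ch < 3; ++ch) {
            u -= a[ch];
            if (u <= 0.0) break;
          }
        }
      }
      if (R > 0.0 && kPtot > 0.0) {
        if (gP > 0.0)
          lam += kPtot * R / gP *
            (std::exp(-gP * (gnext - t_next)) -
             std::exp(-gP * (gnext - t)));
        else
          lam += kPtot * R * (t_next - t);
      }
      if (ch >= 0) apply_event(ch, D, R, P);
      t = t_next;
    }
    const double surv =
      (gP > 0.0) ? std::exp(-gP * (gnext - grid[g - 1])) : 1.0;
    P = rbinom_x(rng, P, surv) + rpois_x(rng, lam);
    if (rowD) rowD[row + (R_xlen_t)g * nrow] = D;
    if (rowR) rowR[row + (R_xlen_t)g * nrow] = R;
    rowP[row + (R_xlen_t)g * nrow] = P;
  }
}

// [[Rcpp::export]]
List ssa_ensemble_cpp(const int variant, const NumericVector params,
                      const double onset, const double duration,
                      const double amplitude, const double basal,
                      const NumericVector grid, const IntegerVector init,
                      const int n, const double seed,
                      const bool keep_D, const bool keep_R,
                      const bool conditional) {
  const int G = grid.size();
  NumericMatrix P(n, G);
  NumericMatrix D = keep_D ? NumericMatrix(n, G) : NumericMatrix(0, 0);
  NumericMatrix R = keep_R ? NumericMatrix(n, G) : NumericMatrix(0, 0);
  for (int i = 0; i < n; ++i) {
    XoRng rng((uint64_t)seed, (uint64_t)(i + 1));
    if (conditional)
      run_one_cond(variant, REAL(params), onset, duration, amplitude,
                   basal, REAL(grid), G, INTEGER(init), rng,
                   keep_D ? REAL(D) : nullptr,
                   keep_R ? REAL(R) : nullptr, REAL(P), i, n);
    else
      run_one(variant, REAL(params), onset, duration, amplitude, basal,
              REAL(grid), G, INTEGER(init), rng,
              keep_D ? REAL(D) : nullptr, keep_R ? REAL(R) : nullptr,
              REAL(P), i, n);
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  List out = List::create(_["P"] = P);
  if (keep_D) out["D"] = D;
  if (keep_R) out["R"] = R;
  return out;
}

// [[Rcpp::export]]
NumericMatrix ssa_grid_cpp(const int variant, const NumericVector params,
                           const double onset, const double duration,
                           const double amplitude, const double basal,
                           const NumericVector grid,
                           const IntegerVector init, const double seed,
                           const double stream) {
  const int G = grid.size();
  NumericMatrix out(1, 3 * G); // D, R, P blocks
  XoRng rng((uint64_t)seed, (uint64_t)stream);
  NumericMatrix res(G, 3);
  // reuse run_one with column-major single-row layout
  std::vector<double> Dv(G), Rv(G), Pv(G);
  run_one(variant, REAL(params), onset, duration, amplitude, basal,
          REAL(grid), G, INTEGER(init), rng,
          Dv.data(), Rv.data(), Pv.data(), 0, 1);
  for (int g = 0; g < G; ++g) {
    res(g, 0) = Dv[g]; res(g, 1) = Rv[g]; res(g, 2) = Pv[g];
  }
  return res;
}

// Draws from the internal exact samplers, for distributional validation
// against the reference implementations in R.
// [[Rcpp::export]]
NumericVector rpois_stream_cpp(const int n, const double lam,
                               const double seed) {
  NumericVector out(n);
  XoRng rng((uint64_t)seed, 1u);
  for (int i = 0; i < n; ++i) out[i] = rpois_x(rng, lam);
  return out;
}

// [[Rcpp::export]]
NumericVector rbinom_stream_cpp(const int n, const double size,
                                const double p, const double seed) {
  NumericVector out(n);
  XoRng rng((uint64_t)seed, 1u);
  for (int i = 0; i < n; ++i) out[i] = rbinom_x(rng, size, p);
  return out;
}

// Full event record of a single trajectory (times and post-event states).
// [[Rcpp::export]]
List ssa_events_cpp(const int variant, const NumericVector params,
                    const double onset, const double duration,
                    const double amplitude, const double basal,
                    const double t0, const double horizon,
                    const IntegerVector init, const int max_events,
                    const double seed, const double stream) {
  const double *p = REAL(params);
  std::vector<double> times, Ds, Rs, Ps;
  double D = init[0], R = init[1], P = init[2];
  const double t_on = onset, t_off = onset + duration;
  double t = t0;
  double a[6];
  XoRng rng((uint64_t)seed, (uint64_t)stream);
  times.push_back(t); Ds.push_back(D); Rs.push_back(R); Ps.push_back(P);

  while (t < horizon) {
    const double stim = (t >= t_on && t < t_off) ? amplitude : basal;
    double t_break = horizon;
    if (t < t_on) t_break = t_on; else if (t < t_off) t_break = t_off;

    channel_rates(variant, p, stim, D, R, P, a);
    double a0 = 0.0;
    for (int i = 0; i < 6; ++i) a0 += a[i];

    if (a0 <= 0.0) { t = t_break; continue; }
    const double dt = -std::log(rng.unif()) / a0;
    if (t + dt >= t_break) { t = t_break; continue; }
    t += dt;
    double u = rng.unif() * a0;
    int ch;
    for (ch = 0; ch < 5; ++ch) {
      u -= a[ch];
      if (u <= 0.0) break;
    }
    apply_event(ch, D, R, P);
    times.push_back(t); Ds.push_back(D); Rs.push_back(R); Ps.push_back(P);
    if ((int)times.size() >= max_events)
      stop("event budget exceeded (%d events before t = %g)", max_events, t);
  }
  return List::create(_["time"] = times, _["D"] = Ds, _["R"] = Rs,
                      _["P"] = Ps);
}
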