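#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Chambers-Mallows-Stuck transform, symmetric (beta = 0) case.
//
// For U ~ Uniform(-pi/2, pi/2), E ~ Exp(1):
//   X = sin(alpha U) cos(U)^{-1/alpha} cos((1-alpha)U)^{(1-alpha)/alpha}
//       * E^{(alpha-1)/alpha}
// reduces to tan(U) at alpha = 1 and to 2 sin(U) sqrt(E) (i.e. N(0, 2)) at
// alpha = 2, so the whole range [1, 2] goes through one formula and the
// alpha -> 2 limit is continuous.
// ---------------------------------------------------------------------------

static const double COS_GUARD = 1e-300; // keep cos factor away from 0

static inline double cms_symmetric(double u, double e, double alpha) {
  if (alpha == 1.0) return std::tan(u);
  double cu = std::cos(u);
  if (cu < COS_GUARD) cu = COS_GUARD;
  double f = std::sin(alpha * u) * std::pow(cu, -1.0 / alpha) *
             std::pow(std::cos((1.0 - alpha) * u), (1.0 - alpha) / alpha);
  return f * std::pow(e, (alpha - 1.0) / alpha);
}

// [[Rcpp::export]]
NumericVector cpp_rstable(int n, double alpha, double gamma, double delta) {
  NumericVector out(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double u = (unif_rand() - 0.5) * M_PI;
    double e = exp_rand();
    out[i] = gamma * cms_symmetric(u, e, alpha) + delta;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Forward simulation of the Levy-flight accumulator (R RNG; user-facing).
// One Euler step: x <- x + v*dt + e * dt^{1/alpha}, e ~ Stable(alpha,0,1,0).
// Returns matrix columns: decision_time, boundary (1 upper / 0 lower),
// censored flag, rt (decision time + uniform non-decision time).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_simulate_trials(NumericVector v, double a, double zr,
                                  double ndt, double sndt, double alpha,
                                  double dt, double max_time) {
  int n = v.size();
  NumericMatrix out(n, 4);
  double dtp = std::pow(dt, 1.0 / alpha);
  double x0 = zr * a;
  int max_steps = (int)std::ceil(max_time / dt);
  // At the Gaussian limit the within-step path is a Brownian bridge
  // (variance 2 per unit time for gamma = 1), so missed within-step
  // boundary crossings can be detected exactly; no closed-form bridge
  // exists for alpha < 2, where first passage is jump-dominated and the
  // discretization bias is inherently small.
  bool gauss_bridge = (alpha == 2.0);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double x = x0;
    int step = 0;
    int boundary = -1;
    while (step < max_steps) {
      double u = (unif_rand() - 0.5) * M_PI;
      double e = exp_rand();
      double x_prev = x;
      x += v[i] * dt + cms_symmetric(u, e, alpha) * dtp;
      ++step;
      if (x >= a) { boundary = 1; break; }
      if (x <= 0.0) { boundary = 0; break; }
      if (gauss_bridge) {
        double p_up = std::exp(-(a - x_prev) * (a - x) / dt);
        double p_lo = std::exp(-x_prev * x / dt);
        double uu = unif_rand();
        if (uu < p_up) { boundary = 1; break; }
        if (uu < p_up + p_lo) { boundary = 0; break; }
      }
    }
    double t = step * dt;
    bool censored = (boundary < 0);
    double nd = ndt - sndt / 2.0 + sndt * unif_rand();
    out(i, 0) = t;
    out(i, 1) = censored ? NA_REAL : (double)boundary;
    out(i, 2) = censored ? 1.0 : 0.0;
    out(i, 3) = censored ? NA_REAL : t + nd;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Deterministic counter-based RNG (splitmix64 -> xoshiro256+) used only for
// the common-random-number pool of the fitting objective, so that the
// objective is a deterministic function of (theta, seed) independent of R's
// RNG state.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t sm = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(sm);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double runif() { // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

// Pool of (u, log E) inputs shared across candidate parameter vectors: the
// same noise stream is re-scaled per alpha through the CMS transform, giving
// a common-random-numbers objective.
// [[Rcpp::export]]
NumericMatrix cpp_crn_pool(double seed, int m) {
  Xoshiro rng((uint64_t)seed + 0x9E3779B9ULL);
  NumericMatrix pool(m, 2);
  for (int i = 0; i < m; ++i) {
    pool(i, 0) = (rng.runif() - 0.5) * M_PI;          // u
    pool(i, 1) = std::log(-std::log(rng.runif()));     // log E, E ~ Exp(1)
  }
  return pool;
}

// Tabulated CMS angular factor f1(u) for one alpha; exact evaluation near the
// endpoints where f1 diverges and linear interpolation would bias the tails.
struct F1Table {
  std::vector<double> tab;
  double alpha, lo, hi, inv_step, edge;
  int n;
  F1Table(double alpha_, int n_ = 2048) : alpha(alpha_), n(n_) {
    edge = M_PI / 2.0 - 0.08;
    lo = -edge; hi = edge;
    inv_step = (n - 1) / (hi - lo);
    tab.resize(n);
    for (int i = 0; i < n; ++i) {
      double u = lo + i / inv_step;
      tab[i] = f1_exact(u);
    }
  }
  inline double f1_exact(double u) const {
    if (alpha == 1.0) return std::tan(u);
    double cu = std::cos(u);
    if (cu < COS_GUARD) cu = COS_GUARD;
    return std::sin(alpha * u) * std::pow(cu, -1.0 / alpha) *
           std::pow(std::cos((1.0 - alpha) * u), (1.0 - alpha) / alpha);
  }
  inline double operator()(double u) const {
    if (u < lo || u > hi) return f1_exact(u);
    double p = (u - lo) * inv_step;
    int i = (int)p;
    if (i >= n - 1) return tab[n - 1];
    double w = p - i;
    return tab[i] * (1.0 - w) + tab[i + 1] * w;
  }
};

// ---------------------------------------------------------------------------
// Quantile-probability composite log-likelihood for one candidate parameter
// vector.
//
// Bins are fixed by the OBSERVED data: per condition and response option,
// edges at the observed RT quantiles `probs`. For a candidate theta, n_sim
// trials per condition are simulated with the CRN pool; the simulated
// proportion landing in each (response, bin) category -- censored paths form
// their own implicit category -- is the predicted probability, and the
// observed counts are scored by the multinomial log-likelihood. This is the
// quantile-probability form whose maximizer is consistent (predicted
// probabilities move, bin counts stay fixed).
//
// obs_edges: concatenated bin edges, nq per condition x response block
//   (lower response block then upper, per condition); NaN-filled where a
//   response option has no observed trials.
// obs_counts: concatenated observed counts, nq+1 per block.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_qmle_loglik(NumericVector v, NumericVector ndt_c, double a,
                       double zr, double sndt, double alpha, double dt,
                       double max_time, int n_sim, NumericMatrix pool,
                       NumericVector obs_edges, NumericVector obs_counts,
                       int nq) {
  int C = v.size();
  int m = pool.nrow();
  double dtp = std::pow(dt, 1.0 / alpha);
  double eaexp = (alpha - 1.0) / alpha;
  int max_steps = (int)std::ceil(max_time / dt);
  double x0 = zr * a;
  F1Table f1(alpha);
  const double *pu = &pool(0, 0);
  const double *ple = &pool(0, 1);

  int nbin = nq + 1;
  std::vector<double> sim_lo, sim_up;
  sim_lo.reserve(n_sim); sim_up.reserve(n_sim);
  double loglik = 0.0;

  for (int c = 0; c < C; ++c) {
    sim_lo.clear(); sim_up.clear();
    double vc = v[c], nd = ndt_c[c];
    for (int i = 0; i < n_sim; ++i) {
      // per-trial offset into the shared pool (odd multiplier: bijection)
      uint32_t idx = (uint32_t)(((uint64_t)(c * n_sim + i) * 2654435761ULL));
      idx %= (uint32_t)m;
      double x = x0;
      int boundary = -1;
      int step = 0;
      while (step < max_steps) {
        double u = pu[idx];
        double e = f1(u) * std::exp(eaexp * ple[idx]);
        if (++idx >= (uint32_t)m) idx = 0;
        x += vc * dt + e * dtp;
        ++step;
        if (x >= a) { boundary = 1; break; }
        if (x <= 0.0) { boundary = 0; break; }
      }
      if (boundary < 0) continue; // censored: mass missing from all bins
      double u01 = pu[idx] / M_PI + 0.5;
      if (++idx >= (uint32_t)m) idx = 0;
      double rt = step * dt + nd - sndt / 2.0 + sndt * u01;
      if (boundary == 1) sim_up.push_back(rt); else sim_lo.push_back(rt);
    }
    std::sort(sim_lo.begin(), sim_lo.end());
    std::sort(sim_up.begin(), sim_up.end());

    // smoothed multinomial over 2 * (nq + 1) categories (+ censored slack)
    double denom = (double)n_sim + 0.5 * (2 * nbin + 1);
    for (int r = 0; r < 2; ++r) {
      std::vector<double> &sim = (r == 0) ? sim_lo : sim_up;
      int ns = (int)sim.size();
      int base = (2 * c + r);
      const double *edges = &obs_edges[base * nq];
      const double *counts = &obs_counts[base * nbin];
      if (ISNAN(edges[0])) continue; // no observed trials of this response
      size_t pos = 0;
      for (int j = 0; j < nbin; ++j) {
        size_t hi = (j < nq)
          ? (std::upper_bound(sim.begin(), sim.end(), edges[j]) -
             sim.begin())
          : (size_t)ns;
        double p = ((double)(hi - pos) + 0.5) / denom;
        pos = hi;
        if (counts[j] > 0) loglik += counts[j] * std::log(p);
      }
    }
  }
  return loglik;
}

// ---------------------------------------------------------------------------
// Kraskov-Stoegbauer-Grassberger (variant 1) mutual information, max-norm.
// I(X;Y) = psi(k) + psi(N) - < psi(nx + 1) + psi(ny + 1) >
// O(n^2); n of a few thousand is the intended scale.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double cpp_ksg_mi(NumericVector x, NumericVector y, int k) {
  int n = x.size();
  std::vector<double> dxy(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    // distance to k-th nearest neighbour in joint (max-norm)
    for (int j = 0; j < n; ++j) {
      double d = std::max(std::fabs(x[i] - x[j]), std::fabs(y[i] - y[j]));
      dxy[j] = d;
    }
    dxy[i] = R_PosInf;
    std::nth_element(dxy.begin(), dxy.begin() + (k - 1), dxy.end());
    double eps = dxy[k - 1];
    int nx = 0, ny = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (std::fabs(x[i] - x[j]) < eps) ++nx;
      if (std::fabs(y[i] - y[j]) < eps) ++ny;
    }
    acc += R::digamma(nx + 1.0) + R::digamma(ny + 1.0);
  }
  return R::digamma((double)k) + R::digamma((double)n) - acc / n;
}

// Frenzel-Pompe conditional MI (KSG-based), max-norm:
// I(X;Y|Z) = psi(k) - < psi(n_xz + 1) + psi(n_yz + 1) - psi(n_z + 1) >
// [[Rcpp::export]]
double cpp_ksg_cmi(NumericVector x, NumericVector y, NumericMatrix z, int k) {
  int n = x.size();
  int dz = z.ncol();
  std::vector<double> dall(n);
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double d = std::max(std::fabs(x[i] - x[j]), std::fabs(y[i] - y[j]));
      for (int l = 0; l < dz; ++l)
        d = std::max(d, std::fabs(z(i, l) - z(j, l)));
      dall[j] = d;
    }
    dall[i] = R_PosInf;
    std::nth_element(dall.begin(), dall.begin() + (k - 1), dall.end());
    double eps = dall[k - 1];
    int nxz = 0, nyz = 0, nz = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dzj = 0.0;
      for (int l = 0; l < dz; ++l)
        dzj = std::max(dzj, std::fabs(z(i, l) - z(j, l)));
      if (dzj < eps) {
        ++nz;
        if (std::fabs(x[i] - x[j]) < eps) ++nxz;
        if (std::fabs(y[i] - y[j]) < eps) ++nyz;
      }
    }
    acc += R::digamma(nxz + 1.0) + R::digamma(nyz + 1.0) -
           R::digamma(nz + 1.0);
  }
  return R::digamma((double)k) - acc / n;
}
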