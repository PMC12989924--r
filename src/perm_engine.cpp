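// Batch evaluation of the two-sample CGE permutation statistic.
//
// The test statistic is the time-normalised integrated absolute difference of
// the two groups' copula-graphic estimators (Clayton generator; theta == 0 is
// read as the independence generator, i.e. Kaplan-Meier),
//
//   L1 = (1 / t*) * \int_0^{t*} | S1(t) - S2(t) | dt,
//   t* = min(max x in group 1, max x in group 2),
//
// and the Monte-Carlo permutation distribution re-randomises the group labels
// of the (time, status) pairs with group sizes fixed. All rows are passed
// sorted by ascending time with events before censorings at ties; the CGE of
// a group then updates at its event rows via the telescoped generator jump
//   A += ((Y-1)/n_g)^{-theta} - (Y/n_g)^{-theta},  S = A^{-1/theta}
// (product form for independence), where Y is the group's current risk count.
// Powers of k/n_g are precomputed per theta, so one permutation costs one
// std::pow per event row and theta.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
using namespace Rcpp;

namespace {

// splitmix64: tiny, fast, platform-independent generator for permutations.
struct Rng {
  uint64_t state;
  explicit Rng(uint64_t seed) : state(seed) {}
  uint64_t next() {
    state += 0x9E3779B97F4A7C15ULL;
    uint64_t z = state;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform on {0, ..., m-1} by rejection (no modulo bias)
  uint64_t below(uint64_t m) {
    uint64_t lim = UINT64_MAX - UINT64_MAX % m;
    uint64_t v;
    do { v = next(); } while (v >= lim);
    return v % m;
  }
};

struct Engine {
  int n, n1, n2, nth;
  std::vector<double> x;
  std::vector<int> ev;              // status per sorted row
  std::vector<double> th;           // thetas, 0 => independence
  std::vector<std::vector<double>> pow1, pow2; // (k/n_g)^{-theta}, k = 0..n_g
  // workspace
  std::vector<double> A1, A2, S1, S2, l1, lsgn;

  Engine(NumericVector x_, IntegerVector ev_, int n1_, NumericVector th_)
      : n(x_.size()), n1(n1_), n2(n - n1_) {
    x.assign(x_.begin(), x_.end());
    ev.assign(ev_.begin(), ev_.end());
    th.assign(th_.begin(), th_.end());
    nth = th.size();
    pow1.resize(nth); pow2.resize(nth);
    for (int t = 0; t < nth; ++t) {
      pow1[t].resize(n1 + 1); pow2[t].resize(n2 + 1);
      if (th[t] > 0.0) {
        for (int k = 0; k <= n1; ++k)
          pow1[t][k] = std::pow((double)k / n1, -th[t]);
        for (int k = 0; k <= n2; ++k)
          pow2[t][k] = std::pow((double)k / n2, -th[t]);
      }
    }
    A1.resize(nth); A2.resize(nth); S1.resize(nth); S2.resize(nth);
    l1.resize(nth); lsgn.resize(nth);
  }

  // g: membership per sorted row (1 = group 1). Fills l1 / lsgn per theta.
  void stat(const std::vector<int>& g) {
    // t* = time of the earlier of the two groups' last rows
    int last1 = -1, last2 = -1;
    for (int i = n - 1; i >= 0; --i) {
      if (g[i]) { if (last1 < 0) last1 = i; }
      else      { if (last2 < 0) last2 = i; }
      if (last1 >= 0 && last2 >= 0) break;
    }
    double tstar = x[last1 < last2 ? last1 : last2];
    int Y1 = n1, Y2 = n2;
    for (int t = 0; t < nth; ++t) {
      A1[t] = 1.0; A2[t] = 1.0; S1[t] = 1.0; S2[t] = 1.0;
      l1[t] = 0.0; lsgn[t] = 0.0;
    }
    double prev = 0.0;
    for (int i = 0; i < n; ++i) {
      double ti = x[i];
      if (ti > prev) {
        double hi = ti < tstar ? ti : tstar;
        if (hi > prev) {
          double w = hi - prev;
          for (int t = 0; t < nth; ++t) {
            double d = S1[t] - S2[t];
            l1[t] += w * std::fabs(d);
            lsgn[t] += w * d;
          }
        }
        prev = ti;
        if (prev >= tstar) break;
      }
      if (ev[i]) {
        if (g[i]) {
          for (int t = 0; t < nth; ++t) {
            if (th[t] > 0.0) {
              A1[t] += pow1[t][Y1 - 1] - pow1[t][Y1];
              S1[t] = std::isinf(A1[t]) ? 0.0 : std::pow(A1[t], -1.0 / th[t]);
            } else {
              S1[t] *= (double)(Y1 - 1) / Y1;
            }
          }
          --Y1;
        } else {
          for (int t = 0; t < nth; ++t) {
            if (th[t] > 0.0) {
              A2[t] += pow2[t][Y2 - 1] - pow2[t][Y2];
              S2[t] = std::isinf(A2[t]) ? 0.0 : std::pow(A2[t], -1.0 / th[t]);
            } else {
              S2[t] *= (double)(Y2 - 1) / Y2;
            }
          }
          --Y2;
        }
      } else {
        if (g[i]) --Y1; else --Y2;
      }
    }
    for (int t = 0; t < nth; ++t) { l1[t] /= tstar; lsgn[t] /= tstar; }
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_perm_test(NumericVector x, IntegerVector status, IntegerVector group,
                   NumericVector thetas, int nperm, double seed) {
  int n = x.size();
  int n1 = 0;
  for (int i = 0; i < n; ++i) n1 += group[i];
  if (n1 < 1 || n1 >= n) stop("both groups must be non-empty");
  if (nperm < 2) stop("nperm must be at least 2");
  Engine eng(x, status, n1, thetas);
  int nth = thetas.size();

  std::vector<int> g(group.begin(), group.end());
  eng.stat(g);
  std::vector<double> l1_obs(eng.l1), lsgn_obs(eng.lsgn);

  std::vector<int> count(nth, 1); // observed assignment always counted
  Rng rng((uint64_t)seed);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  for (int p = 1; p < nperm; ++p) {
    // partial Fisher-Yates: first n1 entries of idx are a uniform subset
    for (int i = 0; i < n1; ++i) {
      int j = i + (int)rng.below((uint64_t)(n - i));
      std::swap(idx[i], idx[j]);
    }
    std::fill(g.begin(), g.end(), 0);
    for (int i = 0; i < n1; ++i) g[idx[i]] = 1;
    eng.stat(g);
    for (int t = 0; t < nth; ++t)
      if (eng.l1[t] >= l1_obs[t]) ++count[t];
  }
  NumericVector pv(nth), l1o(nth), lso(nth);
  IntegerVector cnt(nth);
  for (int t = 0; t < nth; ++t) {
    pv[t] = (double)count[t] / nperm;
    l1o[t] = l1_obs[t]; lso[t] = lsgn_obs[t]; cnt[t] = count[t];
  }
  return List::create(_["l1"] = l1o, _["l1_signed"] = lso,
                      _["p_value"] = pv, _["count_ge"] = cnt,
                      _["nperm"] = nperm);
}

// Evaluate the statistic for explicit group assignments (columns of `groups`).
// [[Rcpp::export]]
List cpp_l1_eval(NumericVector x, IntegerVector status, IntegerMatrix groups,
                 NumericVector thetas) {
  int n = x.size(), m = groups.ncol(), nth = thetas.size();
  if (groups.nrow() != n) stop("assignment matrix has wrong number of rows");
  int n1 = 0;
  for (int i = 0; i < n; ++i) n1 += groups(i, 0);
  Engine eng(x, status, n1, thetas);
  NumericMatrix l1(m, nth), lsgn(m, nth);
  std::vector<int> g(n);
  for (int c = 0; c < m; ++c) {
    int s = 0;
    for (int i = 0; i < n; ++i) { g[i] = groups(i, c); s += g[i]; }
    if (s != n1) stop("all assignments must preserve the group sizes");
    eng.stat(g);
    for (int t = 0; t < nth; ++t) { l1(c, t) = eng.l1[t]; lsgn(c, t) = eng.lsgn[t]; }
  }
  return List::create(_["l1"] = l1, _["l1_signed"] = lsgn);
}
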