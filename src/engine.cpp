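// Fast forward-time core: Hardy-Weinberg genotype allocation and the yearly
// diagnosis/mortality loop. Diagnosis draws are sequential weighted sampling
// without replacement, realised through a global alias table over per-person
// hazard weights with rejection of individuals who have already left the
// unaffected pool (exactly the conditional renormalisation the sequential
// scheme requires) plus an acceptance correction when the odds-ratio-to-
// hazard-ratio conversion shifts weights between years. Pool statistics are
// maintained incrementally, so a year costs O(events), not O(population).
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro-free deterministic generator: same stream on every platform
struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {
    for (int i = 0; i < 8; ++i) next();
  }
  inline uint64_t next() {  // splitmix64
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  inline double unif() {  // in [0, 1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

// Walker/Vose alias method: O(n) build, O(1) draw
struct AliasTable {
  std::vector<double> prob;
  std::vector<int> alias;
  int n = 0;
  double total = 0.0;

  void build(const std::vector<double>& w) {
    n = (int)w.size();
    prob.assign(n, 1.0);
    alias.assign(n, 0);
    total = 0.0;
    for (double x : w) total += x;
    if (n == 0 || total <= 0.0) { n = 0; return; }
    std::vector<double> scaled(n);
    std::vector<int> small, large;
    small.reserve(n); large.reserve(n);
    for (int i = 0; i < n; ++i) {
      scaled[i] = w[i] * n / total;
      (scaled[i] < 1.0 ? small : large).push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = scaled[s];
      alias[s] = l;
      scaled[l] = (scaled[l] + scaled[s]) - 1.0;
      (scaled[l] < 1.0 ? small : large).push_back(l);
    }
    while (!large.empty()) { prob[large.back()] = 1.0; large.pop_back(); }
    while (!small.empty()) { prob[small.back()] = 1.0; small.pop_back(); }
  }

  inline int draw(RNG& g) const {
    double u = g.unif() * n;
    int i = (int)u;
    if (i >= n) i = n - 1;
    return (u - i) < prob[i] ? i : alias[i];
  }
};

// death age from yearly death probabilities: smallest t with S[t] < u,
// where S[t] = P(alive through end of age-year t); returns A if never
inline int death_age_from_u(const std::vector<double>& S, double u, int from) {
  int A = (int)S.size();
  if (A == 0) return 0;
  if (u <= S[A - 1]) return A;
  int lo = from, hi = A - 1;  // S[hi] < u guaranteed here
  if (lo > hi) return A;
  if (S[lo] < u) return lo;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (S[mid] < u) hi = mid; else lo = mid;
  }
  return hi;
}

}  // namespace

// Allocate genotypes and centred polygenic scores for n individuals.
// Untracked variants that share (MAF, OR) are aggregated: their summed
// risk-allele count is Binomial(M, p) with M = 2 * (number of variants),
// which is exactly the sum of independent Hardy-Weinberg Binomial(2, p)
// draws. Tracked variants are drawn individually and their genotypes kept.
// [[Rcpp::export]]
List cpp_sample_population(int n,
                           IntegerVector combo_m, NumericVector combo_p,
                           NumericVector combo_beta,
                           NumericVector tracked_p, NumericVector tracked_beta,
                           double center, double seed) {
  if (n < 1) stop("n must be >= 1");
  RNG rng((uint64_t)seed);
  int nc = combo_m.size(), K = tracked_p.size();

  std::vector<AliasTable> ctab(nc), ttab(K);
  for (int j = 0; j < nc; ++j) {
    int M = combo_m[j];
    std::vector<double> pmf(M + 1);
    for (int k = 0; k <= M; ++k) pmf[k] = R::dbinom(k, M, combo_p[j], 0);
    ctab[j].build(pmf);
  }
  for (int k = 0; k < K; ++k) {
    double p = tracked_p[k];
    std::vector<double> pmf = {(1 - p) * (1 - p), 2 * p * (1 - p), p * p};
    ttab[k].build(pmf);
  }

  NumericVector prs(n);
  IntegerMatrix geno(n, K);
  for (int i = 0; i < n; ++i) {
    double s = -center;
    for (int j = 0; j < nc; ++j) s += combo_beta[j] * ctab[j].draw(rng);
    for (int k = 0; k < K; ++k) {
      int g = ttab[k].draw(rng);
      geno(i, k) = g;
      s += tracked_beta[k] * g;
    }
    prs[i] = s;
  }
  return List::create(_["prs"] = prs, _["geno"] = geno);
}

// Run the yearly diagnosis (+ optional mortality) loop over ages
// 0..A-1, where A = length(incidence). Returns per-age statistics for the
// newly diagnosed, the remaining unaffected pool (post-diagnosis,
// pre-mortality: the individual-values contrast) and the end-of-year
// surviving case and unaffected pools (the cohort bookkeeping), plus final
// per-individual diagnosis and death ages.
// [[Rcpp::export]]
List cpp_run_engine(NumericVector prs, IntegerMatrix geno,
                    NumericVector incidence, NumericVector mort_q,
                    double case_mult, bool zhang_yu, double seed) {
  const int n = prs.size();
  const int A = incidence.size();
  const int K = geno.ncol();
  if (geno.nrow() != n) stop("geno/prs size mismatch");
  if (mort_q.size() != A) stop("incidence/mortality length mismatch");
  RNG rng((uint64_t)seed ^ 0xA5A5A5A5A5A5A5A5ULL);

  // hazard weights (identity OR->HR at zero baseline)
  std::vector<double> orv(n);
  double or_min = R_PosInf, or_max = 0.0;
  for (int i = 0; i < n; ++i) {
    orv[i] = std::exp(prs[i]);
    if (orv[i] < or_min) or_min = orv[i];
    if (orv[i] > or_max) or_max = orv[i];
  }

  bool any_mort = false;
  for (int t = 0; t < A; ++t) if (mort_q[t] > 0) { any_mort = true; break; }

  // survival tables and pre-drawn death ages
  std::vector<double> Sc(A), Sq(A);
  for (int t = 0; t < A; ++t) {
    double q = std::min(1.0, std::max(0.0, mort_q[t]));
    double qc = std::min(1.0, std::max(0.0, mort_q[t] * case_mult));
    Sc[t] = (t ? Sc[t - 1] : 1.0) * (1.0 - q);
    Sq[t] = (t ? Sq[t - 1] : 1.0) * (1.0 - qc);
  }
  std::vector<int> death(n, A);
  std::vector<std::vector<int>> bucket;
  if (any_mort) {
    bucket.assign(A, std::vector<int>());
    for (int i = 0; i < n; ++i) {
      int d = death_age_from_u(Sc, rng.unif(), 0);
      death[i] = d;
      if (d < A) bucket[d].push_back(i);
    }
  }

  std::vector<int> diag(n, -1);
  std::vector<char> dead(n, 0);

  // incremental pool sums
  double u_cnt = n, u_prs = 0, u_prs2 = 0;
  std::vector<double> u_g(K, 0.0);
  for (int i = 0; i < n; ++i) { u_prs += prs[i]; u_prs2 += prs[i] * prs[i]; }
  for (int k = 0; k < K; ++k) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += geno(i, k);
    u_g[k] = s;
  }
  double c_cnt = 0, c_prs = 0, c_prs2 = 0;
  std::vector<double> c_g(K, 0.0);

  // proposal table state
  AliasTable tab;
  std::vector<int> ids(n);
  for (int i = 0; i < n; ++i) ids[i] = i;
  double p_table = 0.0;  // baseline rate the table weights were built at
  auto w_at = [&](double orx, double p0) {
    return zhang_yu ? orx / (1.0 - p0 + p0 * orx) : orx;
  };
  double table_live = 0.0;  // weight (at build-time p) still in the pool
  auto rebuild = [&](double p0) {
    ids.clear();
    std::vector<double> w;
    for (int i = 0; i < n; ++i)
      if (!dead[i] && diag[i] < 0) {
        ids.push_back(i);
        w.push_back(w_at(orv[i], p0));
      }
    tab.build(w);
    p_table = p0;
    table_live = tab.total;
  };
  {
    std::vector<double> w(n);
    for (int i = 0; i < n; ++i) w[i] = orv[i];
    tab.build(w);
    table_live = tab.total;
  }

  // outputs
  NumericVector nu_before(A), n_new(A), new_prs_s(A), new_prs2_s(A),
      iva_cnt(A), iva_prs_s(A), iva_prs2_s(A),
      eoy_case_cnt(A), eoy_case_prs_s(A), eoy_case_prs2_s(A),
      eoy_un_cnt(A), eoy_un_prs_s(A), eoy_un_prs2_s(A);
  NumericMatrix new_g(A, K), iva_g(A, K), eoy_case_g(A, K), eoy_un_g(A, K);

  double carry = 0.0;
  for (int t = 0; t < A; ++t) {
    nu_before[t] = u_cnt;
    double P0 = incidence[t];
    long nnew = 0;
    if (P0 > 0 && u_cnt > 0) {
      double x = P0 * u_cnt + carry;
      nnew = (long)std::nearbyint(x);
      if (nnew < 0) nnew = 0;
      if (nnew > (long)u_cnt) nnew = (long)u_cnt;
      carry = x - nnew;

      // acceptance bound for the year's weight shift (table built at p_table)
      double rho_max = 1.0;
      if (zhang_yu && P0 != p_table) {
        double r1 = w_at(or_min, P0) / w_at(or_min, p_table);
        double r2 = w_at(or_max, P0) / w_at(or_max, p_table);
        rho_max = std::max(r1, r2);
      }
      if (table_live < 0.02 * tab.total) { rebuild(P0); rho_max = 1.0; }

      long accepted = 0, attempts = 0;
      long att_cap = 200 + 4 * (long)u_cnt;
      while (accepted < nnew) {
        if (++attempts > att_cap) {
          rebuild(P0);
          rho_max = 1.0;
          attempts = 0;
          continue;
        }
        int j = tab.draw(rng);
        int i = ids[j];
        if (dead[i] || diag[i] >= 0) continue;
        if (zhang_yu && P0 != p_table) {
          double acc = (w_at(orv[i], P0) / w_at(orv[i], p_table)) / rho_max;
          if (rng.unif() >= acc) continue;
        }
        // diagnose i at age t
        diag[i] = t;
        ++accepted;
        table_live -= w_at(orv[i], p_table);
        double pv = prs[i];
        u_cnt -= 1; u_prs -= pv; u_prs2 -= pv * pv;
        c_cnt += 1; c_prs += pv; c_prs2 += pv * pv;
        new_prs_s[t] += pv; new_prs2_s[t] += pv * pv;
        for (int k = 0; k < K; ++k) {
          double g = geno(i, k);
          u_g[k] -= g; c_g[k] += g; new_g(t, k) += g;
        }
        if (any_mort && case_mult != 1.0) {
          double Sd = (t > 0) ? Sq[t - 1] : 1.0;
          int d;
          if (Sd <= 0) d = t;
          else d = death_age_from_u(Sq, rng.unif() * Sd, t);
          if (death[i] < A) {
            // invalidate old bucket entry by age check below
          }
          death[i] = d;
          if (d < A) bucket[d].push_back(i);
        }
      }
    }
    n_new[t] = (double)nnew;

    // individual-values snapshot: new cases vs remaining unaffected
    iva_cnt[t] = u_cnt; iva_prs_s[t] = u_prs; iva_prs2_s[t] = u_prs2;
    for (int k = 0; k < K; ++k) iva_g(t, k) = u_g[k];

    // mortality for age-year t
    if (any_mort) {
      for (int i : bucket[t]) {
        if (dead[i] || death[i] != t) continue;
        dead[i] = 1;
        double pv = prs[i];
        if (diag[i] >= 0) {
          c_cnt -= 1; c_prs -= pv; c_prs2 -= pv * pv;
          for (int k = 0; k < K; ++k) c_g[k] -= geno(i, k);
        } else {
          u_cnt -= 1; u_prs -= pv; u_prs2 -= pv * pv;
          for (int k = 0; k < K; ++k) u_g[k] -= geno(i, k);
          table_live -= w_at(orv[i], p_table);
        }
      }
    }

    // end-of-year surviving pools (cohort bookkeeping)
    eoy_case_cnt[t] = c_cnt; eoy_case_prs_s[t] = c_prs; eoy_case_prs2_s[t] = c_prs2;
    eoy_un_cnt[t] = u_cnt; eoy_un_prs_s[t] = u_prs; eoy_un_prs2_s[t] = u_prs2;
    for (int k = 0; k < K; ++k) {
      eoy_case_g(t, k) = c_g[k];
      eoy_un_g(t, k) = u_g[k];
    }
  }

  IntegerVector diag_out(n), death_out(n);
  for (int i = 0; i < n; ++i) {
    diag_out[i] = diag[i];
    death_out[i] = (death[i] < A && dead[i]) ? death[i] : -1;
  }
  return List::create(
    _["nu_before"] = nu_before, _["n_new"] = n_new,
    _["new_prs_sum"] = new_prs_s, _["new_prs2_sum"] = new_prs2_s,
    _["new_geno_sum"] = new_g,
    _["un_cnt"] = iva_cnt, _["un_prs_sum"] = iva_prs_s,
    _["un_prs2_sum"] = iva_prs2_s, _["un_geno_sum"] = iva_g,
    _["eoy_case_cnt"] = eoy_case_cnt, _["eoy_case_prs_sum"] = eoy_case_prs_s,
    _["eoy_case_prs2_sum"] = eoy_case_prs2_s, _["eoy_case_geno_sum"] = eoy_case_g,
    _["eoy_un_cnt"] = eoy_un_cnt, _["eoy_un_prs_sum"] = eoy_un_prs_s,
    _["eoy_un_prs2_sum"] = eoy_un_prs2_s, _["eoy_un_geno_sum"] = eoy_un_g,
    _["diag_age"] = diag_out, _["death_age"] = death_out);
}
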