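#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Total-similarity matrix between encoded observation and exemplar feature
// matrices. Features: kind 0 = numeric (sd scaling), 1 = categorical
// (match indicator). Zero-weight features and missing values are skipped
// in both numerator and denominator; a pair with no usable feature is NA.
// Uses the identity wf*we*(1 - |d|/(k*sd*wf*we)) = wf*we - |d|/(k*sd),
// clamped at zero.
// [[Rcpp::export]]
NumericMatrix cpp_ts_matrix(NumericMatrix obs, NumericMatrix ex,
                            IntegerVector kind, NumericVector sd,
                            NumericVector wf, NumericVector we, double k) {
  const int n_obs = obs.nrow(), n_ex = ex.nrow(), nf = obs.ncol();
  NumericMatrix ts(n_obs, n_ex);
  std::vector<double> num(n_obs), den(n_obs);
  for (int j = 0; j < n_ex; ++j) {
    std::fill(num.begin(), num.end(), 0.0);
    std::fill(den.begin(), den.end(), 0.0);
    const double wej = we[j];
    if (wej <= 0.0) {
      for (int i = 0; i < n_obs; ++i) ts(i, j) = NA_REAL;
      continue;
    }
    for (int f = 0; f < nf; ++f) {
      const double wff = wf[f];
      if (wff <= 0.0) continue;
      const double e = ex(j, f);
      if (ISNAN(e)) continue;
      const double cap = wff * wej;
      if (kind[f] == 1) {
        for (int i = 0; i < n_obs; ++i) {
          const double o = obs(i, f);
          if (ISNAN(o)) continue;
          num[i] += (o == e) ? cap : 0.0;
          den[i] += cap;
        }
      } else {
        const double inv = 1.0 / (k * sd[f]);
        for (int i = 0; i < n_obs; ++i) {
          const double o = obs(i, f);
          if (ISNAN(o)) continue;
          double ps = cap - std::fabs(o - e) * inv;
          if (ps < 0.0) ps = 0.0;
          num[i] += ps;
          den[i] += cap;
        }
      }
    }
    for (int i = 0; i < n_obs; ++i)
      ts(i, j) = den[i] > 0.0 ? num[i] / den[i] : NA_REAL;
  }
  return ts;
}

// Similarity-budget decisions for every row of a TS matrix.
// Per row: exemplars with positive, defined similarity are ranked
// descending (ties by column order, i.e. exemplar id) and accumulated until
// the summed similarity reaches k; the crossing exemplar is included in
// full. target: coverage fractions, or 0/1 (absence/presence) when
// is_class. exclude: 0-based column to leave out of the row's decision set
// (leave-one-out), -1 for none. Rows with no usable exemplar return NA.
// contrib accumulates, per exemplar, the similarity it contributed across
// all decision sets (used to find the least-contributing exemplar).
// [[Rcpp::export]]
List cpp_decide_rows(NumericMatrix ts, NumericVector target, bool is_class,
                     double k, IntegerVector exclude) {
  const int n = ts.nrow(), m = ts.ncol();
  NumericVector value(n), certainty(n), mean_sim(n), cum(n);
  IntegerVector n_used(n);
  LogicalVector exhausted(n);
  NumericVector contrib(m);
  std::vector<int> idx;
  idx.reserve(m);
  for (int i = 0; i < n; ++i) {
    idx.clear();
    const int ex_j = exclude[i];
    for (int j = 0; j < m; ++j) {
      const double t = ts(i, j);
      if (j != ex_j && !ISNAN(t) && t > 0.0) idx.push_back(j);
    }
    if (idx.empty()) {
      value[i] = NA_REAL; certainty[i] = NA_REAL; mean_sim[i] = NA_REAL;
      cum[i] = 0.0; n_used[i] = 0; exhausted[i] = true;
      continue;
    }
    // rank descending by similarity, ties by column (= exemplar id) order;
    // the comparator is a strict total order so any sort is deterministic.
    // Decision sets are usually far smaller than the base, so select the
    // top block incrementally instead of sorting everything.
    auto cmp = [&](int a, int b) {
      const double ta = ts(i, a), tb = ts(i, b);
      return ta > tb || (ta == tb && a < b);
    };
    size_t top = std::min<size_t>(32, idx.size());
    std::partial_sort(idx.begin(), idx.begin() + top, idx.end(), cmp);
    double reach = 0.0;
    for (size_t r = 0; r < top; ++r) reach += ts(i, idx[r]);
    while (reach < k && top < idx.size()) {
      size_t nt = std::min(idx.size(), top * 4);
      std::partial_sort(idx.begin() + top, idx.begin() + nt, idx.end(), cmp);
      for (size_t r = top; r < nt; ++r) reach += ts(i, idx[r]);
      top = nt;
    }
    double acc = 0.0, s_pres = 0.0, wsum = 0.0;
    int used = 0;
    for (size_t r = 0; r < idx.size(); ++r) {
      const int j = idx[r];
      const double t = ts(i, j);
      acc += t;
      ++used;
      contrib[j] += t;
      if (is_class) { if (target[j] == 1.0) s_pres += t; }
      else wsum += t * target[j];
      if (acc >= k) break;
    }
    cum[i] = acc;
    n_used[i] = used;
    exhausted[i] = acc < k;
    mean_sim[i] = acc / used;
    if (is_class) {
      const double s_abs = acc - s_pres;
      value[i] = (s_pres > s_abs) ? 1.0 : 0.0;  // tie -> absence
      certainty[i] = std::max(s_pres, s_abs) / acc;
    } else {
      value[i] = wsum / acc;
      certainty[i] = NA_REAL;
    }
  }
  return List::create(_["value"] = value, _["certainty"] = certainty,
                      _["mean_similarity"] = mean_sim, _["cumulative"] = cum,
                      _["n_used"] = n_used, _["exhausted"] = exhausted,
                      _["contrib"] = contrib);
}
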