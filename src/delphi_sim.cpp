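// Compiled core for the Monte-Carlo dependency experiments: simulates one
// full multi-round Delphi study and returns the nine study-wide consensus
// indices. Mirrors the R reference implementation operation-for-operation
// (same unif_rand stream, same candidate-window ordering, same IEEE
// expression shapes) so that both engines agree from a common seed.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Win {
  int low, high, count;
  double sum;  // sum of member ratings
};

// Greedy consensus-cluster identification on one item's rating counts.
// Candidates: every interval of width 1..v; ranked by count desc, width
// desc, low asc; selected subject to disjointness while count >= p*r_mode.
void find_clusters(const std::vector<int>& cnt, int q, int v, double p,
                   std::vector<Win>& out) {
  out.clear();
  std::vector<int> pc(q + 1, 0);
  std::vector<double> ps(q + 1, 0.0);
  for (int j = 1; j <= q; ++j) {
    pc[j] = pc[j - 1] + cnt[j - 1];
    ps[j] = ps[j - 1] + (double)j * cnt[j - 1];
  }
  std::vector<Win> cand;
  cand.reserve(q * v);
  int vmax = v < q ? v : q;
  for (int w = 1; w <= vmax; ++w)
    for (int a = 1; a + w - 1 <= q; ++a) {
      int b = a + w - 1;
      cand.push_back({a, b, pc[b] - pc[a - 1], ps[b] - ps[a - 1]});
    }
  std::sort(cand.begin(), cand.end(), [](const Win& x, const Win& y) {
    if (x.count != y.count) return x.count > y.count;
    int wx = x.high - x.low, wy = y.high - y.low;
    if (wx != wy) return wx > wy;
    return x.low < y.low;
  });
  int r_mode = cand.front().count;
  if (r_mode == 0) return;  // cannot happen with >= 1 rating
  double thr = p * r_mode - 1e-9;
  std::vector<char> used(q + 1, 0);
  for (const Win& w : cand) {
    if (w.count < thr || w.count == 0) break;
    bool overlap = false;
    for (int j = w.low; j <= w.high; ++j)
      if (used[j]) { overlap = true; break; }
    if (overlap) continue;
    for (int j = w.low; j <= w.high; ++j) used[j] = 1;
    out.push_back(w);
  }
}

// Distance from a rating to a cluster's score interval (0 inside).
double cdist(double rating, const Win& w) {
  if (rating < w.low) return w.low - rating;
  if (rating > w.high) return rating - w.high;
  return 0.0;
}

// Nearest cluster by interval distance; exact midway tie -> larger
// cluster; remaining tie -> cluster lower on the scale.
int nearest_cluster(double rating, const std::vector<Win>& cl) {
  int best = 0;
  double bd = cdist(rating, cl[0]);
  for (int c = 1; c < (int)cl.size(); ++c) {
    double d = cdist(rating, cl[c]);
    bool better = false;
    if (d < bd) better = true;
    else if (d == bd) {
      if (cl[c].count > cl[best].count) better = true;
      else if (cl[c].count == cl[best].count && cl[c].low < cl[best].low)
        better = true;
    }
    if (better) { best = c; bd = d; }
  }
  return best;
}

// R's quantile type 7 on a sorted vector (0-based).
double quantile7(const std::vector<int>& x, double prob) {
  int n = (int)x.size();
  double idx = (n - 1) * prob;
  int lo = (int)std::floor(idx);
  double g = idx - lo;
  if (lo + 1 >= n) return (double)x[n - 1];
  return (1.0 - g) * x[lo] + g * x[lo + 1];
}

}  // namespace

// Simulate one Delphi study and return the nine study-wide indices in the
// order DM, PWA, CPWA, XCPWA, KF, KC, M, CM, IQR. Consumes R's RNG stream
// (seed with set.seed() before calling).
// [[Rcpp::export]]
NumericVector cpp_study_indices(int n_items, int n_experts, double gci,
                                int scale_max, int cluster_width,
                                double threshold, int n_rounds,
                                IntegerVector lower_group,
                                IntegerVector upper_group) {
  const int n = n_items, r = n_experts, q = scale_max;
  if (n < 1 || r < 2 || q < 2) stop("invalid study dimensions");
  if (gci < 0.0 || gci > 1.0) stop("gci must lie in [0, 1]");

  // round 1: i.i.d. discrete uniform, item-major draw order (matches the
  // column-major fill of the R path)
  std::vector<int> m((size_t)r * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < r; ++k) {
      int x = (int)std::floor(unif_rand() * q) + 1;
      if (x > q) x = q;
      m[(size_t)i * r + k] = x;
    }

  std::vector<int> cnt(q);
  std::vector<Win> cl;

  // rounds 2..n_rounds: clustered convergence
  for (int t = 1; t < n_rounds; ++t) {
    for (int i = 0; i < n; ++i) {
      int* col = &m[(size_t)i * r];
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int k = 0; k < r; ++k) cnt[col[k] - 1]++;
      find_clusters(cnt, q, cluster_width, threshold, cl);
      if (cl.empty()) continue;
      for (int k = 0; k < r; ++k) {
        int c = nearest_cluster((double)col[k], cl);
        double mean = cl[c].sum / cl[c].count;
        double nx = std::floor(gci * mean + (1.0 - gci) * (double)col[k] + 0.5);
        if (nx < 1.0) nx = 1.0;
        if (nx > (double)q) nx = (double)q;
        col[k] = (int)nx;
      }
    }
  }

  // indices on the final round
  const double pairs = (double)r * (r - 1);
  double dm = 0, pwa = 0, cpwa = 0, xcpwa = 0, mo = 0, cm = 0, iqr = 0;
  double sum_cnt2 = 0;                 // sum_i sum_j r_ij^2
  std::vector<double> colsum_j(q, 0);  // sum_i r_ij
  const int xl1 = lower_group[0], xl2 = lower_group[1];
  const int xu1 = upper_group[0], xu2 = upper_group[1];
  std::vector<int> sorted(r);

  for (int i = 0; i < n; ++i) {
    const int* col = &m[(size_t)i * r];
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int k = 0; k < r; ++k) cnt[col[k] - 1]++;

    int maxc = 0;
    double pa = 0;
    for (int j = 0; j < q; ++j) {
      if (cnt[j] > maxc) maxc = cnt[j];
      pa += (double)cnt[j] * (cnt[j] - 1);
      sum_cnt2 += (double)cnt[j] * cnt[j];
      colsum_j[j] += cnt[j];
    }
    if (maxc == r) dm += 1.0;
    pwa += pa / pairs;
    mo += (double)maxc / r;

    find_clusters(cnt, q, cluster_width, threshold, cl);
    if (!cl.empty()) {
      double cp = 0;
      int best = 0;
      for (const Win& w : cl) {
        cp += (double)w.count * (w.count - 1);
        if (w.count > best) best = w.count;
      }
      cpwa += cp / pairs;
      cm += (double)best / r;
    }

    int ml = 0, mu = 0;
    for (int j = xl1; j <= xl2; ++j) ml += cnt[j - 1];
    for (int j = xu1; j <= xu2; ++j) mu += cnt[j - 1];
    xcpwa += ((double)ml * (ml - 1) + (double)mu * (mu - 1)) / pairs;

    std::copy(col, col + r, sorted.begin());
    std::sort(sorted.begin(), sorted.end());
    iqr += quantile7(sorted, 0.75) - quantile7(sorted, 0.25);
  }

  // Fleiss' kappa over all items jointly
  double P = (sum_cnt2 - (double)n * r) / ((double)n * r * (r - 1));
  double Pe_k = 0;
  for (int j = 0; j < q; ++j) {
    double pj = colsum_j[j] / ((double)n * r);
    Pe_k += pj * pj;
  }
  double kf = (P >= 1.0 - 1e-12) ? 1.0 : (P - Pe_k) / (1.0 - Pe_k);

  // Conger's kappa: subtract the between-expert marginal variance
  std::vector<double> njk_sum(q, 0), njk_sum2(q, 0);
  std::vector<int> ek(q);
  for (int k = 0; k < r; ++k) {
    std::fill(ek.begin(), ek.end(), 0);
    for (int i = 0; i < n; ++i) ek[m[(size_t)i * r + k] - 1]++;
    for (int j = 0; j < q; ++j) {
      njk_sum[j] += ek[j];
      njk_sum2[j] += (double)ek[j] * ek[j];
    }
  }
  double s2sum = 0;
  for (int j = 0; j < q; ++j)
    s2sum += (r * njk_sum2[j] - njk_sum[j] * njk_sum[j]) /
             ((double)n * n * r * r);
  double Pe_C = Pe_k - s2sum / (r - 1);
  double kc = (P >= 1.0 - 1e-12) ? 1.0 : (P - Pe_C) / (1.0 - Pe_C);

  NumericVector out = NumericVector::create(
      Named("DM") = dm / n, Named("PWA") = pwa / n, Named("CPWA") = cpwa / n,
      Named("XCPWA") = xcpwa / n, Named("KF") = kf, Named("KC") = kc,
      Named("M") = mo / n, Named("CM") = cm / n, Named("IQR") = iqr / n);
  return out;
}
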