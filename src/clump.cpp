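#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact 1-D k-medoids on sorted, length-normalized mutation positions.
// Clusters of an optimal 1-D k-medoids solution are contiguous runs of the
// sorted positions, so the optimum is found by dynamic programming over
// segment boundaries; each segment's optimal medoid is its (lower) median.
// Backtracking prefers the leftmost feasible boundary so the reported
// partition is canonical and reproducible.

static const double TOL = 1e-12;

// cumulative sums: cs[i] = sum of x[0..i-1]
static std::vector<double> cumsum0(const std::vector<double>& x) {
    std::vector<double> cs(x.size() + 1, 0.0);
    for (size_t i = 0; i < x.size(); ++i) cs[i + 1] = cs[i] + x[i];
    return cs;
}

// L1 cost of segment [i, j] (inclusive) served by its lower median
static double seg_cost(const std::vector<double>& cs,
                       const std::vector<double>& x, int i, int j) {
    int m = i + (j - i) / 2;
    double xm = x[m];
    double left  = xm * (m - i + 1) - (cs[m + 1] - cs[i]);
    double right = (cs[j + 1] - cs[m + 1]) - xm * (j - m);
    return left + right;
}

// sum of |x[i] - x[j]| over j in [l, r]
static double sum_dist(const std::vector<double>& cs,
                       const std::vector<double>& x, int i, int l, int r) {
    if (i <= l) return (cs[r + 1] - cs[l]) - x[i] * (r - l + 1);
    if (i >= r) return x[i] * (r - l + 1) - (cs[r + 1] - cs[l]);
    double left  = x[i] * (i - l + 1) - (cs[i + 1] - cs[l]);
    double right = (cs[r + 1] - cs[i + 1]) - x[i] * (r - i);
    return left + right;
}

// mean silhouette width of a contiguous partition (segment end indices,
// inclusive). Singleton clusters get s = 0; s = 0 when max(a, b) = 0.
static double mean_silhouette(const std::vector<double>& cs,
                              const std::vector<double>& x,
                              const std::vector<int>& ends) {
    int n = (int)x.size(), K = (int)ends.size();
    if (K < 2) return 0.0;
    std::vector<int> starts(K);
    starts[0] = 0;
    for (int c = 1; c < K; ++c) starts[c] = ends[c - 1] + 1;
    double tot = 0.0;
    for (int c = 0; c < K; ++c) {
        int l = starts[c], r = ends[c], sz = r - l + 1;
        for (int i = l; i <= r; ++i) {
            if (sz == 1) continue; // s_i = 0
            double a = sum_dist(cs, x, i, l, r) / (sz - 1);
            double b = R_PosInf;
            for (int c2 = 0; c2 < K; ++c2) {
                if (c2 == c) continue;
                int l2 = starts[c2], r2 = ends[c2];
                double d = sum_dist(cs, x, i, l2, r2) / (r2 - l2 + 1);
                if (d < b) b = d;
            }
            double mx = std::max(a, b);
            if (mx > TOL) tot += (b - a) / mx;
        }
    }
    return tot / n;
}

struct KFit {
    double cost;
    std::vector<int> ends; // inclusive segment ends, canonical (leftmost)
};

// exact DP for all k in 1..kmax; suffix costs allow leftmost backtracking
static std::vector<KFit> kmedoids_all(const std::vector<double>& x, int kmax) {
    int n = (int)x.size();
    std::vector<double> cs = cumsum0(x);
    // suf[k][i]: min cost of covering points i..n-1 with k segments
    std::vector<std::vector<double>> suf(kmax + 1,
        std::vector<double>(n + 1, R_PosInf));
    for (int i = 0; i < n; ++i) suf[1][i] = seg_cost(cs, x, i, n - 1);
    suf[1][n] = R_PosInf;
    for (int k = 2; k <= kmax; ++k) {
        for (int i = 0; i <= n - k; ++i) {
            double best = R_PosInf;
            for (int e = i; e <= n - k; ++e) {
                double v = seg_cost(cs, x, i, e) + suf[k - 1][e + 1];
                if (v < best) best = v;
            }
            suf[k][i] = best;
        }
    }
    std::vector<KFit> fits(kmax + 1);
    for (int k = 1; k <= kmax; ++k) {
        KFit f;
        f.cost = suf[k][0];
        int s = 0;
        for (int kk = k; kk >= 1; --kk) {
            if (kk == 1) { f.ends.push_back(n - 1); break; }
            for (int e = s; e <= n - kk; ++e) {
                double v = seg_cost(cs, x, s, e) + suf[kk - 1][e + 1];
                if (v <= suf[kk][s] + TOL) { // leftmost feasible boundary
                    f.ends.push_back(e);
                    s = e + 1;
                    break;
                }
            }
        }
        fits[k] = f;
    }
    return fits;
}

// Core scorer. x: length-normalized positions (any order); k_max >= 1.
// Returns S (mean L1 distance to nearest medoid at the selected k), the
// selected k, and per-k costs and mean silhouettes for k = 1..k_hi.
// [[Rcpp::export(name = ".clump_core")]]
List clump_core(NumericVector x, int k_max) {
    int m = x.size();
    if (m < 1) stop("at least one position required");
    if (k_max < 1) stop("k_max must be >= 1");
    std::vector<double> xs(x.begin(), x.end());
    std::sort(xs.begin(), xs.end());
    int u = 1;
    for (int i = 1; i < m; ++i) if (xs[i] != xs[i - 1]) ++u;
    int k_hi = std::min(k_max, std::min(m, u));
    if (m < 3) k_hi = 1; // too few points to select k by silhouette
    std::vector<double> cs = cumsum0(xs);
    std::vector<KFit> fits = kmedoids_all(xs, k_hi);
    NumericVector costs(k_hi), sils(k_hi);
    int k_sel = 1;
    double sil_best = 0.0; // k = 1 baseline silhouette
    for (int k = 1; k <= k_hi; ++k) {
        costs[k - 1] = fits[k].cost;
        double s = (k == 1) ? 0.0 : mean_silhouette(cs, xs, fits[k].ends);
        sils[k - 1] = s;
        if (s > sil_best + TOL) { sil_best = s; k_sel = k; }
    }
    double S = fits[k_sel].cost / m;
    return List::create(_["S"] = S, _["k"] = k_sel,
                        _["costs"] = costs, _["silhouettes"] = sils);
}

static double score_of(std::vector<double> xs, int k_max) {
    std::sort(xs.begin(), xs.end());
    int m = (int)xs.size();
    int u = 1;
    for (int i = 1; i < m; ++i) if (xs[i] != xs[i - 1]) ++u;
    int k_hi = std::min(k_max, std::min(m, u));
    if (m < 3) k_hi = 1;
    std::vector<double> cs = cumsum0(xs);
    std::vector<KFit> fits = kmedoids_all(xs, k_hi);
    int k_sel = 1;
    double sil_best = 0.0;
    for (int k = 2; k <= k_hi; ++k) {
        double s = mean_silhouette(cs, xs, fits[k].ends);
        if (s > sil_best + TOL) { sil_best = s; k_sel = k; }
    }
    return fits[k_sel].cost / m;
}

// Case/control permutation test on the clustering score. Uses R's RNG so
// results are reproducible under set.seed(). delta = S(control) - S(case);
// one-sided p with the +1 correction.
// [[Rcpp::export(name = ".clump_perm")]]
List clump_perm(NumericVector case_x, NumericVector ctrl_x,
                int n_perm, int k_max) {
    int n1 = case_x.size(), n2 = ctrl_x.size();
    if (n1 < 1 || n2 < 1) stop("both position sets must be non-empty");
    std::vector<double> cx(case_x.begin(), case_x.end());
    std::vector<double> kx(ctrl_x.begin(), ctrl_x.end());
    double s_case = score_of(cx, k_max);
    double s_ctrl = score_of(kx, k_max);
    double d_obs = s_ctrl - s_case;
    std::vector<double> pool;
    pool.reserve(n1 + n2);
    pool.insert(pool.end(), cx.begin(), cx.end());
    pool.insert(pool.end(), kx.begin(), kx.end());
    int n = n1 + n2;
    int count = 0;
    NumericVector deltas(n_perm);
    for (int p = 0; p < n_perm; ++p) {
        // partial Fisher-Yates: first n1 entries become the permuted cases
        std::vector<double> v(pool);
        for (int i = 0; i < n1; ++i) {
            int j = i + (int)(unif_rand() * (n - i));
            if (j >= n) j = n - 1;
            std::swap(v[i], v[j]);
        }
        std::vector<double> pc(v.begin(), v.begin() + n1);
        std::vector<double> pk(v.begin() + n1, v.end());
        double d = score_of(pk, k_max) - score_of(pc, k_max);
        deltas[p] = d;
        if (d >= d_obs - TOL) ++count;
    }
    double pval = (1.0 + count) / (1.0 + n_perm);
    return List::create(_["delta"] = d_obs, _["p"] = pval,
                        _["case_score"] = s_case, _["control_score"] = s_ctrl,
                        _["perm_deltas"] = deltas);
}
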