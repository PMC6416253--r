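#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Pearson correlation over finite pairs; 0 when degenerate.
static double pearson(const std::vector<double>& x, const std::vector<double>& y) {
    const int n = x.size();
    if (n < 3) return 0.0;
    double mx = 0, my = 0;
    for (int i = 0; i < n; ++i) { mx += x[i]; my += y[i]; }
    mx /= n; my /= n;
    double sxy = 0, sxx = 0, syy = 0;
    for (int i = 0; i < n; ++i) {
        const double dx = x[i] - mx, dy = y[i] - my;
        sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
    }
    if (sxx <= 0 || syy <= 0) return 0.0;
    double r = sxy / std::sqrt(sxx * syy);
    if (r > 1) r = 1; if (r < -1) r = -1;
    return r;
}

// Bootstrap cross-map skill.
//
// D:           full targets x library-candidates distance matrix (square,
//              rows and columns index the same embedding-vector set)
// lib_vals:    cause value at each library vector's head time
// target_vals: cause value at each target vector's head time
// seg, tim:    segment id and within-segment time of each vector
// boot:        n_boot x L matrix of 1-based vector indices (sampled library)
// k:           neighbors used (E + 1)
// excl:        Theiler exclusion radius; a candidate is ineligible when it
//              lies in the target's segment within +/- excl steps (excl = 0
//              still excludes the target vector itself)
//
// Returns one Pearson rho per bootstrap replicate; targets with fewer than
// k eligible neighbors are skipped.
// [[Rcpp::export]]
NumericVector ccm_boot_rho(const NumericMatrix& D,
                           const NumericVector& lib_vals,
                           const NumericVector& target_vals,
                           const IntegerVector& seg,
                           const IntegerVector& tim,
                           const IntegerMatrix& boot,
                           const int k,
                           const int excl) {
    const int n = D.nrow();
    const int n_boot = boot.nrow();
    const int L = boot.ncol();
    NumericVector rho(n_boot);
    std::vector<double> nd(k);
    std::vector<int> ni(k);
    std::vector<double> pred_v, obs_v;
    pred_v.reserve(n); obs_v.reserve(n);

    for (int b = 0; b < n_boot; ++b) {
        pred_v.clear(); obs_v.clear();
        for (int i = 0; i < n; ++i) {
            int found = 0;
            double worst = 0.0;
            int worst_at = -1;
            for (int j = 0; j < L; ++j) {
                const int idx = boot(b, j) - 1;
                if (idx == i) continue;
                if (seg[idx] == seg[i] && std::abs(tim[idx] - tim[i]) <= excl)
                    continue;
                const double d = D(i, idx);
                if (found < k) {
                    nd[found] = d; ni[found] = idx;
                    ++found;
                    if (found == k) {
                        worst_at = 0; worst = nd[0];
                        for (int m = 1; m < k; ++m)
                            if (nd[m] > worst) { worst = nd[m]; worst_at = m; }
                    }
                } else if (d < worst) {
                    nd[worst_at] = d; ni[worst_at] = idx;
                    worst_at = 0; worst = nd[0];
                    for (int m = 1; m < k; ++m)
                        if (nd[m] > worst) { worst = nd[m]; worst_at = m; }
                }
            }
            if (found < k) continue;  // too few eligible neighbors: skip target
            double dmin = nd[0];
            for (int m = 1; m < k; ++m) if (nd[m] < dmin) dmin = nd[m];
            double sw = 0, sp = 0;
            if (dmin == 0.0) {
                // exact matches: uniform weights over zero-distance neighbors
                for (int m = 0; m < k; ++m)
                    if (nd[m] == 0.0) { sw += 1.0; sp += lib_vals[ni[m]]; }
            } else {
                for (int m = 0; m < k; ++m) {
                    const double w = std::exp(-nd[m] / dmin);
                    sw += w; sp += w * lib_vals[ni[m]];
                }
            }
            pred_v.push_back(sp / sw);
            obs_v.push_back(target_vals[i]);
        }
        rho[b] = pearson(pred_v, obs_v);
    }
    return rho;
}

// Full-library simplex weight matrix for contemporaneous cross-mapping:
// row i holds the normalized neighbor weights of target i over all library
// vectors (columns).  Rows with fewer than k eligible neighbors are NA.
// [[Rcpp::export]]
NumericMatrix ccm_weight_matrix(const NumericMatrix& D,
                                const IntegerVector& seg,
                                const IntegerVector& tim,
                                const int k,
                                const int excl) {
    const int n = D.nrow();
    NumericMatrix W(n, n);
    std::vector<std::pair<double,int> > cand;
    cand.reserve(n);
    for (int i = 0; i < n; ++i) {
        cand.clear();
        for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            if (seg[j] == seg[i] && std::abs(tim[j] - tim[i]) <= excl) continue;
            cand.push_back(std::make_pair(D(i, j), j));
        }
        if ((int)cand.size() < k) {
            for (int j = 0; j < n; ++j) W(i, j) = NA_REAL;
            continue;
        }
        std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
        const double dmin = cand[0].first;
        double sw = 0.0;
        if (dmin == 0.0) {
            for (int m = 0; m < k; ++m)
                if (cand[m].first == 0.0) { W(i, cand[m].second) = 1.0; sw += 1.0; }
        } else {
            for (int m = 0; m < k; ++m) {
                const double w = std::exp(-cand[m].first / dmin);
                W(i, cand[m].second) = w; sw += w;
            }
        }
        for (int m = 0; m < k; ++m) W(i, cand[m].second) /= sw;
    }
    return W;
}

// Bootstrap cross-map skill for many candidate cause series at once.
// vals: one column per candidate series (values aligned to vector heads);
// boot: B x L bootstrap library draws shared by all candidates.
// Returns a B x S matrix of Pearson skills.
// [[Rcpp::export]]
NumericMatrix ccm_boot_rho_matrix(const NumericMatrix& D,
                                  const NumericMatrix& vals,
                                  const IntegerVector& seg,
                                  const IntegerVector& tim,
                                  const IntegerMatrix& boot,
                                  const int k,
                                  const int excl) {
    const int n = D.nrow();
    const int S = vals.ncol();
    const int B = boot.nrow();
    const int L = boot.ncol();
    NumericMatrix rho(B, S);
    std::vector<double> nd(k);
    std::vector<int> ni(k);
    std::vector<int> tgt; tgt.reserve(n);
    NumericMatrix pred(n, S);
    for (int b = 0; b < B; ++b) {
        tgt.clear();
        for (int i = 0; i < n; ++i) {
            int found = 0;
            double worst = 0.0; int worst_at = -1;
            for (int j = 0; j < L; ++j) {
                const int idx = boot(b, j) - 1;
                if (idx == i) continue;
                if (seg[idx] == seg[i] && std::abs(tim[idx] - tim[i]) <= excl)
                    continue;
                const double d = D(i, idx);
                if (found < k) {
                    nd[found] = d; ni[found] = idx; ++found;
                    if (found == k) {
                        worst_at = 0; worst = nd[0];
                        for (int m = 1; m < k; ++m)
                            if (nd[m] > worst) { worst = nd[m]; worst_at = m; }
                    }
                } else if (d < worst) {
                    nd[worst_at] = d; ni[worst_at] = idx;
                    worst_at = 0; worst = nd[0];
                    for (int m = 1; m < k; ++m)
                        if (nd[m] > worst) { worst = nd[m]; worst_at = m; }
                }
            }
            if (found < k) continue;
            double dmin = nd[0];
            for (int m = 1; m < k; ++m) if (nd[m] < dmin) dmin = nd[m];
            double sw = 0;
            std::vector<double> w(k, 0.0);
            if (dmin == 0.0) {
                for (int m = 0; m < k; ++m) if (nd[m] == 0.0) { w[m] = 1.0; sw += 1.0; }
            } else {
                for (int m = 0; m < k; ++m) { w[m] = std::exp(-nd[m] / dmin); sw += w[m]; }
            }
            for (int s = 0; s < S; ++s) {
                double sp = 0;
                for (int m = 0; m < k; ++m) sp += w[m] * vals(ni[m], s);
                pred(i, s) = sp / sw;
            }
            tgt.push_back(i);
        }
        const int nt = tgt.size();
        std::vector<double> pv(nt), ov(nt);
        for (int s = 0; s < S; ++s) {
            for (int m = 0; m < nt; ++m) { pv[m] = pred(tgt[m], s); ov[m] = vals(tgt[m], s); }
            rho(b, s) = pearson(pv, ov);
        }
    }
    return rho;
}
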