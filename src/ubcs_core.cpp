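// Core routines for biased-clustered-substitution (BCS) statistics.
//
// A substitution is clustered when some m-bp window (start aligned to a
// divisor d of m) holds at least `min_cluster` substitutions, and biased
// clustered when such a window additionally holds at least a fraction
// `threshold` of weak-to-strong substitutions.  The expected probability
// that a given substitution is BCS under independent Bernoulli(p) bias
// labels is the probability of a union of per-window events; it is
// computed exactly by a dynamic program over a compressed bin
// representation of the representative windows.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

typedef long long ll;

// upper tail P(K >= start) for K ~ Binomial(size, p)
static inline double binom_upper(int size, int start, double p) {
    if (start <= 0) return 1.0;
    if (start > size) return 0.0;
    return R::pbinom(start - 1.0, size, p, 0, 0);
}

// minimal biased count for a cluster of csize substitutions to satisfy
// biased_count / csize >= num / den, using exact integer arithmetic
static inline int bias_min_count(ll csize, ll num, ll den) {
    return (int)((num * csize + den - 1) / den);
}

static inline double align_up(double x, double d) {
    if (x < 0) x = 0;
    return std::ceil(x / d) * d;
}

struct RepWindows {
    std::vector<double> starts;
    std::vector<int> lo, hi; // 0-based inclusive index range of substitutions
};

// Representative m-bp windows containing the focal substitution: one
// witness per distinct contained-substitution set (smallest start kept),
// each with at least min_cluster substitutions.  chrom_len < 0 disables
// the right chromosome bound.
static RepWindows select_windows(const std::vector<double>& pos, int f,
                                 double m, int min_cluster, double d,
                                 double chrom_len) {
    RepWindows W;
    int n = (int)pos.size();
    double pf = pos[f];
    double s = align_up(pf - m + 1, d);
    if (s > pf) return W;
    int lo = (int)(std::lower_bound(pos.begin(), pos.end(), s) - pos.begin());
    int hi = lo - 1;
    int prev_lo = -2, prev_hi = -2;
    while (s <= pf) {
        if (chrom_len >= 0 && s + m > chrom_len) break;
        while (lo < n && pos[lo] < s) ++lo;
        while (hi + 1 < n && pos[hi + 1] < s + m) ++hi;
        int cnt = hi - lo + 1;
        if (cnt >= min_cluster) {
            if (lo != prev_lo || hi != prev_hi) {
                W.starts.push_back(s);
                W.lo.push_back(lo);
                W.hi.push_back(hi);
                prev_lo = lo;
                prev_hi = hi;
            }
            s += d;
        } else {
            // earliest start whose window could hold min_cluster substitutions
            if (lo + min_cluster - 1 >= n) break;
            double sj = align_up(pos[lo + min_cluster - 1] - m + 1, d);
            s = std::max(s + d, sj);
        }
    }
    return W;
}

// 2n-1 bins delimited by the ordered starts and ends of n representative
// windows; bin i counts the substitutions it contains
static std::vector<int> compress_bins(const RepWindows& W,
                                      const std::vector<double>& pos,
                                      double m) {
    int nw = (int)W.starts.size();
    std::vector<double> bounds;
    bounds.reserve(2 * nw);
    for (int i = 0; i < nw; ++i) bounds.push_back(W.starts[i]);
    for (int i = 0; i < nw; ++i) bounds.push_back(W.starts[i] + m);
    // starts are increasing, ends are increasing, and every window contains
    // the focal position, so last start < first end: bounds are sorted
    std::vector<int> b(2 * nw - 1);
    for (int i = 0; i + 1 < (int)bounds.size(); ++i) {
        int lo = (int)(std::lower_bound(pos.begin(), pos.end(), bounds[i]) - pos.begin());
        int hi = (int)(std::lower_bound(pos.begin(), pos.end(), bounds[i + 1]) - pos.begin());
        b[i] = hi - lo;
    }
    return b;
}

// Exact union probability P(A_1 u ... u A_n) for the telescoping sum
// P(A_1) + sum_k P(A_k & !A_1 & ... & !A_{k-1}), conditioning on the
// per-bin counts of biased substitutions (law of total probability;
// clusters k-1 and k share n-1 bins, so conditioning on those bins makes
// the past and the current cluster independent).
static double prob_bcs_exact(const std::vector<int>& b, double p,
                             ll num, ll den) {
    int B = (int)b.size();
    int n = (B + 1) / 2;
    std::vector<ll> csize(n);
    std::vector<int> thr(n);
    for (int k = 0; k < n; ++k) {
        ll c = 0;
        for (int i = k; i < k + n; ++i) c += b[i];
        csize[k] = c;
        thr[k] = bias_min_count(c, num, den);
    }
    double result = binom_upper((int)csize[0], thr[0], p);
    if (n == 1) return result;

    std::vector< std::vector<double> > db(B);
    for (int i = 0; i < B; ++i) {
        db[i].resize(b[i] + 1);
        for (int x = 0; x <= b[i]; ++x) db[i][x] = R::dbinom(x, b[i], p, 0);
    }

    // mem[state over bins k..k+n-2] = P(!A_0 & ... & !A_{k-1} | state)
    std::vector<double> mem;
    {
        ll N = 1;
        for (int i = 1; i <= n - 1; ++i) N *= (ll)(b[i] + 1);
        mem.assign((size_t)N, 0.0);
        for (ll idx = 0; idx < N; ++idx) {
            ll r = idx;
            int S = 0;
            for (int i = 1; i <= n - 1; ++i) {
                S += (int)(r % (b[i] + 1));
                r /= (b[i] + 1);
            }
            mem[(size_t)idx] = 1.0 - binom_upper(b[0], thr[0] - S, p);
        }
    }
    for (int k = 1; k < n; ++k) {
        if (k >= 2) {
            // slide the conditioning window from bins k-1..k+n-3 to k..k+n-2
            ll Nnew = 1;
            for (int i = k; i <= k + n - 2; ++i) Nnew *= (ll)(b[i] + 1);
            ll M = 1;
            for (int i = k; i <= k + n - 3; ++i) M *= (ll)(b[i] + 1);
            int bk1 = b[k - 1];
            std::vector<double> nm((size_t)Nnew, 0.0);
            for (ll idx = 0; idx < Nnew; ++idx) {
                ll r = idx;
                int S = 0;
                for (int i = k; i <= k + n - 2; ++i) {
                    S += (int)(r % (b[i] + 1));
                    r /= (b[i] + 1);
                }
                ll base = idx % M; // digits for bins k..k+n-3
                double acc = 0.0;
                for (int x = 0; x <= bk1; ++x) {
                    if ((ll)x + S < thr[k - 1])
                        acc += mem[(size_t)(x + (ll)(bk1 + 1) * base)] * db[k - 1][x];
                }
                nm[(size_t)idx] = acc;
            }
            mem.swap(nm);
        }
        ll N = 1;
        for (int i = k; i <= k + n - 2; ++i) N *= (ll)(b[i] + 1);
        double contrib = 0.0;
        for (ll idx = 0; idx < N; ++idx) {
            ll r = idx;
            int S = 0;
            double w = 1.0;
            for (int i = k; i <= k + n - 2; ++i) {
                int x = (int)(r % (b[i] + 1));
                r /= (b[i] + 1);
                S += x;
                w *= db[i][x];
            }
            contrib += binom_upper(b[k + n - 1], thr[k] - S, p) * mem[(size_t)idx] * w;
        }
        result += contrib;
    }
    if (result < 0.0) result = 0.0;
    if (result > 1.0) result = 1.0;
    return result;
}

// Seeded Monte-Carlo estimate of the same union probability, used when the
// covering region is too dense for the exact dynamic program
static double prob_bcs_mc(const std::vector<int>& b, double p,
                          ll num, ll den, int draws) {
    int B = (int)b.size();
    int n = (B + 1) / 2;
    std::vector<int> thr(n);
    for (int k = 0; k < n; ++k) {
        ll c = 0;
        for (int i = k; i < k + n; ++i) c += b[i];
        thr[k] = bias_min_count(c, num, den);
    }
    std::vector<int> x(B);
    int hit = 0;
    for (int it = 0; it < draws; ++it) {
        for (int i = 0; i < B; ++i) x[i] = (int)R::rbinom(b[i], p);
        for (int k = 0; k < n; ++k) {
            int S = 0;
            for (int i = k; i < k + n; ++i) S += x[i];
            if (S >= thr[k]) { ++hit; break; }
        }
    }
    return (double)hit / (double)draws;
}

// quick check: number of substitutions in the covering span around focal f
static inline int covering_count(const std::vector<double>& pos, int f, double m) {
    double pf = pos[f];
    int lo = (int)(std::lower_bound(pos.begin(), pos.end(), pf - m + 1) - pos.begin());
    int hi = (int)(std::upper_bound(pos.begin(), pos.end(), pf + m - 1) - pos.begin()) - 1;
    return hi - lo + 1;
}

// greedy thinning: keep a point when it lies at least `spacing` bp after
// the previously kept point (positions sorted)
// [[Rcpp::export]]
LogicalVector cpp_min_spacing(NumericVector positions, double spacing) {
    int n = positions.size();
    LogicalVector keep(n);
    if (n == 0) return keep;
    keep[0] = true;
    double last = positions[0];
    for (int i = 1; i < n; ++i) {
        if (positions[i] - last >= spacing) {
            keep[i] = true;
            last = positions[i];
        }
    }
    return keep;
}

// [[Rcpp::export]]
List cpp_select_windows(NumericVector positions, int focal, double m,
                        int min_cluster, double d, double chrom_len) {
    std::vector<double> pos(positions.begin(), positions.end());
    RepWindows W = select_windows(pos, focal - 1, m, min_cluster, d, chrom_len);
    IntegerVector lo(W.lo.size()), hi(W.hi.size());
    for (size_t i = 0; i < W.lo.size(); ++i) {
        lo[i] = W.lo[i] + 1;
        hi[i] = W.hi[i] + 1;
    }
    return List::create(_["starts"] = NumericVector(W.starts.begin(), W.starts.end()),
                        _["lo"] = lo, _["hi"] = hi);
}

// [[Rcpp::export]]
IntegerVector cpp_compress_bins(NumericVector starts, NumericVector positions,
                                double m) {
    RepWindows W;
    W.starts.assign(starts.begin(), starts.end());
    std::vector<double> pos(positions.begin(), positions.end());
    std::vector<int> b = compress_bins(W, pos, m);
    return IntegerVector(b.begin(), b.end());
}

// [[Rcpp::export]]
double cpp_prob_bcs(IntegerVector bins, double p, double thr_num,
                    double thr_den, double c_max, int mc_draws) {
    std::vector<int> b(bins.begin(), bins.end());
    ll c = 0;
    for (size_t i = 0; i < b.size(); ++i) c += b[i];
    if ((double)c > c_max)
        return prob_bcs_mc(b, p, (ll)thr_num, (ll)thr_den, mc_draws);
    return prob_bcs_exact(b, p, (ll)thr_num, (ll)thr_den);
}

// Per-substitution probability of being BCS under Bernoulli(p_i) labels.
// Returns the probability vector with attribute "n_mc" = number of
// substitutions that used the Monte-Carlo fallback.
// [[Rcpp::export]]
NumericVector cpp_expected_probs(NumericVector positions, NumericVector pvec,
                                 double m, int min_cluster, double thr_num,
                                 double thr_den, double d, double chrom_len,
                                 double c_max, int mc_draws) {
    int n = positions.size();
    std::vector<double> pos(positions.begin(), positions.end());
    NumericVector out(n);
    int n_mc = 0;
    for (int f = 0; f < n; ++f) {
        if (covering_count(pos, f, m) < min_cluster) { out[f] = 0.0; continue; }
        RepWindows W = select_windows(pos, f, m, min_cluster, d, chrom_len);
        if (W.starts.empty()) { out[f] = 0.0; continue; }
        std::vector<int> b = compress_bins(W, pos, m);
        ll c = 0;
        for (size_t i = 0; i < b.size(); ++i) c += b[i];
        if ((double)c > c_max) {
            out[f] = prob_bcs_mc(b, pvec[f], (ll)thr_num, (ll)thr_den, mc_draws);
            ++n_mc;
        } else {
            out[f] = prob_bcs_exact(b, pvec[f], (ll)thr_num, (ll)thr_den);
        }
    }
    out.attr("n_mc") = n_mc;
    return out;
}

// Observed BCS flags: substitution i is flagged when some admissible
// window containing it holds >= min_cluster substitutions of which a
// fraction >= thr_num/thr_den carry the biased label.
// [[Rcpp::export]]
LogicalVector cpp_observed_flags(NumericVector positions, IntegerVector biased,
                                 double m, int min_cluster, double thr_num,
                                 double thr_den, double d, double chrom_len) {
    int n = positions.size();
    LogicalVector out(n);
    if (n == 0) return out;
    std::vector<double> pos(positions.begin(), positions.end());
    std::vector<int> pb(n + 1, 0);
    for (int i = 0; i < n; ++i) pb[i + 1] = pb[i] + (biased[i] ? 1 : 0);
    std::vector<int> delta(n + 1, 0);
    ll num = (ll)thr_num, den = (ll)thr_den;
    double s = align_up(pos[0] - m + 1, d);
    int lo = 0, hi = -1;
    while (true) {
        if (chrom_len >= 0 && s + m > chrom_len) break;
        while (lo < n && pos[lo] < s) ++lo;
        if (lo >= n) break;
        if (pos[lo] >= s + m) { // empty window: jump to the next occupied one
            s = std::max(s + d, align_up(pos[lo] - m + 1, d));
            continue;
        }
        if (hi < lo - 1) hi = lo - 1;
        while (hi + 1 < n && pos[hi + 1] < s + m) ++hi;
        int cnt = hi - lo + 1;
        if (cnt >= min_cluster) {
            int bc = pb[hi + 1] - pb[lo];
            if ((ll)bc * den >= num * (ll)cnt) {
                delta[lo] += 1;
                delta[hi + 1] -= 1;
            }
            s += d;
        } else {
            if (lo + min_cluster - 1 >= n) break;
            s = std::max(s + d, align_up(pos[lo + min_cluster - 1] - m + 1, d));
        }
    }
    int acc = 0;
    for (int i = 0; i < n; ++i) {
        acc += delta[i];
        out[i] = acc > 0;
    }
    return out;
}
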