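#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Hartigan & Hartigan's dip statistic for unimodality.
//
// Works on the sorted sample in "count" units: the empirical CDF at x[i]
// (0-based) jumps from i/n to (i+1)/n, so a unimodal CDF G must satisfy
// (i+1) - t*n <= n*G(x[i]) <= i + t*n for sup|Fn - G| <= t.  The iterative
// algorithm maintains a candidate modal interval [lo, hi], fits the greatest
// convex minorant (GCM) and least concave majorant (LCM) of the points
// (x[i], i+1) on it, finds the largest disagreement between the two fits,
// accrues the deviations of the convex part left of / concave part right of
// the disagreement, and narrows the modal interval until the fits agree up
// to the deviation already paid.  The dip is (max deviation)/(2n).

static double dip_sorted(const double *x, int n) {
    if (n <= 0) return NA_REAL;
    if (n <= 3) return 0.5 / n;

    std::vector<int> mn(n), mj(n), gcm(n + 1), lcm(n + 1);
    int lo = 0, hi = n - 1;
    double D = 0.0; // best (largest required) deviation so far, count units

    for (int iter = 0; iter < 2 * n + 10; ++iter) {
        // GCM predecessor pointers on [lo, hi]: chain below points (x[i], i)
        mn[lo] = lo;
        for (int j = lo + 1; j <= hi; ++j) {
            mn[j] = j - 1;
            while (mn[j] != lo) {
                int b = mn[j], a = mn[b];
                // keep b iff slope(a->b) < slope(b->j)
                if ((double)(b - a) * (x[j] - x[b]) <
                    (double)(j - b) * (x[b] - x[a])) break;
                mn[j] = a;
            }
        }
        // LCM successor pointers on [lo, hi]: chain above the points
        mj[hi] = hi;
        for (int j = hi - 1; j >= lo; --j) {
            mj[j] = j + 1;
            while (mj[j] != hi) {
                int b = mj[j], c = mj[b];
                // keep b iff slope(j->b) > slope(b->c)
                if ((double)(b - j) * (x[c] - x[b]) >
                    (double)(c - b) * (x[b] - x[j])) break;
                mj[j] = c;
            }
        }
        // gcm[1..l_gcm]: vertices from hi down to lo; lcm[1..l_lcm]: lo..hi
        int l_gcm = 0, i = hi;
        do { gcm[++l_gcm] = i; i = mn[i]; } while (gcm[l_gcm] != lo);
        int l_lcm = 0; i = lo;
        do { lcm[++l_lcm] = i; i = mj[i]; } while (lcm[l_lcm] != hi);

        double d;
        int ig = l_gcm, ih = l_lcm;
        if (l_gcm == 2 && l_lcm == 2) {
            d = 1.0;
        } else {
            // walk both vertex lists, measuring each vertex of one fit
            // against the spanning chord of the other
            d = 0.0;
            int ix = l_gcm - 1, iv = 2;
            do {
                int gx = gcm[ix], lv = lcm[iv];
                if (gx > lv) {
                    // LCM vertex lv inside GCM chord (gcm[ix+1], gcm[ix])
                    int a = gcm[ix + 1], b = gx;
                    double dx = (lv - a + 1) -
                        (x[lv] - x[a]) * (double)(b - a) / (x[b] - x[a]);
                    ++iv;
                    if (dx >= d) { d = dx; ig = ix + 1; ih = iv - 1; }
                } else {
                    // GCM vertex gx inside LCM chord (lcm[iv-1], lcm[iv])
                    int a = lcm[iv - 1], b = lv;
                    double dx = (x[gx] - x[a]) * (double)(b - a) /
                        (x[b] - x[a]) - (gx - a - 1);
                    --ix;
                    if (dx > d) { d = dx; ig = ix + 1; ih = iv; }
                }
                if (ix < 1) ix = 1;
                if (iv > l_lcm) iv = l_lcm;
            } while (gcm[ix] != lcm[iv]);
        }
        if (d <= D) break;

        // deviation of the convex fit on [lo, gcm[ig]]
        double dip_l = 1.0;
        for (int j = ig; j < l_gcm; ++j) {
            int a = gcm[j + 1], b = gcm[j];
            if (b - a > 1 && x[b] != x[a]) {
                double C = (double)(b - a) / (x[b] - x[a]);
                for (int jj = a + 1; jj < b; ++jj) {
                    double t = (jj - a + 1) - (x[jj] - x[a]) * C;
                    if (t > dip_l) dip_l = t;
                }
            }
        }
        // deviation of the concave fit on [lcm[ih], hi]
        double dip_u = 1.0;
        for (int j = ih; j < l_lcm; ++j) {
            int a = lcm[j], b = lcm[j + 1];
            if (b - a > 1 && x[b] != x[a]) {
                double C = (double)(b - a) / (x[b] - x[a]);
                for (int jj = a + 1; jj < b; ++jj) {
                    double t = (x[jj] - x[a]) * C - (jj - a - 1);
                    if (t > dip_u) dip_u = t;
                }
            }
        }
        if (dip_l > D) D = dip_l;
        if (dip_u > D) D = dip_u;

        int new_lo = gcm[ig], new_hi = lcm[ih];
        if (new_lo == lo && new_hi == hi) { if (d > D) D = d; break; }
        lo = new_lo; hi = new_hi;
    }
    if (D < 1.0) D = 1.0;
    return D / (2.0 * n);
}

// [[Rcpp::export]]
double dip_stat_cpp(NumericVector x) {
    NumericVector xs = clone(x);
    std::sort(xs.begin(), xs.end());
    return dip_sorted(REAL(xs), xs.size());
}

// Bootstrap null sample of the dip under the uniform distribution.
// Uses R's RNG so reproducibility follows set.seed() in the caller.
// [[Rcpp::export]]
NumericVector dip_null_cpp(int n, int B) {
    NumericVector out(B);
    std::vector<double> buf(n);
    for (int b = 0; b < B; ++b) {
        for (int i = 0; i < n; ++i) buf[i] = unif_rand();
        std::sort(buf.begin(), buf.end());
        out[b] = dip_sorted(buf.data(), n);
    }
    return out;
}
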