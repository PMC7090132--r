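#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher's
// lower-envelope-of-parabolas method), separable over axes, with per-axis
// voxel spacing.  Arrays are indexed (z, y, x) with z fastest (R array with
// dim = c(Z, Y, X)).

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform of sampled function f at coordinates pos[]
static void dt1d(const std::vector<double> &f, const std::vector<double> &pos,
                 std::vector<double> &d) {
    int n = f.size();
    std::vector<int> v(n);
    std::vector<double> z(n + 1);
    int k = 0;
    v[0] = 0; z[0] = -INF; z[1] = INF;
    for (int q = 1; q < n; ++q) {
        if (f[q] == INF) continue;
        if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
        double s;
        while (true) {
            int p = v[k];
            s = ((f[q] + pos[q] * pos[q]) - (f[p] + pos[p] * pos[p])) /
                (2 * pos[q] - 2 * pos[p]);
            if (s <= z[k]) { --k; } else break;
        }
        ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        if (f[v[0]] == INF) { d[q] = INF; continue; }
        while (z[k + 1] < pos[q]) ++k;
        double dp = pos[q] - pos[v[k]];
        d[q] = dp * dp + f[v[k]];
    }
}

// Squared distance from every voxel to the nearest background (FALSE) voxel.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
    int Z = dim[0], Y = dim[1], X = dim[2];
    double dz = spacing[0], dy = spacing[1], dx = spacing[2];
    R_xlen_t n = (R_xlen_t)Z * Y * X;
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? INF : 0.0;

    std::vector<double> f, pos, d;
    // along z
    if (Z > 1) {
        f.resize(Z); d.resize(Z); pos.resize(Z);
        for (int i = 0; i < Z; ++i) pos[i] = i * dz;
        for (int x = 0; x < X; ++x)
            for (int y = 0; y < Y; ++y) {
                R_xlen_t base = (R_xlen_t)Z * (y + (R_xlen_t)Y * x);
                for (int z = 0; z < Z; ++z) f[z] = out[base + z];
                dt1d(f, pos, d);
                for (int z = 0; z < Z; ++z) out[base + z] = d[z];
            }
    }
    // along y
    if (Y > 1) {
        f.resize(Y); d.resize(Y); pos.resize(Y);
        for (int i = 0; i < Y; ++i) pos[i] = i * dy;
        for (int x = 0; x < X; ++x)
            for (int z = 0; z < Z; ++z) {
                R_xlen_t base = z + (R_xlen_t)Z * Y * x;
                for (int y = 0; y < Y; ++y) f[y] = out[base + (R_xlen_t)Z * y];
                dt1d(f, pos, d);
                for (int y = 0; y < Y; ++y) out[base + (R_xlen_t)Z * y] = d[y];
            }
    }
    // along x
    if (X > 1) {
        f.resize(X); d.resize(X); pos.resize(X);
        for (int i = 0; i < X; ++i) pos[i] = i * dx;
        for (int y = 0; y < Y; ++y)
            for (int z = 0; z < Z; ++z) {
                R_xlen_t base = z + (R_xlen_t)Z * y;
                for (int x = 0; x < X; ++x)
                    f[x] = out[base + (R_xlen_t)Z * Y * x];
                dt1d(f, pos, d);
                for (int x = 0; x < X; ++x)
                    out[base + (R_xlen_t)Z * Y * x] = d[x];
            }
    }
    // all-foreground input: no background anywhere -> infinite distance
    return out;
}
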