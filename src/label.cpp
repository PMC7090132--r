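#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component machinery on 3D logical arrays indexed (z, y, x),
// z fastest (R array dim = c(Z, Y, X)).  Connectivity 6, 18 or 26.

struct Grid {
    int Z, Y, X;
    Grid(IntegerVector dim) : Z(dim[0]), Y(dim[1]), X(dim[2]) {}
    inline R_xlen_t idx(int z, int y, int x) const {
        return z + (R_xlen_t)Z * (y + (R_xlen_t)Y * x);
    }
};

static inline bool conn_ok(int dz, int dy, int dx, int conn) {
    int m = std::abs(dz) + std::abs(dy) + std::abs(dx);
    if (m == 0) return false;
    if (conn == 6) return m == 1;
    if (conn == 18) return m <= 2;
    return true; // 26
}

// Label 26/18/6-connected components of TRUE voxels; 0 = background.
// [[Rcpp::export]]
IntegerVector label_cc_cpp(LogicalVector mask, IntegerVector dim, int conn) {
    Grid g(dim);
    R_xlen_t n = (R_xlen_t)g.Z * g.Y * g.X;
    IntegerVector lab(n, 0);
    std::vector<R_xlen_t> queue;
    int next = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || lab[s]) continue;
        lab[s] = ++next;
        queue.clear(); queue.push_back(s);
        while (!queue.empty()) {
            R_xlen_t v = queue.back(); queue.pop_back();
            int z = v % g.Z, y = (v / g.Z) % g.Y, x = v / ((R_xlen_t)g.Z * g.Y);
            for (int dz = -1; dz <= 1; ++dz)
                for (int dy = -1; dy <= 1; ++dy)
                    for (int dx = -1; dx <= 1; ++dx) {
                        if (!conn_ok(dz, dy, dx, conn)) continue;
                        int zz = z + dz, yy = y + dy, xx = x + dx;
                        if (zz < 0 || zz >= g.Z || yy < 0 || yy >= g.Y ||
                            xx < 0 || xx >= g.X) continue;
                        R_xlen_t w = g.idx(zz, yy, xx);
                        if (mask[w] && !lab[w]) {
                            lab[w] = next;
                            queue.push_back(w);
                        }
                    }
        }
    }
    lab.attr("n_components") = next;
    return lab;
}

// TRUE voxels connected (conn-connectivity) to the seed voxel (0-based z,y,x).
// Returns all-FALSE if the seed itself is FALSE.
// [[Rcpp::export]]
LogicalVector flood_cpp(LogicalVector mask, IntegerVector dim,
                        IntegerVector seed, int conn) {
    Grid g(dim);
    R_xlen_t n = (R_xlen_t)g.Z * g.Y * g.X;
    LogicalVector out(n, false);
    R_xlen_t s = g.idx(seed[0], seed[1], seed[2]);
    if (!mask[s]) return out;
    std::vector<R_xlen_t> queue;
    out[s] = true; queue.push_back(s);
    while (!queue.empty()) {
        R_xlen_t v = queue.back(); queue.pop_back();
        int z = v % g.Z, y = (v / g.Z) % g.Y, x = v / ((R_xlen_t)g.Z * g.Y);
        for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
                for (int dx = -1; dx <= 1; ++dx) {
                    if (!conn_ok(dz, dy, dx, conn)) continue;
                    int zz = z + dz, yy = y + dy, xx = x + dx;
                    if (zz < 0 || zz >= g.Z || yy < 0 || yy >= g.Y ||
                        xx < 0 || xx >= g.X) continue;
                    R_xlen_t w = g.idx(zz, yy, xx);
                    if (mask[w] && !out[w]) { out[w] = true; queue.push_back(w); }
                }
    }
    return out;
}

// Plateau-aware regional maxima of `values` restricted to TRUE voxels of
// `mask`.  A regional maximum is a conn-connected set of equal value none of
// whose in-mask neighbours has a larger value.  Returns a label array with
// one positive label per maximum plateau (0 elsewhere).
// [[Rcpp::export]]
IntegerVector regmax_cpp(NumericVector values, LogicalVector mask,
                         IntegerVector dim, int conn) {
    Grid g(dim);
    R_xlen_t n = (R_xlen_t)g.Z * g.Y * g.X;
    IntegerVector lab(n, 0);
    std::vector<R_xlen_t> queue, comp;
    int next = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || lab[s]) continue;
        // flood the equal-value plateau containing s
        double val = values[s];
        bool is_max = true;
        ++next;
        lab[s] = next;
        queue.clear(); comp.clear();
        queue.push_back(s); comp.push_back(s);
        while (!queue.empty()) {
            R_xlen_t v = queue.back(); queue.pop_back();
            int z = v % g.Z, y = (v / g.Z) % g.Y, x = v / ((R_xlen_t)g.Z * g.Y);
            for (int dz = -1; dz <= 1; ++dz)
                for (int dy = -1; dy <= 1; ++dy)
                    for (int dx = -1; dx <= 1; ++dx) {
                        if (!conn_ok(dz, dy, dx, conn)) continue;
                        int zz = z + dz, yy = y + dy, xx = x + dx;
                        if (zz < 0 || zz >= g.Z || yy < 0 || yy >= g.Y ||
                            xx < 0 || xx >= g.X) continue;
                        R_xlen_t w = g.idx(zz, yy, xx);
                        if (!mask[w]) continue;
                        if (values[w] > val) is_max = false;
                        else if (values[w] == val && lab[w] != next) {
                            lab[w] = next;
                            queue.push_back(w); comp.push_back(w);
                        }
                    }
        }
        if (!is_max) {
            for (R_xlen_t v : comp) lab[v] = -1; // visited, not a maximum
        }
    }
    for (R_xlen_t i = 0; i < n; ++i) if (lab[i] < 0) lab[i] = 0;
    return lab;
}
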