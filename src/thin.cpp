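#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Topology-preserving 3D curve thinning.  A voxel is "simple" (deletable
// without changing topology) iff (A) the foreground voxels of its 26-
// neighbourhood form exactly one 26-connected component adjacent to it, and
// (B) the background voxels of its 18-neighbourhood form exactly one
// 6-connected component 6-adjacent to it (standard simple-point
// characterization).  Curve endpoints (<= 1 foreground neighbour) are kept.
// Candidates are removed in order of increasing priority (Euclidean distance
// to the boundary), which keeps the medial curve centred in the object.

static inline int off3(int dz, int dy, int dx) {
    return (dz + 1) + 3 * ((dy + 1) + 3 * (dx + 1));
}

// foreground occupancy of the 3x3x3 neighbourhood (center forced FALSE)
static void neighborhood(const int *mask, int Z, int Y, int X,
                         int z, int y, int x, bool nb[27]) {
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int zz = z + dz, yy = y + dy, xx = x + dx;
                bool v = false;
                if (zz >= 0 && zz < Z && yy >= 0 && yy < Y &&
                    xx >= 0 && xx < X)
                    v = mask[zz + (R_xlen_t)Z * (yy + (R_xlen_t)Y * xx)] != 0;
                nb[off3(dz, dy, dx)] = v;
            }
    nb[off3(0, 0, 0)] = false;
}

static bool is_simple(const bool nb[27]) {
    // condition A: one 26-connected foreground component in N26
    int compA = 0;
    bool seen[27] = {false};
    int stack[27];
    for (int i = 0; i < 27; ++i) {
        if (i == 13 || !nb[i] || seen[i]) continue;
        ++compA;
        if (compA > 1) return false;
        int top = 0; stack[top++] = i; seen[i] = true;
        while (top) {
            int v = stack[--top];
            int vz = v % 3, vy = (v / 3) % 3, vx = v / 9;
            for (int w = 0; w < 27; ++w) {
                if (w == 13 || seen[w] || !nb[w]) continue;
                int wz = w % 3, wy = (w / 3) % 3, wx = w / 9;
                if (std::abs(wz - vz) <= 1 && std::abs(wy - vy) <= 1 &&
                    std::abs(wx - vx) <= 1) {
                    seen[w] = true; stack[top++] = w;
                }
            }
        }
    }
    if (compA != 1) return false;

    // condition B: background 6-components within the 18-neighbourhood that
    // touch the center by a face; must be exactly one
    bool bg[27], seenB[27] = {false};
    for (int i = 0; i < 27; ++i) {
        int z = i % 3 - 1, y = (i / 3) % 3 - 1, x = i / 9 - 1;
        int m = std::abs(z) + std::abs(y) + std::abs(x);
        bg[i] = (m >= 1 && m <= 2) && !nb[i];
    }
    int compB = 0;
    for (int i = 0; i < 27; ++i) {
        if (!bg[i] || seenB[i]) continue;
        // grow the 6-connected background component within N18
        int top = 0; stack[top++] = i; seenB[i] = true;
        bool touches = false;
        while (top) {
            int v = stack[--top];
            int vz = v % 3 - 1, vy = (v / 3) % 3 - 1, vx = v / 9 - 1;
            if (std::abs(vz) + std::abs(vy) + std::abs(vx) == 1) touches = true;
            for (int w = 0; w < 27; ++w) {
                if (!bg[w] || seenB[w]) continue;
                int wz = w % 3 - 1, wy = (w / 3) % 3 - 1, wx = w / 9 - 1;
                if (std::abs(wz - vz) + std::abs(wy - vy) +
                    std::abs(wx - vx) == 1) {
                    seenB[w] = true; stack[top++] = w;
                }
            }
        }
        if (touches) ++compB;
        if (compB > 1) return false;
    }
    return compB == 1;
}

static inline int n26_count(const bool nb[27]) {
    int c = 0;
    for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++c;
    return c;
}

// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector priority) {
    int Z = dim[0], Y = dim[1], X = dim[2];
    R_xlen_t n = (R_xlen_t)Z * Y * X;
    std::vector<int> m(n);
    for (R_xlen_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;

    bool nb[27];
    bool changed = true;
    std::vector<std::pair<double, R_xlen_t> > cand;
    while (changed) {
        changed = false;
        cand.clear();
        for (R_xlen_t i = 0; i < n; ++i) {
            if (!m[i]) continue;
            int z = i % Z, y = (i / Z) % Y, x = i / ((R_xlen_t)Z * Y);
            neighborhood(m.data(), Z, Y, X, z, y, x, nb);
            int cnt = n26_count(nb);
            if (cnt <= 1 || cnt == 26) continue; // endpoint or interior-full
            if (is_simple(nb)) cand.push_back(std::make_pair(priority[i], i));
        }
        std::sort(cand.begin(), cand.end());
        for (size_t k = 0; k < cand.size(); ++k) {
            R_xlen_t i = cand[k].second;
            int z = i % Z, y = (i / Z) % Y, x = i / ((R_xlen_t)Z * Y);
            neighborhood(m.data(), Z, Y, X, z, y, x, nb);
            if (n26_count(nb) <= 1) continue; // became an endpoint
            if (!is_simple(nb)) continue;     // deletion order invalidated it
            m[i] = 0;
            changed = true;
        }
    }
    LogicalVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = m[i] != 0;
    return out;
}
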