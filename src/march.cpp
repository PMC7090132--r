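#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Iso-surface area by marching tetrahedra.  Each cell of 8 voxel samples is
// split into 6 tetrahedra sharing the main diagonal; within a tetrahedron
// the level-set of the linear interpolant is a triangle or a quad (two
// triangles) whose corners lie on the edges crossing the iso-level.
// Physical voxel coordinates (z*dz, y*dy, x*dx) make the result an area in
// squared physical units.  Array indexed (z, y, x), z fastest.

struct P3 { double z, y, x; };

static inline P3 lerp(const P3 &a, const P3 &b, double fa, double fb,
                      double level) {
    double t = (level - fa) / (fb - fa);
    P3 p; p.z = a.z + t * (b.z - a.z); p.y = a.y + t * (b.y - a.y);
    p.x = a.x + t * (b.x - a.x);
    return p;
}

static inline double tri_area(const P3 &a, const P3 &b, const P3 &c) {
    double uz = b.z - a.z, uy = b.y - a.y, ux = b.x - a.x;
    double vz = c.z - a.z, vy = c.y - a.y, vx = c.x - a.x;
    double cz = uy * vx - ux * vy;
    double cy = ux * vz - uz * vx;
    double cx = uz * vy - uy * vz;
    return 0.5 * std::sqrt(cz * cz + cy * cy + cx * cx);
}

// tetrahedra of the unit cube (corner ids 0..7 with bit 0 = z, 1 = y, 2 = x)
static const int TETS[6][4] = {
    {0,1,3,7}, {0,3,2,7}, {0,2,6,7}, {0,6,4,7}, {0,4,5,7}, {0,5,1,7}
};

static double tet_area(const P3 v[4], const double f[4], double level) {
    int above = 0, idxA[4], idxB[4], nA = 0, nB = 0;
    for (int i = 0; i < 4; ++i) {
        if (f[i] > level) { idxA[nA++] = i; ++above; }
        else idxB[nB++] = i;
    }
    if (above == 0 || above == 4) return 0.0;
    if (above == 1 || above == 3) {
        int a = (above == 1) ? idxA[0] : idxB[0];
        const int *others = (above == 1) ? idxB : idxA;
        P3 p0 = lerp(v[a], v[others[0]], f[a], f[others[0]], level);
        P3 p1 = lerp(v[a], v[others[1]], f[a], f[others[1]], level);
        P3 p2 = lerp(v[a], v[others[2]], f[a], f[others[2]], level);
        return tri_area(p0, p1, p2);
    }
    // 2 above / 2 below: quad with corners on the 4 crossing edges
    int a0 = idxA[0], a1 = idxA[1], b0 = idxB[0], b1 = idxB[1];
    P3 p00 = lerp(v[a0], v[b0], f[a0], f[b0], level);
    P3 p01 = lerp(v[a0], v[b1], f[a0], f[b1], level);
    P3 p10 = lerp(v[a1], v[b0], f[a1], f[b0], level);
    P3 p11 = lerp(v[a1], v[b1], f[a1], f[b1], level);
    return tri_area(p00, p01, p11) + tri_area(p00, p11, p10);
}

// [[Rcpp::export]]
double mt_area_cpp(NumericVector field, IntegerVector dim,
                   NumericVector spacing, double level) {
    int Z = dim[0], Y = dim[1], X = dim[2];
    double dz = spacing[0], dy = spacing[1], dx = spacing[2];
    double total = 0.0;
    for (int x = 0; x + 1 < X; ++x)
        for (int y = 0; y + 1 < Y; ++y)
            for (int z = 0; z + 1 < Z; ++z) {
                P3 v[8]; double f[8];
                for (int c = 0; c < 8; ++c) {
                    int cz = z + (c & 1), cy = y + ((c >> 1) & 1),
                        cx = x + ((c >> 2) & 1);
                    v[c].z = cz * dz; v[c].y = cy * dy; v[c].x = cx * dx;
                    f[c] = field[cz + (R_xlen_t)Z * (cy + (R_xlen_t)Y * cx)];
                }
                bool any = false, all = true;
                for (int c = 0; c < 8; ++c) {
                    if (f[c] > level) any = true; else all = false;
                }
                if (!any || all) continue;
                for (int t = 0; t < 6; ++t) {
                    P3 tv[4]; double tf[4];
                    for (int i = 0; i < 4; ++i) {
                        tv[i] = v[TETS[t][i]];
                        tf[i] = f[TETS[t][i]];
                    }
                    total += tet_area(tv, tf, level);
                }
            }
    return total;
}
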