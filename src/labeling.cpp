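#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Neighborhood offsets for 6/18/26 connectivity in 3D.
// 6: face neighbours; 18: face + edge; 26: face + edge + corner.
static void neighbour_offsets(int connectivity,
                              std::vector<int>& dx,
                              std::vector<int>& dy,
                              std::vector<int>& dz) {
    dx.clear(); dy.clear(); dz.clear();
    for (int cz = -1; cz <= 1; ++cz)
        for (int cy = -1; cy <= 1; ++cy)
            for (int cx = -1; cx <= 1; ++cx) {
                int nz = std::abs(cx) + std::abs(cy) + std::abs(cz);
                if (nz == 0) continue;
                if (connectivity == 6 && nz > 1) continue;
                if (connectivity == 18 && nz > 2) continue;
                dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
            }
}

// Connected-component labeling of a binary 3D mask.
// Components are numbered 1..K in order of first encounter under
// column-major scan, so the result is deterministic.
// [[Rcpp::export(name = ".cc_label3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims, int connectivity) {
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dims");

    std::vector<int> dx, dy, dz;
    neighbour_offsets(connectivity, dx, dy, dz);
    const int nn = (int)dx.size();

    IntegerVector out(n, 0);
    int next_id = 0;
    std::queue<R_xlen_t> q;

    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i] || out[i] != 0) continue;
        ++next_id;
        out[i] = next_id;
        q.push(i);
        while (!q.empty()) {
            R_xlen_t v = q.front(); q.pop();
            int x = (int)(v % nx);
            int y = (int)((v / nx) % ny);
            int z = (int)(v / ((R_xlen_t)nx * ny));
            for (int k = 0; k < nn; ++k) {
                int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                    continue;
                R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
                if (mask[w] && out[w] == 0) {
                    out[w] = next_id;
                    q.push(w);
                }
            }
        }
    }
    out.attr("n_components") = next_id;
    return out;
}

struct GeoNode {
    double dist;
    int id;
    R_xlen_t idx;
};
struct GeoNodeCmp {
    // min-heap on (dist, id, idx) so expansion order is deterministic
    bool operator()(const GeoNode& a, const GeoNode& b) const {
        if (a.dist != b.dist) return a.dist > b.dist;
        if (a.id != b.id) return a.id > b.id;
        return a.idx > b.idx;
    }
};

// Multi-source Dijkstra over the region mask (edge ∪ core voxels).
// seeds[i] > 0 marks a source voxel carrying that instance id (core voxels).
// Steps move between 26-neighbours inside the region, weighted by the
// physical (anisotropic) Euclidean step length in mm. Each region voxel is
// assigned the id of its geodesically nearest source; distance ties are
// broken in favour of the smaller instance id. Unreachable region voxels
// (edge components with no core) stay 0.
// [[Rcpp::export(name = ".geodesic_assign")]]
IntegerVector geodesic_assign(LogicalVector region, IntegerVector seeds,
                              IntegerVector dims, NumericVector spacing) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (region.size() != n || seeds.size() != n)
        stop("region/seeds length does not match dims");

    std::vector<int> dx, dy, dz;
    neighbour_offsets(26, dx, dy, dz);
    const int nn = (int)dx.size();
    std::vector<double> step(nn);
    for (int k = 0; k < nn; ++k) {
        double sx = dx[k] * spacing[0], sy = dy[k] * spacing[1], sz = dz[k] * spacing[2];
        step[k] = std::sqrt(sx * sx + sy * sy + sz * sz);
    }

    const double INF = R_PosInf;
    const double EPS = 1e-9;
    std::vector<double> dist(n, INF);
    IntegerVector id(n, 0);

    std::priority_queue<GeoNode, std::vector<GeoNode>, GeoNodeCmp> pq;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (seeds[i] > 0) {
            dist[i] = 0.0;
            id[i] = seeds[i];
            pq.push({0.0, seeds[i], i});
        }
    }

    while (!pq.empty()) {
        GeoNode cur = pq.top(); pq.pop();
        if (cur.dist > dist[cur.idx] + EPS || cur.id != id[cur.idx]) continue;
        int x = (int)(cur.idx % nx);
        int y = (int)((cur.idx / nx) % ny);
        int z = (int)(cur.idx / ((R_xlen_t)nx * ny));
        for (int k = 0; k < nn; ++k) {
            int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                continue;
            R_xlen_t w = (R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
            if (!region[w]) continue;
            double nd = cur.dist + step[k];
            bool better = nd < dist[w] - EPS;
            bool tie_lower_id = std::abs(nd - dist[w]) <= EPS && cur.id < id[w];
            if (better || tie_lower_id) {
                dist[w] = nd;
                id[w] = cur.id;
                pq.push({nd, cur.id, w});
            }
        }
    }
    return id;
}
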