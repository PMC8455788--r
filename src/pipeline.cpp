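#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// All arrays are column-major (x fastest), 0-based linear indices internally.

static inline void neighbors6(int idx, int nx, int ny, int nz, int* out, int& n) {
    n = 0;
    int x = idx % nx;
    int y = (idx / nx) % ny;
    int z = idx / (nx * ny);
    if (x > 0)      out[n++] = idx - 1;
    if (x < nx - 1) out[n++] = idx + 1;
    if (y > 0)      out[n++] = idx - nx;
    if (y < ny - 1) out[n++] = idx + nx;
    if (z > 0)      out[n++] = idx - nx * ny;
    if (z < nz - 1) out[n++] = idx + nx * ny;
}

// 6-connected component labeling; labels assigned 1..K in ascending order of
// each component's first-encountered voxel (column-major scan).
// [[Rcpp::export(name = ".cc_label6")]]
IntegerVector cc_label6(LogicalVector mask, IntegerVector dims) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector labels(n, 0);
    std::vector<int> stack;
    int nb[6], nnb;
    int next = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (!mask[i] || labels[i] != 0) continue;
        ++next;
        labels[i] = next;
        stack.push_back((int)i);
        while (!stack.empty()) {
            int v = stack.back();
            stack.pop_back();
            neighbors6(v, nx, ny, nz, nb, nnb);
            for (int k = 0; k < nnb; ++k) {
                int u = nb[k];
                if (mask[u] && labels[u] == 0) {
                    labels[u] = next;
                    stack.push_back(u);
                }
            }
        }
    }
    labels.attr("dim") = dims;
    return labels;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher lower envelope).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
    const double INF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        double s;
        while (true) {
            s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
            if (s <= z[k]) { --k; } else break;
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        double dq = q - (double)v[k];
        d[q] = dq * dq + f[v[k]];
    }
}

// Squared Euclidean distance from each foreground voxel to the nearest
// background voxel; 0 on background. Exact, separable; per-axis weights
// express anisotropic voxel spacing (all 1 = plain voxel units).
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector fg, IntegerVector dims, NumericVector w) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    const double INF = 1e15;
    NumericVector D(n);
    for (R_xlen_t i = 0; i < n; ++i) D[i] = fg[i] ? INF : 0.0;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // weighted pass along an axis: D_new(q) = min_v ((q-v)^2 w^2 + D_old(v)),
    // realized by rescaling the parabola inputs by w^2
    double wx2 = w[0] * w[0], wy2 = w[1] * w[1], wz2 = w[2] * w[2];
    // x pass
    for (int zz = 0; zz < nz; ++zz)
        for (int y = 0; y < ny; ++y) {
            R_xlen_t base = (R_xlen_t)zz * nx * ny + (R_xlen_t)y * nx;
            for (int x = 0; x < nx; ++x) f[x] = D[base + x] / wx2;
            dt1d(f, d, v, z, nx);
            for (int x = 0; x < nx; ++x) D[base + x] = d[x] * wx2;
        }
    // y pass
    for (int zz = 0; zz < nz; ++zz)
        for (int x = 0; x < nx; ++x) {
            R_xlen_t base = (R_xlen_t)zz * nx * ny + x;
            for (int y = 0; y < ny; ++y) f[y] = D[base + (R_xlen_t)y * nx] / wy2;
            dt1d(f, d, v, z, ny);
            for (int y = 0; y < ny; ++y) D[base + (R_xlen_t)y * nx] = d[y] * wy2;
        }
    // z pass
    for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
            R_xlen_t base = (R_xlen_t)y * nx + x;
            for (int zz = 0; zz < nz; ++zz) f[zz] = D[base + (R_xlen_t)zz * nx * ny] / wz2;
            dt1d(f, d, v, z, nz);
            for (int zz = 0; zz < nz; ++zz) D[base + (R_xlen_t)zz * nx * ny] = d[zz] * wz2;
        }
    D.attr("dim") = dims;
    return D;
}

// Greyscale geodesic reconstruction by dilation under 6-connectivity:
// largest image <= ceiling whose value at each voxel is reached by repeated
// 6-neighbor dilation from marker. Alternating raster sweeps to convergence.
// [[Rcpp::export(name = ".reconstruct_dilate6")]]
NumericVector reconstruct_dilate6(NumericVector marker, NumericVector ceiling_img,
                                  IntegerVector dims) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector R_(clone(marker));
    for (R_xlen_t i = 0; i < n; ++i)
        if (R_[i] > ceiling_img[i]) R_[i] = ceiling_img[i];

    bool changed = true;
    int iter = 0;
    while (changed && iter < 10000) {
        changed = false;
        ++iter;
        // forward sweep: causal neighbors x-1, y-1, z-1
        for (R_xlen_t i = 0; i < n; ++i) {
            int x = (int)(i % nx), y = (int)((i / nx) % ny), zz = (int)(i / ((R_xlen_t)nx * ny));
            double m = R_[i];
            if (x > 0 && R_[i - 1] > m) m = R_[i - 1];
            if (y > 0 && R_[i - nx] > m) m = R_[i - nx];
            if (zz > 0 && R_[i - (R_xlen_t)nx * ny] > m) m = R_[i - (R_xlen_t)nx * ny];
            if (m > ceiling_img[i]) m = ceiling_img[i];
            if (m > R_[i]) { R_[i] = m; changed = true; }
        }
        // backward sweep: anti-causal neighbors x+1, y+1, z+1
        for (R_xlen_t i = n - 1; i >= 0; --i) {
            int x = (int)(i % nx), y = (int)((i / nx) % ny), zz = (int)(i / ((R_xlen_t)nx * ny));
            double m = R_[i];
            if (x < nx - 1 && R_[i + 1] > m) m = R_[i + 1];
            if (y < ny - 1 && R_[i + nx] > m) m = R_[i + nx];
            if (zz < nz - 1 && R_[i + (R_xlen_t)nx * ny] > m) m = R_[i + (R_xlen_t)nx * ny];
            if (m > ceiling_img[i]) m = ceiling_img[i];
            if (m > R_[i]) { R_[i] = m; changed = true; }
            if (i == 0) break;
        }
    }
    R_.attr("dim") = dims;
    return R_;
}

struct WsEntry {
    double prio;
    long order;
    int idx;
    int label;
};
struct WsCompare {
    bool operator()(const WsEntry& a, const WsEntry& b) const {
        if (a.prio != b.prio) return a.prio < b.prio;  // max-heap on priority
        return a.order > b.order;                      // FIFO on ties
    }
};

// Seeded watershed by priority flooding (Meyer), 6-connectivity, restricted
// to mask. Voxels whose already-labeled neighbors disagree at assignment time
// become ridge voxels and stay 0 in the output.
// [[Rcpp::export(name = ".watershed_seeded")]]
IntegerVector watershed_seeded(NumericVector prio, IntegerVector seeds,
                               LogicalVector mask, IntegerVector dims) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    const int RIDGE = -1;
    IntegerVector labels(n, 0);
    std::priority_queue<WsEntry, std::vector<WsEntry>, WsCompare> pq;
    long order = 0;
    int nb[6], nnb;

    for (R_xlen_t i = 0; i < n; ++i)
        if (seeds[i] > 0 && mask[i]) labels[i] = seeds[i];
    for (R_xlen_t i = 0; i < n; ++i) {
        if (labels[i] <= 0) continue;
        neighbors6((int)i, nx, ny, nz, nb, nnb);
        for (int k = 0; k < nnb; ++k) {
            int u = nb[k];
            if (mask[u] && labels[u] == 0)
                pq.push(WsEntry{prio[u], order++, u, labels[i]});
        }
    }
    while (!pq.empty()) {
        WsEntry e = pq.top();
        pq.pop();
        if (labels[e.idx] != 0) continue;
        neighbors6(e.idx, nx, ny, nz, nb, nnb);
        bool conflict = false;
        for (int k = 0; k < nnb; ++k) {
            int lu = labels[nb[k]];
            if (lu > 0 && lu != e.label) { conflict = true; break; }
        }
        if (conflict) {
            labels[e.idx] = RIDGE;
            continue;
        }
        labels[e.idx] = e.label;
        for (int k = 0; k < nnb; ++k) {
            int u = nb[k];
            if (mask[u] && labels[u] == 0)
                pq.push(WsEntry{prio[u], order++, u, e.label});
        }
    }
    for (R_xlen_t i = 0; i < n; ++i)
        if (labels[i] == RIDGE) labels[i] = 0;
    labels.attr("dim") = dims;
    return labels;
}

// One round of 6-connected label dilation. Unlabeled voxels adjacent to at
// least one labeled voxel take a label; when several labels compete, the
// neighbor with the largest priority value wins, exact priority ties go to
// the first neighbor in the fixed scan order (-x,+x,-y,+y,-z,+z), which is
// label-independent and hence equivariant under label permutation.
// [[Rcpp::export(name = ".dilate_labels_once")]]
IntegerVector dilate_labels_once(IntegerVector labels, NumericVector prio,
                                 IntegerVector dims) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    R_xlen_t n = (R_xlen_t)nx * ny * nz;
    IntegerVector out(clone(labels));
    int nb[6], nnb;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (labels[i] != 0) continue;
        int best = 0;
        double bestp = -1.0;
        neighbors6((int)i, nx, ny, nz, nb, nnb);
        for (int k = 0; k < nnb; ++k) {
            int lu = labels[nb[k]];
            if (lu <= 0) continue;
            double pu = prio[nb[k]];
            if (best == 0 || pu > bestp) {
                best = lu;
                bestp = pu;
            }
        }
        if (best > 0) out[i] = best;
    }
    out.attr("dim") = dims;
    return out;
}
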