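#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 3D binary voxel operations on (z, y, x) arrays stored in R's column-major
// order, i.e. linear index = z + nz*(y + ny*x). All connectivity is
// 6-connected (face neighbours), matching the closed-shell invariants used
// by the segmentation module.

static inline int idx3(int z, int y, int x, int nz, int ny) {
    return z + nz * (y + ny * x);
}

// Label 6-connected foreground components; return the largest as a logical
// mask plus bookkeeping (component count, voxel count, border contact).
// [[Rcpp::export(name = ".cc_largest")]]
List cc_largest(LogicalVector mask, IntegerVector dims) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    if (mask.size() != n) stop("mask length does not match dims");
    std::vector<int> label(n, 0);
    std::vector<int> stack;
    int ncomp = 0, best = 0, best_size = 0;
    std::vector<int> sizes(1, 0);
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!mask[s] || label[s]) continue;
        ++ncomp;
        sizes.push_back(0);
        stack.clear();
        stack.push_back((int)s);
        label[s] = ncomp;
        while (!stack.empty()) {
            int v = stack.back(); stack.pop_back();
            ++sizes[ncomp];
            int z = v % nz, rest = v / nz, y = rest % ny, x = rest / ny;
            const int dz[6] = {-1, 1, 0, 0, 0, 0};
            const int dy[6] = {0, 0, -1, 1, 0, 0};
            const int dx[6] = {0, 0, 0, 0, -1, 1};
            for (int k = 0; k < 6; ++k) {
                int z2 = z + dz[k], y2 = y + dy[k], x2 = x + dx[k];
                if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny ||
                    x2 < 0 || x2 >= nx) continue;
                int w = idx3(z2, y2, x2, nz, ny);
                if (mask[w] && !label[w]) {
                    label[w] = ncomp;
                    stack.push_back(w);
                }
            }
        }
        if (sizes[ncomp] > best_size) { best_size = sizes[ncomp]; best = ncomp; }
    }
    LogicalVector out(n);
    bool border = false;
    for (R_xlen_t s = 0; s < n; ++s) {
        bool in = (label[s] == best) && best > 0;
        out[s] = in;
        if (in && !border) {
            int z = s % nz; R_xlen_t rest = s / nz;
            int y = rest % ny, x = rest / ny;
            if (z == 0 || z == nz - 1 || y == 0 || y == ny - 1 ||
                x == 0 || x == nx - 1) border = true;
        }
    }
    out.attr("dim") = dims;
    return List::create(_["mask"] = out, _["n_components"] = ncomp,
                        _["size"] = best_size, _["touches_border"] = border);
}

// Fill interior cavities: voxels not 6-connected to the array border through
// the background become foreground.
// [[Rcpp::export(name = ".fill_holes")]]
LogicalVector fill_holes(LogicalVector mask, IntegerVector dims) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    if (mask.size() != n) stop("mask length does not match dims");
    std::vector<uint8_t> outside(n, 0);
    std::vector<int> stack;
    // seed the flood from every background border voxel
    for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
            for (int z = 0; z < nz; ++z) {
                if (z != 0 && z != nz - 1 && y != 0 && y != ny - 1 &&
                    x != 0 && x != nx - 1) continue;
                int v = idx3(z, y, x, nz, ny);
                if (!mask[v] && !outside[v]) { outside[v] = 1; stack.push_back(v); }
            }
    while (!stack.empty()) {
        int v = stack.back(); stack.pop_back();
        int z = v % nz, rest = v / nz, y = rest % ny, x = rest / ny;
        const int dz[6] = {-1, 1, 0, 0, 0, 0};
        const int dy[6] = {0, 0, -1, 1, 0, 0};
        const int dx[6] = {0, 0, 0, 0, -1, 1};
        for (int k = 0; k < 6; ++k) {
            int z2 = z + dz[k], y2 = y + dy[k], x2 = x + dx[k];
            if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny ||
                x2 < 0 || x2 >= nx) continue;
            int w = idx3(z2, y2, x2, nz, ny);
            if (!mask[w] && !outside[w]) { outside[w] = 1; stack.push_back(w); }
        }
    }
    LogicalVector out(n);
    for (R_xlen_t s = 0; s < n; ++s) out[s] = mask[s] || !outside[s];
    out.attr("dim") = dims;
    return out;
}

static LogicalVector morph6(LogicalVector mask, IntegerVector dims,
                            int iter, bool dilate) {
    const int nz = dims[0], ny = dims[1], nx = dims[2];
    const R_xlen_t n = (R_xlen_t)nz * ny * nx;
    std::vector<uint8_t> a(n), b(n);
    for (R_xlen_t s = 0; s < n; ++s) a[s] = mask[s] ? 1 : 0;
    for (int it = 0; it < iter; ++it) {
        for (int x = 0; x < nx; ++x)
            for (int y = 0; y < ny; ++y)
                for (int z = 0; z < nz; ++z) {
                    int v = idx3(z, y, x, nz, ny);
                    uint8_t acc = a[v];
                    const int dz[6] = {-1, 1, 0, 0, 0, 0};
                    const int dy[6] = {0, 0, -1, 1, 0, 0};
                    const int dx[6] = {0, 0, 0, 0, -1, 1};
                    for (int k = 0; k < 6 && (dilate ? !acc : acc); ++k) {
                        int z2 = z + dz[k], y2 = y + dy[k], x2 = x + dx[k];
                        uint8_t nb;
                        if (z2 < 0 || z2 >= nz || y2 < 0 || y2 >= ny ||
                            x2 < 0 || x2 >= nx)
                            nb = 0;  // outside counts as background
                        else
                            nb = a[idx3(z2, y2, x2, nz, ny)];
                        if (dilate) acc = acc || nb; else acc = acc && nb;
                    }
                    b[v] = acc;
                }
        std::swap(a, b);
    }
    LogicalVector out(n);
    for (R_xlen_t s = 0; s < n; ++s) out[s] = a[s] != 0;
    out.attr("dim") = dims;
    return out;
}

// Morphological closing (dilation then erosion) with a 6-connected cross
// structuring element applied `iter` times each way.
// [[Rcpp::export(name = ".close6")]]
LogicalVector close6(LogicalVector mask, IntegerVector dims, int iter) {
    if (iter <= 0) { mask.attr("dim") = dims; return mask; }
    LogicalVector d = morph6(mask, dims, iter, true);
    return morph6(d, dims, iter, false);
}
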