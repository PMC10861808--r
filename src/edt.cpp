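#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// 1D squared Euclidean distance transform of a sampled function
// (Felzenszwalb & Huttenlocher), sample spacing w (mm).
// f: input values (INF where no site), d: output, n: length.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w) {
    const double INF = std::numeric_limits<double>::infinity();
    const double w2 = w * w;
    int k = -1;
    // build the lower envelope over finite parabolas only; rows with no
    // finite entry (no site reachable yet) stay infinite
    for (int q = 0; q < n; ++q) {
        if (f[q] == INF) continue;
        double s = -INF;
        while (k >= 0) {
            int p = v[k];
            // intersection of parabolas rooted at p and q (mm units)
            s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) /
                (2.0 * w2 * (q - p));
            if (s <= z[k]) { --k; } else break;
        }
        ++k;
        v[k] = q;
        z[k] = (k == 0) ? -INF : s;
        z[k + 1] = INF;
    }
    if (k < 0) {
        for (int q = 0; q < n; ++q) d[q] = INF;
        return;
    }
    // z boundaries are in grid-index units (the w^2 factors cancel)
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        int p = v[k];
        double dq = w * (q - p);
        d[q] = dq * dq + f[p];
    }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest
// foreground voxel centre of a 3D mask, honouring per-axis spacing.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(IntegerVector mask, IntegerVector dims,
                         NumericVector spacing) {
    const double INF = std::numeric_limits<double>::infinity();
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    if (mask.size() != n) stop("mask length does not match dims");

    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x (fastest-varying)
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
            for (int i = 0; i < nx; ++i) f[i] = out[base + i];
            dt1d(f, d, v, z, nx, spacing[0]);
            for (int i = 0; i < nx; ++i) out[base + i] = d[i];
        }
    // pass along y
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + i;
            for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
            dt1d(f, d, v, z, ny, spacing[1]);
            for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
        }
    // pass along z
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)j * nx + i;
            for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nx * ny];
            dt1d(f, d, v, z, nz, spacing[2]);
            for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nx * ny] = d[k];
        }
    return out;
}
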