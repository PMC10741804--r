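#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared Euclidean distance transform of a sampled function
// (Felzenszwalb & Huttenlocher, lower envelope of parabolas).
// f[i] is the squared distance so far at sample i; samples sit at i * w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double w, std::vector<int>& v, std::vector<double>& z) {
    const int n = (int)f.size();
    const double INF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    const double w2 = w * w;
    for (int q = 1; q < n; ++q) {
        if (f[q] == INF) continue;
        double s;
        while (true) {
            if (f[v[k]] == INF) { s = -INF; }
            else {
                // intersection abscissa (mm) of parabolas at q*w and v[k]*w
                s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
                    (2.0 * w * (q - v[k]));
            }
            if (s <= z[k]) {
                --k;
                if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; s = INF; break; }
            } else break;
        }
        if (s == INF) continue;   // q became the sole parabola
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < w * q) ++k;
        double dq = w * (q - v[k]);
        d[q] = dq * dq + f[v[k]];
    }
}

// Exact anisotropic squared Euclidean distance transform on a 3D grid.
// Returns, for every voxel, the squared distance in mm^2 from its center to
// the nearest center of a TRUE voxel (Inf if the mask is empty).
// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    const double INF = std::numeric_limits<double>::infinity();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // pass along x
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
            bool any = false;
            for (int i = 0; i < nx; ++i) { f[i] = out[base + i]; if (f[i] < INF) any = true; }
            if (!any) continue;
            f.resize(nx); d.resize(nx);
            dt1d(f, d, spacing[0], v, z);
            for (int i = 0; i < nx; ++i) out[base + i] = d[i];
            f.resize(nmax); d.resize(nmax);
        }
    // pass along y
    for (int k = 0; k < nz; ++k)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)k * nx * ny + i;
            bool any = false;
            for (int j = 0; j < ny; ++j) { f[j] = out[base + (R_xlen_t)j * nx]; if (f[j] < INF) any = true; }
            if (!any) continue;
            f.resize(ny); d.resize(ny);
            dt1d(f, d, spacing[1], v, z);
            for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
            f.resize(nmax); d.resize(nmax);
        }
    // pass along z
    for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
            R_xlen_t base = (R_xlen_t)j * nx + i;
            bool any = false;
            for (int k = 0; k < nz; ++k) { f[k] = out[base + (R_xlen_t)k * nx * ny]; if (f[k] < INF) any = true; }
            if (!any) continue;
            f.resize(nz); d.resize(nz);
            dt1d(f, d, spacing[2], v, z);
            for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nx * ny] = d[k];
            f.resize(nmax); d.resize(nmax);
        }
    out.attr("dim") = dims;
    return out;
}
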