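#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Mirror (reflect about edge samples) index into [0, n-1]; period 2(n-1).
static inline int mirror_index(int i, int n) {
    if (n == 1) return 0;
    const int period = 2 * (n - 1);
    i = std::abs(i) % period;
    if (i >= n) i = period - i;
    return i;
}

// Cubic B-spline evaluation at one (possibly out-of-grid) voxel coordinate.
static inline double cubic_at(const double *c, int nx, int ny, int nz,
                              double x, double y, double z, bool *ok) {
    if (!(x >= 0.0 && x <= nx - 1 && y >= 0.0 && y <= ny - 1 &&
          z >= 0.0 && z <= nz - 1)) {
        *ok = false;
        return 0.0;
    }
    *ok = true;
    int ix = (int)std::floor(x), iy = (int)std::floor(y),
        iz = (int)std::floor(z);
    if (ix > nx - 2) ix = nx - 2;
    if (iy > ny - 2) iy = ny - 2;
    if (iz > nz - 2) iz = nz - 2;
    const double tx = x - ix, ty = y - iy, tz = z - iz;
    double wx[4], wy[4], wz[4];
    {
        const double t = tx, u = 1.0 - t;
        wx[0] = u * u * u / 6.0;
        wx[1] = (4.0 - 6.0 * t * t + 3.0 * t * t * t) / 6.0;
        wx[2] = (1.0 + 3.0 * t + 3.0 * t * t - 3.0 * t * t * t) / 6.0;
        wx[3] = t * t * t / 6.0;
    }
    {
        const double t = ty, u = 1.0 - t;
        wy[0] = u * u * u / 6.0;
        wy[1] = (4.0 - 6.0 * t * t + 3.0 * t * t * t) / 6.0;
        wy[2] = (1.0 + 3.0 * t + 3.0 * t * t - 3.0 * t * t * t) / 6.0;
        wy[3] = t * t * t / 6.0;
    }
    {
        const double t = tz, u = 1.0 - t;
        wz[0] = u * u * u / 6.0;
        wz[1] = (4.0 - 6.0 * t * t + 3.0 * t * t * t) / 6.0;
        wz[2] = (1.0 + 3.0 * t + 3.0 * t * t - 3.0 * t * t * t) / 6.0;
        wz[3] = t * t * t / 6.0;
    }
    int jx[4], jy[4], jz[4];
    for (int k = 0; k < 4; ++k) {
        jx[k] = mirror_index(ix - 1 + k, nx);
        jy[k] = mirror_index(iy - 1 + k, ny);
        jz[k] = mirror_index(iz - 1 + k, nz);
    }
    const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
    double acc = 0.0;
    for (int kz = 0; kz < 4; ++kz) {
        const R_xlen_t oz = (R_xlen_t)jz[kz] * sz;
        double accz = 0.0;
        for (int ky = 0; ky < 4; ++ky) {
            const R_xlen_t oy = oz + (R_xlen_t)jy[ky] * sy;
            double accy = 0.0;
            for (int kx = 0; kx < 4; ++kx)
                accy += wx[kx] * c[oy + jx[kx]];
            accz += wy[ky] * accy;
        }
        acc += wz[kz] * accz;
    }
    return acc;
}

// Weighted Pearson CC between template values and map density sampled at a
// rigid pose of the template grid (rotation column-major 3x3, translation
// in Angstrom); out-of-map points count as zero density.
// [[Rcpp::export]]
double pose_cc_cpp(NumericVector coef, NumericVector origin,
                   NumericVector voxel, NumericMatrix pts,
                   NumericVector tmean, NumericVector w,
                   NumericVector rot, NumericVector trans) {
    IntegerVector dim = coef.attr("dim");
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const double *c = coef.begin();
    const int n = pts.nrow();
    const double r11 = rot[0], r21 = rot[1], r31 = rot[2];
    const double r12 = rot[3], r22 = rot[4], r32 = rot[5];
    const double r13 = rot[6], r23 = rot[7], r33 = rot[8];
    double sw = 0, swx = 0, swy = 0, swxx = 0, swyy = 0, swxy = 0;
    for (int i = 0; i < n; ++i) {
        const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
        const double gx = r11 * px + r12 * py + r13 * pz + trans[0];
        const double gy = r21 * px + r22 * py + r23 * pz + trans[1];
        const double gz = r31 * px + r32 * py + r33 * pz + trans[2];
        bool ok;
        const double x = cubic_at(c, nx, ny, nz,
                                  (gx - origin[0]) / voxel[0],
                                  (gy - origin[1]) / voxel[1],
                                  (gz - origin[2]) / voxel[2], &ok);
        const double y = tmean[i], wi = w[i];
        sw += wi;
        swx += wi * x; swy += wi * y;
        swxx += wi * x * x; swyy += wi * y * y; swxy += wi * x * y;
    }
    if (sw <= 0) return 0.0;
    const double mx = swx / sw, my = swy / sw;
    const double vx = swxx / sw - mx * mx, vy = swyy / sw - my * my;
    if (vx <= 0 || vy <= 0) return 0.0;
    return (swxy / sw - mx * my) / std::sqrt(vx * vy);
}

// Evaluate a separable cubic B-spline interpolant at arbitrary points.
// `coef`: prefiltered B-spline coefficient array (dim attribute set),
// `pts`: m x 3 matrix of 0-based voxel coordinates. Points outside the
// grid hull [0, n-1] on any axis yield NA (the caller's "no density"
// sentinel); interior stencils that poke past the edge use the same
// mirror convention as the prefilter.
// [[Rcpp::export]]
NumericVector interp_cubic_cpp(NumericVector coef, NumericMatrix pts) {
    IntegerVector dim = coef.attr("dim");
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int m = pts.nrow();
    NumericVector out(m);
    const double *c = coef.begin();
    const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;

    for (int p = 0; p < m; ++p) {
        const double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
        if (!(x >= 0.0 && x <= nx - 1 && y >= 0.0 && y <= ny - 1 &&
              z >= 0.0 && z <= nz - 1)) {
            out[p] = NA_REAL;
            continue;
        }
        int ix = (int)std::floor(x), iy = (int)std::floor(y),
            iz = (int)std::floor(z);
        if (ix > nx - 2) ix = nx - 2;
        if (iy > ny - 2) iy = ny - 2;
        if (iz > nz - 2) iz = nz - 2;
        const double tx = x - ix, ty = y - iy, tz = z - iz;

        double wx[4], wy[4], wz[4];
        {
            const double t = tx, u = 1.0 - t;
            wx[0] = u * u * u / 6.0;
            wx[1] = (4.0 - 6.0 * t * t + 3.0 * t * t * t) / 6.0;
            wx[2] = (1.0 + 3.0 * t + 3.0 * t * t - 3.0 * t * t * t) / 6.0;
            wx[3] = t * t * t / 6.0;
        }
        {
            const double t = ty, u = 1.0 - t;
            wy[0] = u * u * u / 6.0;
            wy[1] = (4.0 - 6.0 * t * t + 3.0 * t * t * t) / 6.0;
            wy[2] = (1.0 + 3.0 * t + 3.0 * t * t - 3.0 * t * t * t) / 6.0;
            wy[3] = t * t * t / 6.0;
        }
        {
            const double t = tz, u = 1.0 - t;
            wz[0] = u * u * u / 6.0;
            wz[1] = (4.0 - 6.0 * t * t + 3.0 * t * t * t) / 6.0;
            wz[2] = (1.0 + 3.0 * t + 3.0 * t * t - 3.0 * t * t * t) / 6.0;
            wz[3] = t * t * t / 6.0;
        }

        int jx[4], jy[4], jz[4];
        for (int k = 0; k < 4; ++k) {
            jx[k] = mirror_index(ix - 1 + k, nx);
            jy[k] = mirror_index(iy - 1 + k, ny);
            jz[k] = mirror_index(iz - 1 + k, nz);
        }

        double acc = 0.0;
        for (int kz = 0; kz < 4; ++kz) {
            const R_xlen_t oz = (R_xlen_t)jz[kz] * sz;
            double accz = 0.0;
            for (int ky = 0; ky < 4; ++ky) {
                const R_xlen_t oy = oz + (R_xlen_t)jy[ky] * sy;
                double accy = 0.0;
                for (int kx = 0; kx < 4; ++kx)
                    accy += wx[kx] * c[oy + jx[kx] * sx];
                accz += wy[ky] * accy;
            }
            acc += wz[kz] * accz;
        }
        out[p] = acc;
    }
    return out;
}

// Trilinear interpolation; NA outside the grid hull.
// [[Rcpp::export]]
NumericVector interp_linear_cpp(NumericVector data, NumericMatrix pts) {
    IntegerVector dim = data.attr("dim");
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int m = pts.nrow();
    NumericVector out(m);
    const double *d = data.begin();
    const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;

    for (int p = 0; p < m; ++p) {
        const double x = pts(p, 0), y = pts(p, 1), z = pts(p, 2);
        if (!(x >= 0.0 && x <= nx - 1 && y >= 0.0 && y <= ny - 1 &&
              z >= 0.0 && z <= nz - 1)) {
            out[p] = NA_REAL;
            continue;
        }
        int ix = (int)std::floor(x), iy = (int)std::floor(y),
            iz = (int)std::floor(z);
        if (ix > nx - 2) ix = nx - 2;
        if (iy > ny - 2) iy = ny - 2;
        if (iz > nz - 2) iz = nz - 2;
        const double tx = x - ix, ty = y - iy, tz = z - iz;
        const R_xlen_t o = ix + iy * sy + iz * sz;
        const double c000 = d[o], c100 = d[o + 1];
        const double c010 = d[o + sy], c110 = d[o + sy + 1];
        const double c001 = d[o + sz], c101 = d[o + sz + 1];
        const double c011 = d[o + sy + sz], c111 = d[o + sy + sz + 1];
        const double c00 = c000 * (1 - tx) + c100 * tx;
        const double c10 = c010 * (1 - tx) + c110 * tx;
        const double c01 = c001 * (1 - tx) + c101 * tx;
        const double c11 = c011 * (1 - tx) + c111 * tx;
        const double c0 = c00 * (1 - ty) + c10 * ty;
        const double c1 = c01 * (1 - ty) + c11 * ty;
        out[p] = c0 * (1 - tz) + c1 * tz;
    }
    return out;
}

// Coarse template pre-screen: for every candidate centre, score every
// probe-point orientation (mean trilinear map value over the probe set,
// out-of-grid probes contributing zero) and keep the best orientation.
// `probes` is a list of nprobe x 3 matrices of voxel-unit offsets (one per
// orientation); `centers` is ncenter x 3 in 0-based voxel coordinates.
// Returns ncenter x 2: best score, best orientation (1-based).
// [[Rcpp::export]]
NumericMatrix fast_search_cpp(NumericVector data, List probes,
                              NumericMatrix centers) {
    IntegerVector dim = data.attr("dim");
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const double *d = data.begin();
    const R_xlen_t sy = nx, sz = (R_xlen_t)nx * ny;
    const int nc = centers.nrow();
    const int no = probes.size();

    std::vector<NumericMatrix> pm(no);
    for (int i = 0; i < no; ++i) pm[i] = as<NumericMatrix>(probes[i]);

    NumericMatrix out(nc, 2);
    for (int ic = 0; ic < nc; ++ic) {
        const double cx = centers(ic, 0), cy = centers(ic, 1),
                     cz = centers(ic, 2);
        double best = -1e300;
        int besto = 0;
        for (int io = 0; io < no; ++io) {
            const NumericMatrix &P = pm[io];
            const int np = P.nrow();
            double acc = 0.0;
            for (int ip = 0; ip < np; ++ip) {
                const double x = cx + P(ip, 0), y = cy + P(ip, 1),
                             z = cz + P(ip, 2);
                if (!(x >= 0.0 && x <= nx - 1 && y >= 0.0 && y <= ny - 1 &&
                      z >= 0.0 && z <= nz - 1))
                    continue;
                int ix = (int)x, iy = (int)y, iz = (int)z;
                if (ix > nx - 2) ix = nx - 2;
                if (iy > ny - 2) iy = ny - 2;
                if (iz > nz - 2) iz = nz - 2;
                const double tx = x - ix, ty = y - iy, tz = z - iz;
                const R_xlen_t o = ix + iy * sy + iz * sz;
                const double c00 = d[o] * (1 - tx) + d[o + 1] * tx;
                const double c10 = d[o + sy] * (1 - tx) + d[o + sy + 1] * tx;
                const double c01 = d[o + sz] * (1 - tx) + d[o + sz + 1] * tx;
                const double c11 =
                    d[o + sy + sz] * (1 - tx) + d[o + sy + sz + 1] * tx;
                const double c0 = c00 * (1 - ty) + c10 * ty;
                const double c1 = c01 * (1 - ty) + c11 * ty;
                acc += c0 * (1 - tz) + c1 * tz;
            }
            acc /= np;
            if (acc > best) {
                best = acc;
                besto = io + 1;
            }
        }
        out(ic, 0) = best;
        out(ic, 1) = besto;
    }
    return out;
}
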