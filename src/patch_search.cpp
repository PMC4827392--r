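#include <Rcpp.h>
using namespace Rcpp;

// Nearest-patch cross-modality synthesis.
//
// For every masked voxel v of each query volume, scans all atlases (and
// offsets within search_radius) for the x-patch minimising the L2 distance
// to the query's x-patch around v, then copies the winning atlas's
// y-intensity at the matched centre (or the mean of its y-patch).
//
// The comparison window is the query's patch window clamped to the grid;
// atlas coordinates (window voxel + search offset) are clamped likewise, so
// no out-of-grid values are invented. Ties are broken by lowest atlas index,
// then lexicographic (dx, dy, dz) offset: the scan visits candidates in that
// order and only a strictly smaller distance replaces the incumbent.
//
// Volumes are passed as full-grid vectors in column-major order (x fastest).
// exclude is a per-query 1-based atlas index to skip (0 = none), used for
// leave-one-out schemes.

// [[Rcpp::export]]
List patch_search_cpp(NumericMatrix atlas_x, NumericMatrix atlas_y,
                      NumericMatrix query_x, IntegerVector dims,
                      LogicalVector mask, int patch_side, int search_radius,
                      bool aggregate_mean, IntegerVector exclude) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int A = atlas_x.nrow(), Q = query_x.nrow(), V = nx * ny * nz;
  const int hp = patch_side / 2, sr = search_radius;
  NumericMatrix yhat(Q, V);
  IntegerMatrix winner(Q, V);
  std::fill(winner.begin(), winner.end(), NA_INTEGER);

  auto clampi = [](int v, int lo, int hi) { return v < lo ? lo : (v > hi ? hi : v); };

  for (int q = 0; q < Q; ++q) {
    const int excl = exclude[q] - 1;  // -1 when nothing excluded
    for (int vz = 0; vz < nz; ++vz)
      for (int vy = 0; vy < ny; ++vy)
        for (int vx = 0; vx < nx; ++vx) {
          const int v = vx + nx * (vy + ny * vz);
          if (!mask[v]) continue;
          const int x0 = std::max(0, vx - hp), x1 = std::min(nx - 1, vx + hp);
          const int y0 = std::max(0, vy - hp), y1 = std::min(ny - 1, vy + hp);
          const int z0 = std::max(0, vz - hp), z1 = std::min(nz - 1, vz + hp);
          double best = R_PosInf;
          int besta = -1, bdx = 0, bdy = 0, bdz = 0;
          for (int a = 0; a < A; ++a) {
            if (a == excl) continue;
            for (int dx = -sr; dx <= sr; ++dx)
              for (int dy = -sr; dy <= sr; ++dy)
                for (int dz = -sr; dz <= sr; ++dz) {
                  double d2 = 0.0;
                  for (int pz = z0; pz <= z1 && d2 < best; ++pz) {
                    const int az = clampi(pz + dz, 0, nz - 1);
                    for (int py = y0; py <= y1; ++py) {
                      const int ay = clampi(py + dy, 0, ny - 1);
                      const int qbase = nx * (py + ny * pz);
                      const int abase = nx * (ay + ny * az);
                      for (int px = x0; px <= x1; ++px) {
                        const int ax = clampi(px + dx, 0, nx - 1);
                        const double diff = query_x(q, px + qbase) - atlas_x(a, ax + abase);
                        d2 += diff * diff;
                      }
                    }
                  }
                  if (d2 < best) {
                    best = d2; besta = a; bdx = dx; bdy = dy; bdz = dz;
                  }
                }
          }
          if (besta < 0) stop("empty patch database");
          if (aggregate_mean) {
            double s = 0.0; int n = 0;
            for (int pz = z0; pz <= z1; ++pz) {
              const int az = clampi(pz + bdz, 0, nz - 1);
              for (int py = y0; py <= y1; ++py) {
                const int ay = clampi(py + bdy, 0, ny - 1);
                for (int px = x0; px <= x1; ++px) {
                  const int ax = clampi(px + bdx, 0, nx - 1);
                  s += atlas_y(besta, ax + nx * (ay + ny * az));
                  ++n;
                }
              }
            }
            yhat(q, v) = s / n;
          } else {
            const int cx = clampi(vx + bdx, 0, nx - 1);
            const int cy = clampi(vy + bdy, 0, ny - 1);
            const int cz = clampi(vz + bdz, 0, nz - 1);
            yhat(q, v) = atlas_y(besta, cx + nx * (cy + ny * cz));
          }
          winner(q, v) = besta + 1;
        }
  }
  return List::create(_["yhat"] = yhat, _["winner"] = winner);
}
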