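// Native kernels: DRR ray integration, im2col-style conv support for the
// network core, exact Euclidean distance transform, tetrahedral isosurface
// extraction, and point-to-mesh closest distances.
#include <RcppArmadillo.h>
#include <map>
#include <utility>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double trilinear(const arma::cube &v, double x, double y, double z) {
  // x,y,z in 0-based voxel-index coordinates; outside treated as 0
  const int nx = v.n_rows, ny = v.n_cols, nz = v.n_slices;
  if (x <= -1.0 || y <= -1.0 || z <= -1.0 || x >= nx || y >= ny || z >= nz) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double out = 0.0;
  for (int dz = 0; dz <= 1; ++dz) for (int dy = 0; dy <= 1; ++dy) for (int dx = 0; dx <= 1; ++dx) {
    int xi = x0 + dx, yi = y0 + dy, zi = z0 + dz;
    if (xi < 0 || yi < 0 || zi < 0 || xi >= nx || yi >= ny || zi >= nz) continue;
    double w = (dx ? fx : 1.0 - fx) * (dy ? fy : 1.0 - fy) * (dz ? fz : 1.0 - fz);
    out += w * v(xi, yi, zi);
  }
  return out;
}

// Line-integral DRR. view: 0 = frontal (rays along -Y), 1 = sagittal (rays
// along -X). mode: 0 parallel, 1 horizontal fan with vertically moving source.
// Detector u axis: X (frontal) or Y (sagittal); v axis: -Z (top-down).
// [[Rcpp::export]]
NumericMatrix drr_project_cpp(const arma::cube &vol, NumericVector spacing,
                              NumericVector origin, int view, int mode,
                              int nu, int nv, double su, double sv,
                              double det_cu, double det_cv, double iso_r,
                              double sad, double add, double step) {
  NumericMatrix img(nv, nu); // rows = v, cols = u
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // ray-axis world extent of the volume (with half-voxel margins)
  double rmin, rmax;
  if (view == 0) { rmin = oy - sy; rmax = oy + (vol.n_cols) * sy; }
  else           { rmin = ox - sx; rmax = ox + (vol.n_rows) * sx; }
  for (int iu = 0; iu < nu; ++iu) {
    double umm = det_cu + (iu - (nu - 1) / 2.0) * su;
    for (int iv = 0; iv < nv; ++iv) {
      double zmm = det_cv - (iv - (nv - 1) / 2.0) * sv;
      double acc = 0.0;
      if (mode == 0) {
        for (double t = rmin; t <= rmax; t += step) {
          double wx, wy;
          if (view == 0) { wx = umm; wy = t; } else { wx = t; wy = umm; }
          acc += trilinear(vol, (wx - ox) / sx, (wy - oy) / sy, (zmm - oz) / sz);
        }
      } else {
        // horizontal fan at height zmm: source on the central axis at
        // distance sad from the iso line, detector plane at distance add
        double s_r = iso_r + sad;      // source position along the ray axis
        double d_r = iso_r - add;      // detector plane along the ray axis
        double s_u = det_cu, d_u = umm;
        double len = std::sqrt((d_r - s_r) * (d_r - s_r) + (d_u - s_u) * (d_u - s_u));
        double dr = (d_r - s_r) / len, du = (d_u - s_u) / len;
        for (double t = 0.0; t <= len; t += step) {
          double pr = s_r + t * dr, pu = s_u + t * du;
          double wx, wy;
          if (view == 0) { wx = pu; wy = pr; } else { wx = pr; wy = pu; }
          acc += trilinear(vol, (wx - ox) / sx, (wy - oy) / sy, (zmm - oz) / sz);
        }
      }
      img(iv, iu) = acc * step;
    }
  }
  return img;
}

// ---- conv support: feature maps are (npix, C) matrices, pixel index
// column-major over the spatial dims (first dim fastest) ----

// [[Rcpp::export]]
arma::mat im2col2_cpp(const arma::mat &X, int H, int W) {
  const int C = X.n_cols;
  arma::mat out(H * W, 9 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dw = -1; dw <= 1; ++dw)
      for (int dh = -1; dh <= 1; ++dh) {
        int col = c * 9 + (dw + 1) * 3 + (dh + 1);
        for (int w = 0; w < W; ++w) {
          int ww = w + dw; if (ww < 0 || ww >= W) continue;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const double *src = X.colptr(c) + (h0 + dh) + H * ww;
          double *dst = out.colptr(col) + h0 + H * w;
          std::copy(src, src + (h1 - h0), dst);
        }
      }
  return out;
}

// [[Rcpp::export]]
arma::mat col2im2_cpp(const arma::mat &dcol, int H, int W, int C) {
  arma::mat dX(H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int dw = -1; dw <= 1; ++dw)
      for (int dh = -1; dh <= 1; ++dh) {
        int col = c * 9 + (dw + 1) * 3 + (dh + 1);
        for (int w = 0; w < W; ++w) {
          int ww = w + dw; if (ww < 0 || ww >= W) continue;
          int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
          const double *src = dcol.colptr(col) + h0 + H * w;
          double *dst = dX.colptr(c) + (h0 + dh) + H * ww;
          for (int i = 0; i < h1 - h0; ++i) dst[i] += src[i];
        }
      }
  return dX;
}

// [[Rcpp::export]]
arma::mat im2col3_cpp(const arma::mat &X, int D1, int D2, int D3) {
  const int C = X.n_cols, n12 = D1 * D2;
  arma::mat out(D1 * D2 * D3, 27 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int d3 = -1; d3 <= 1; ++d3)
      for (int d2 = -1; d2 <= 1; ++d2)
        for (int d1 = -1; d1 <= 1; ++d1) {
          int col = c * 27 + (d3 + 1) * 9 + (d2 + 1) * 3 + (d1 + 1);
          for (int k = 0; k < D3; ++k) {
            int kk = k + d3; if (kk < 0 || kk >= D3) continue;
            for (int j = 0; j < D2; ++j) {
              int jj = j + d2; if (jj < 0 || jj >= D2) continue;
              int i0 = std::max(0, -d1), i1 = std::min(D1, D1 - d1);
              const double *src = X.colptr(c) + (i0 + d1) + D1 * jj + n12 * kk;
              double *dst = out.colptr(col) + i0 + D1 * j + n12 * k;
              std::copy(src, src + (i1 - i0), dst);
            }
          }
        }
  return out;
}

// [[Rcpp::export]]
arma::mat col2im3_cpp(const arma::mat &dcol, int D1, int D2, int D3, int C) {
  const int n12 = D1 * D2;
  arma::mat dX(D1 * D2 * D3, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int d3 = -1; d3 <= 1; ++d3)
      for (int d2 = -1; d2 <= 1; ++d2)
        for (int d1 = -1; d1 <= 1; ++d1) {
          int col = c * 27 + (d3 + 1) * 9 + (d2 + 1) * 3 + (d1 + 1);
          for (int k = 0; k < D3; ++k) {
            int kk = k + d3; if (kk < 0 || kk >= D3) continue;
            for (int j = 0; j < D2; ++j) {
              int jj = j + d2; if (jj < 0 || jj >= D2) continue;
              int i0 = std::max(0, -d1), i1 = std::min(D1, D1 - d1);
              const double *src = dcol.colptr(col) + i0 + D1 * j + n12 * k;
              double *dst = dX.colptr(c) + (i0 + d1) + D1 * jj + n12 * kk;
              for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
            }
          }
        }
  return dX;
}

// shifted copy of a 3D feature-map matrix under neighbor offset (d1,d2,d3):
// out(p, c) = X(p + d1 + D1*d2 + D1*D2*d3, c) where in bounds, else 0
static void shift3(const arma::mat &X, int D1, int D2, int D3,
                   int d1, int d2, int d3, arma::mat &out) {
  out.zeros();
  const int C = X.n_cols, n12 = D1 * D2;
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < D3; ++k) {
      int kk = k + d3; if (kk < 0 || kk >= D3) continue;
      for (int j = 0; j < D2; ++j) {
        int jj = j + d2; if (jj < 0 || jj >= D2) continue;
        int i0 = std::max(0, -d1), i1 = std::min(D1, D1 - d1);
        const double *src = X.colptr(c) + (i0 + d1) + D1 * jj + n12 * kk;
        double *dst = out.colptr(c) + i0 + D1 * j + n12 * k;
        std::copy(src, src + (i1 - i0), dst);
      }
    }
  }
}
// scatter-add: dX(p + offset, c) += T(p, c)
static void scatter3(const arma::mat &T, int D1, int D2, int D3,
                     int d1, int d2, int d3, arma::mat &dX) {
  const int C = T.n_cols, n12 = D1 * D2;
  for (int c = 0; c < C; ++c) {
    for (int k = 0; k < D3; ++k) {
      int kk = k + d3; if (kk < 0 || kk >= D3) continue;
      for (int j = 0; j < D2; ++j) {
        int jj = j + d2; if (jj < 0 || jj >= D2) continue;
        int i0 = std::max(0, -d1), i1 = std::min(D1, D1 - d1);
        const double *src = T.colptr(c) + i0 + D1 * j + n12 * k;
        double *dst = dX.colptr(c) + (i0 + d1) + D1 * jj + n12 * kk;
        for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
      }
    }
  }
}
static arma::mat gather_w3(const arma::mat &W, int C, int o) {
  arma::mat Wo(C, W.n_cols);
  for (int c = 0; c < C; ++c) Wo.row(c) = W.row(c * 27 + o);
  return Wo;
}

// 3D same-padding 3x3x3 convolution: offset-grouped GEMM, avoids the large
// im2col matrix. W rows ordered c*27 + offset (same layout as im2col3).
// [[Rcpp::export]]
arma::mat conv3_fwd_cpp(const arma::mat &X, int D1, int D2, int D3,
                        const arma::mat &W, const arma::rowvec &b) {
  const int C = X.n_cols;
  arma::mat Y(X.n_rows, W.n_cols, arma::fill::zeros);
  arma::mat buf(X.n_rows, C);
  for (int d3 = -1; d3 <= 1; ++d3)
    for (int d2 = -1; d2 <= 1; ++d2)
      for (int d1 = -1; d1 <= 1; ++d1) {
        int o = (d3 + 1) * 9 + (d2 + 1) * 3 + (d1 + 1);
        shift3(X, D1, D2, D3, d1, d2, d3, buf);
        Y += buf * gather_w3(W, C, o);
      }
  Y.each_row() += b;
  return Y;
}

// [[Rcpp::export]]
List conv3_bwd_cpp(const arma::mat &dZ, const arma::mat &X,
                   int D1, int D2, int D3, const arma::mat &W) {
  const int C = X.n_cols;
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::mat dX(X.n_rows, C, arma::fill::zeros);
  arma::mat buf(X.n_rows, C);
  for (int d3 = -1; d3 <= 1; ++d3)
    for (int d2 = -1; d2 <= 1; ++d2)
      for (int d1 = -1; d1 <= 1; ++d1) {
        int o = (d3 + 1) * 9 + (d2 + 1) * 3 + (d1 + 1);
        shift3(X, D1, D2, D3, d1, d2, d3, buf);
        arma::mat dWo = buf.t() * dZ;           // C x Cout
        for (int c = 0; c < C; ++c) dW.row(c * 27 + o) = dWo.row(c);
        arma::mat T = dZ * gather_w3(W, C, o).t(); // nvox x C
        scatter3(T, D1, D2, D3, d1, d2, d3, dX);
      }
  arma::rowvec db = arma::sum(dZ, 0);
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}

// [[Rcpp::export]]
List maxpool_cpp(const arma::mat &X, IntegerVector dims) {
  // dims: spatial dims (length 2 or 3), each even; pool 2 per axis
  int nd = dims.size();
  int D1 = dims[0], D2 = dims[1], D3 = nd == 3 ? dims[2] : 1;
  int O1 = D1 / 2, O2 = D2 / 2, O3 = nd == 3 ? D3 / 2 : 1;
  const int C = X.n_cols;
  arma::mat Y(O1 * O2 * O3, C);
  arma::umat idx(O1 * O2 * O3, C);
  for (int c = 0; c < C; ++c) {
    const double *xc = X.colptr(c);
    for (int k = 0; k < O3; ++k)
      for (int j = 0; j < O2; ++j)
        for (int i = 0; i < O1; ++i) {
          double best = -1e300; int bi = 0;
          int k1 = nd == 3 ? 2 : 1;
          for (int dk = 0; dk < k1; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                int p = (2 * i + di) + D1 * (2 * j + dj) + D1 * D2 * (2 * k + dk);
                if (xc[p] > best) { best = xc[p]; bi = p; }
              }
          int q = i + O1 * j + O1 * O2 * k;
          Y(q, c) = best; idx(q, c) = bi;
        }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::mat maxpool_back_cpp(const arma::mat &dY, const arma::umat &idx, int npix) {
  const int C = dY.n_cols;
  arma::mat dX(npix, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (arma::uword q = 0; q < dY.n_rows; ++q)
      dX(idx(q, c), c) += dY(q, c);
  return dX;
}

// [[Rcpp::export]]
arma::mat upsample_cpp(const arma::mat &X, IntegerVector dims) {
  int nd = dims.size();
  int D1 = dims[0], D2 = dims[1], D3 = nd == 3 ? dims[2] : 1;
  int O1 = 2 * D1, O2 = 2 * D2, O3 = nd == 3 ? 2 * D3 : 1;
  const int C = X.n_cols;
  arma::mat Y(O1 * O2 * O3, C);
  for (int c = 0; c < C; ++c) {
    const double *xc = X.colptr(c);
    double *yc = Y.colptr(c);
    for (int k = 0; k < O3; ++k)
      for (int j = 0; j < O2; ++j)
        for (int i = 0; i < O1; ++i)
          yc[i + O1 * j + O1 * O2 * k] =
            xc[(i / 2) + D1 * (j / 2) + D1 * D2 * (nd == 3 ? k / 2 : 0)];
  }
  return Y;
}

// [[Rcpp::export]]
arma::mat upsample_back_cpp(const arma::mat &dY, IntegerVector dims) {
  int nd = dims.size();
  int D1 = dims[0], D2 = dims[1], D3 = nd == 3 ? dims[2] : 1;
  int O1 = 2 * D1, O2 = 2 * D2, O3 = nd == 3 ? 2 * D3 : 1;
  const int C = dY.n_cols;
  arma::mat dX(D1 * D2 * D3, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double *yc = dY.colptr(c);
    double *xc = dX.colptr(c);
    for (int k = 0; k < O3; ++k)
      for (int j = 0; j < O2; ++j)
        for (int i = 0; i < O1; ++i)
          xc[(i / 2) + D1 * (j / 2) + D1 * D2 * (nd == 3 ? k / 2 : 0)] +=
            yc[i + O1 * j + O1 * O2 * k];
  }
  return dX;
}

// ---- exact squared Euclidean distance transform (separable lower envelope) --
static void edt1d(const std::vector<double> &f, std::vector<double> &d) {
  const int n = (int)f.size();
  std::vector<int> v(n); std::vector<double> z(n + 1);
  int k = 0; v[0] = 0; z[0] = -1e300; z[1] = 1e300;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
arma::cube edt_cpp(const arma::cube &mask) {
  // squared distance (in voxels) to the nearest nonzero voxel
  const int nx = mask.n_rows, ny = mask.n_cols, nz = mask.n_slices;
  arma::cube d(nx, ny, nz);
  const double INF = 1e300;
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x)
    d(x, y, z) = mask(x, y, z) > 0 ? 0.0 : INF;
  std::vector<double> f, g;
  // x pass
  f.resize(nx); g.resize(nx);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) f[x] = d(x, y, z);
    edt1d(f, g);
    for (int x = 0; x < nx; ++x) d(x, y, z) = g[x];
  }
  f.resize(ny); g.resize(ny);
  for (int z = 0; z < nz; ++z) for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) f[y] = d(x, y, z);
    edt1d(f, g);
    for (int y = 0; y < ny; ++y) d(x, y, z) = g[y];
  }
  f.resize(nz); g.resize(nz);
  for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    for (int z = 0; z < nz; ++z) f[z] = d(x, y, z);
    edt1d(f, g);
    for (int z = 0; z < nz; ++z) d(x, y, z) = g[z];
  }
  return d;
}

// separable Gaussian smoothing of a 3D field (reflected borders)
// [[Rcpp::export]]
arma::cube gauss3_cpp(const arma::cube &f, double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) { k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += k[i + r]; }
  for (double &v : k) v /= s;
  const int nx = f.n_rows, ny = f.n_cols, nz = f.n_slices;
  arma::cube a = f, b(nx, ny, nz);
  auto refl = [](int i, int n) {
    while (i < 0 || i >= n) { if (i < 0) i = -i - 1; if (i >= n) i = 2 * n - i - 1; }
    return i; };
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    double acc = 0; for (int i = -r; i <= r; ++i) acc += k[i + r] * a(refl(x + i, nx), y, z);
    b(x, y, z) = acc; }
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    double acc = 0; for (int i = -r; i <= r; ++i) acc += k[i + r] * b(x, refl(y + i, ny), z);
    a(x, y, z) = acc; }
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    double acc = 0; for (int i = -r; i <= r; ++i) acc += k[i + r] * a(x, y, refl(z + i, nz));
    b(x, y, z) = acc; }
  return b;
}

// ---- isosurface by tetrahedral decomposition (6 tets per cell) ----
// field < iso is inside; triangles oriented with outward normals
// [[Rcpp::export]]
List march_tets_cpp(const arma::cube &field, double iso) {
  const int nx = field.n_rows, ny = field.n_cols, nz = field.n_slices;
  // cube corner offsets
  static const int corner[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // 6-tet decomposition sharing the main diagonal 0-6
  static const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};
  std::map<std::pair<long long,long long>, int> edge_id;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  auto node = [&](int x, int y, int z) -> long long {
    return (long long)x + (long long)nx * y + (long long)nx * ny * z; };
  auto vert_on_edge = [&](long long a, long long b, const double *pa,
                          const double *pb, double va, double vb) -> int {
    std::pair<long long,long long> key = a < b ? std::make_pair(a, b) : std::make_pair(b, a);
    auto it = edge_id.find(key);
    if (it != edge_id.end()) return it->second;
    double t = (iso - va) / (vb - va);
    if (a > b) { } // t computed consistently from the ordered (a,b) arguments below
    int id = (int)vx.size();
    vx.push_back(pa[0] + t * (pb[0] - pa[0]));
    vy.push_back(pa[1] + t * (pb[1] - pa[1]));
    vz.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_id[key] = id;
    return id;
  };
  for (int z = 0; z < nz - 1; ++z)
    for (int y = 0; y < ny - 1; ++y)
      for (int x = 0; x < nx - 1; ++x) {
        double val[8]; double pos[8][3]; long long nid[8];
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + corner[c][0], cy = y + corner[c][1], cz = z + corner[c][2];
          val[c] = field(cx, cy, cz);
          pos[c][0] = cx; pos[c][1] = cy; pos[c][2] = cz;
          nid[c] = node(cx, cy, cz);
          if (val[c] < iso) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          int a = tets[t][0], b = tets[t][1], c = tets[t][2], d = tets[t][3];
          int ids[4] = {a, b, c, d};
          int in[4], nin = 0;
          for (int q = 0; q < 4; ++q) { in[q] = val[ids[q]] < iso; nin += in[q]; }
          if (nin == 0 || nin == 4) continue;
          // gather inside/outside corner lists
          int ins[4], outs[4], ni = 0, no = 0;
          for (int q = 0; q < 4; ++q) { if (in[q]) ins[ni++] = ids[q]; else outs[no++] = ids[q]; }
          auto emit = [&](int v0, int v1, int v2, int inside_corner) {
            // orient: normal must point away from the inside corner
            double ax = vx[v1] - vx[v0], ay = vy[v1] - vy[v0], az = vz[v1] - vz[v0];
            double bx2 = vx[v2] - vx[v0], by2 = vy[v2] - vy[v0], bz2 = vz[v2] - vz[v0];
            double nxv = ay * bz2 - az * by2, nyv = az * bx2 - ax * bz2, nzv = ax * by2 - ay * bx2;
            double cx2 = pos[inside_corner][0] - vx[v0];
            double cy2 = pos[inside_corner][1] - vy[v0];
            double cz2 = pos[inside_corner][2] - vz[v0];
            if (nxv * cx2 + nyv * cy2 + nzv * cz2 > 0) std::swap(v1, v2);
            tri.push_back(v0); tri.push_back(v1); tri.push_back(v2);
          };
          if (nin == 1) {
            int i0 = ins[0];
            int e0 = vert_on_edge(nid[i0], nid[outs[0]], pos[i0], pos[outs[0]], val[i0], val[outs[0]]);
            int e1 = vert_on_edge(nid[i0], nid[outs[1]], pos[i0], pos[outs[1]], val[i0], val[outs[1]]);
            int e2 = vert_on_edge(nid[i0], nid[outs[2]], pos[i0], pos[outs[2]], val[i0], val[outs[2]]);
            emit(e0, e1, e2, i0);
          } else if (nin == 3) {
            int o0 = outs[0];
            int e0 = vert_on_edge(nid[ins[0]], nid[o0], pos[ins[0]], pos[o0], val[ins[0]], val[o0]);
            int e1 = vert_on_edge(nid[ins[1]], nid[o0], pos[ins[1]], pos[o0], val[ins[1]], val[o0]);
            int e2 = vert_on_edge(nid[ins[2]], nid[o0], pos[ins[2]], pos[o0], val[ins[2]], val[o0]);
            emit(e0, e1, e2, ins[0]);
          } else { // 2-2: quad split into two triangles
            int e00 = vert_on_edge(nid[ins[0]], nid[outs[0]], pos[ins[0]], pos[outs[0]], val[ins[0]], val[outs[0]]);
            int e01 = vert_on_edge(nid[ins[0]], nid[outs[1]], pos[ins[0]], pos[outs[1]], val[ins[0]], val[outs[1]]);
            int e10 = vert_on_edge(nid[ins[1]], nid[outs[0]], pos[ins[1]], pos[outs[0]], val[ins[1]], val[outs[0]]);
            int e11 = vert_on_edge(nid[ins[1]], nid[outs[1]], pos[ins[1]], pos[outs[1]], val[ins[1]], val[outs[1]]);
            emit(e00, e01, e11, ins[0]);
            emit(e00, e11, e10, ins[0]);
          }
        }
      }
  const int nV = (int)vx.size(), nT = (int)tri.size() / 3;
  NumericMatrix V(nV, 3); IntegerMatrix F(nT, 3);
  for (int i = 0; i < nV; ++i) { V(i,0) = vx[i]; V(i,1) = vy[i]; V(i,2) = vz[i]; }
  for (int i = 0; i < nT; ++i) { F(i,0) = tri[3*i] + 1; F(i,1) = tri[3*i+1] + 1; F(i,2) = tri[3*i+2] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// ---- point-to-triangle distances ----
static double point_tri_dist2(const double *p, const double *a,
                              const double *b, const double *c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i]=b[i]-a[i]; ac[i]=c[i]-a[i]; ap[i]=p[i]-a[i]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  auto dist2_to = [&](double qx,double qy,double qz){
    double dx=p[0]-qx, dy=p[1]-qy, dz=p[2]-qz; return dx*dx+dy*dy+dz*dz; };
  if (d1 <= 0 && d2 <= 0) return dist2_to(a[0],a[1],a[2]);
  double bp[3]; for (int i=0;i<3;++i) bp[i]=p[i]-b[i];
  double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
  double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
  if (d3 >= 0 && d4 <= d3) return dist2_to(b[0],b[1],b[2]);
  double vc = d1*d4 - d3*d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    return dist2_to(a[0]+t*ab[0], a[1]+t*ab[1], a[2]+t*ab[2]);
  }
  double cp[3]; for (int i=0;i<3;++i) cp[i]=p[i]-c[i];
  double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
  double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
  if (d6 >= 0 && d5 <= d6) return dist2_to(c[0],c[1],c[2]);
  double vb = d5*d2 - d1*d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    return dist2_to(a[0]+t*ac[0], a[1]+t*ac[1], a[2]+t*ac[2]);
  }
  double va = d3*d6 - d5*d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return dist2_to(b[0]+t*(c[0]-b[0]), b[1]+t*(c[1]-b[1]), b[2]+t*(c[2]-b[2]));
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return dist2_to(a[0]+ab[0]*v+ac[0]*w, a[1]+ab[1]*v+ac[1]*w, a[2]+ab[2]*v+ac[2]*w);
}

// Closest distance from each query point to a triangle mesh. Uses a uniform
// grid over triangle bounding boxes with ring expansion; exact result.
// [[Rcpp::export]]
NumericVector mesh_point_dist_cpp(const arma::mat &P, const arma::mat &V,
                                  const arma::imat &F, double cell) {
  const int nP = P.n_rows, nT = F.n_rows;
  NumericVector out(nP);
  if (nT == 0) { std::fill(out.begin(), out.end(), NA_REAL); return out; }
  arma::rowvec lo = arma::min(V, 0), hi = arma::max(V, 0);
  if (cell <= 0) {
    double ext = arma::max(hi - lo);
    cell = std::max(ext / 32.0, 1e-6);
  }
  int gx = std::max(1, (int)std::ceil((hi[0]-lo[0]) / cell));
  int gy = std::max(1, (int)std::ceil((hi[1]-lo[1]) / cell));
  int gz = std::max(1, (int)std::ceil((hi[2]-lo[2]) / cell));
  std::vector<std::vector<int>> bins((size_t)gx * gy * gz);
  auto binid = [&](int x, int y, int z) { return (size_t)x + (size_t)gx*y + (size_t)gx*gy*z; };
  auto clampi = [](int v, int n) { return v < 0 ? 0 : (v >= n ? n - 1 : v); };
  std::vector<std::array<double,9>> tv(nT);
  for (int t = 0; t < nT; ++t) {
    double tlo[3] = {1e300,1e300,1e300}, thi[3] = {-1e300,-1e300,-1e300};
    for (int k = 0; k < 3; ++k) {
      int vi = F(t,k) - 1;
      for (int d = 0; d < 3; ++d) {
        double c = V(vi,d); tv[t][3*k+d] = c;
        if (c < tlo[d]) tlo[d] = c; if (c > thi[d]) thi[d] = c;
      }
    }
    int x0 = clampi((int)((tlo[0]-lo[0])/cell), gx), x1 = clampi((int)((thi[0]-lo[0])/cell), gx);
    int y0 = clampi((int)((tlo[1]-lo[1])/cell), gy), y1 = clampi((int)((thi[1]-lo[1])/cell), gy);
    int z0 = clampi((int)((tlo[2]-lo[2])/cell), gz), z1 = clampi((int)((thi[2]-lo[2])/cell), gz);
    for (int z = z0; z <= z1; ++z) for (int y = y0; y <= y1; ++y) for (int x = x0; x <= x1; ++x)
      bins[binid(x,y,z)].push_back(t);
  }
  for (int ip = 0; ip < nP; ++ip) {
    double p[3] = {P(ip,0), P(ip,1), P(ip,2)};
    int cx = clampi((int)((p[0]-lo[0])/cell), gx);
    int cy = clampi((int)((p[1]-lo[1])/cell), gy);
    int cz = clampi((int)((p[2]-lo[2])/cell), gz);
    double best = 1e300;
    int maxr = std::max(gx, std::max(gy, gz));
    for (int r = 0; r <= maxr; ++r) {
      // once a hit exists, expand only until further rings cannot beat it
      if (best < 1e299) {
        double safe = (r - 1) * cell; // min distance to ring-r cells
        if (safe > 0 && safe * safe > best) break;
      }
      bool any = false;
      for (int z = cz - r; z <= cz + r; ++z) {
        if (z < 0 || z >= gz) continue;
        for (int y = cy - r; y <= cy + r; ++y) {
          if (y < 0 || y >= gy) continue;
          for (int x = cx - r; x <= cx + r; ++x) {
            if (x < 0 || x >= gx) continue;
            if (std::max(std::abs(x-cx), std::max(std::abs(y-cy), std::abs(z-cz))) != r) continue;
            any = true;
            for (int t : bins[binid(x,y,z)]) {
              double d2 = point_tri_dist2(p, &tv[t][0], &tv[t][3], &tv[t][6]);
              if (d2 < best) best = d2;
            }
          }
        }
      }
      if (!any && r > maxr) break;
    }
    out[ip] = std::sqrt(best);
  }
  return out;
}

// Brute-force variant (cross-check for the gridded query)
// [[Rcpp::export]]
NumericVector mesh_point_dist_brute_cpp(const arma::mat &P, const arma::mat &V,
                                        const arma::imat &F) {
  const int nP = P.n_rows, nT = F.n_rows;
  NumericVector out(nP);
  for (int ip = 0; ip < nP; ++ip) {
    double p[3] = {P(ip,0), P(ip,1), P(ip,2)};
    double best = 1e300;
    for (int t = 0; t < nT; ++t) {
      double a[3], b[3], c[3];
      for (int d = 0; d < 3; ++d) {
        a[d] = V(F(t,0)-1, d); b[d] = V(F(t,1)-1, d); c[d] = V(F(t,2)-1, d);
      }
      double d2 = point_tri_dist2(p, a, b, c);
      if (d2 < best) best = d2;
    }
    out[ip] = std::sqrt(best);
  }
  return out;
}
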