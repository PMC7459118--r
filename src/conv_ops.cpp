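// Core numerical kernels for the conv-net engine and distance metrics.
// Layout conventions (R column-major):
//   activations: dim (H, W, C, N)
//   conv weights: dim (k, k, Cin, Cout), "same" zero padding, stride 1, odd k
// Transposed (stride-2) convolutions are composed in R from upsample2_zero_cpp
// followed by an ordinary stride-1 convolution, so only stride-1 kernels live here.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline void get_dim4(const NumericVector &x, int d[4]) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

// Fill im2col matrix for one sample: cols is (k*k*Cin) x (H*W).
// Row index r = a + k*(b + k*ci); column index = i + H*j.
static void im2col(const double *x, int H, int W, int Cin, int k, int pad,
                   arma::mat &cols) {
  cols.zeros();
  const int HW = H * W;
  for (int ci = 0; ci < Cin; ++ci) {
    const double *xc = x + (size_t)ci * HW;
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const int r = a + k * (b + k * ci);
        for (int j = 0; j < W; ++j) {
          const int js = j + b - pad;
          if (js < 0 || js >= W) continue;
          const int i0 = std::max(0, pad - a);
          const int i1 = std::min(H, H + pad - a);
          if (i0 >= i1) continue;
          const double *src = xc + (size_t)js * H + (i0 + a - pad);
          double *dst = cols.colptr(i0 + (size_t)j * H) + r;
          // strided write: consecutive i share column stride k*k*Cin
          const size_t cstride = cols.n_rows;
          for (int i = i0; i < i1; ++i) {
            *dst = *src++;
            dst += cstride;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w, NumericVector b) {
  int dx[4], dw[4];
  get_dim4(x, dx); get_dim4(w, dw);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[3];
  if (dw[1] != k || dw[2] != Cin) stop("weight dims do not match input channels");
  if (k % 2 == 0) stop("kernel size must be odd");
  const int pad = (k - 1) / 2, HW = H * W, kk = k * k * Cin;

  NumericVector out = alloc4(H, W, Cout, N);
  arma::mat Wm(const_cast<double *>(w.begin()), (size_t)kk, Cout, false, true);
  arma::mat cols(kk, HW);
  arma::vec bv(const_cast<double *>(b.begin()), Cout, false, true);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * Cin, H, W, Cin, k, pad, cols);
    arma::mat Y = Wm.t() * cols;             // Cout x HW
    Y.each_col() += bv;
    double *o = out.begin() + (size_t)n * HW * Cout;
    for (int p = 0; p < HW; ++p)
      for (int co = 0; co < Cout; ++co)
        o[p + (size_t)co * HW] = Y(co, p);
  }
  return out;
}

// Gradient w.r.t. input: correlation of dy with spatially flipped, channel-swapped weights.
// [[Rcpp::export]]
NumericVector conv2d_bwd_data_cpp(NumericVector dy, NumericVector w) {
  int dw[4];
  get_dim4(w, dw);
  const int k = dw[0], Cin = dw[2], Cout = dw[3];
  NumericVector wt = alloc4(k, k, Cout, Cin);
  // wt[a,b,co,ci] = w[k-1-a, k-1-b, ci, co]
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int b = 0; b < k; ++b)
        for (int a = 0; a < k; ++a)
          wt[a + k * ((size_t)b + k * ((size_t)co + (size_t)Cout * ci))] =
            w[(k - 1 - a) + k * ((size_t)(k - 1 - b) + k * ((size_t)ci + (size_t)Cin * co))];
  NumericVector zb(Cin);
  return conv2d_fwd_cpp(dy, wt, zb);
}

// Gradients w.r.t. weights and bias. Returns list(dw, db).
// [[Rcpp::export]]
List conv2d_bwd_filter_cpp(NumericVector x, NumericVector dy, int k) {
  int dx[4], dd[4];
  get_dim4(x, dx); get_dim4(dy, dd);
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int Cout = dd[2];
  const int pad = (k - 1) / 2, HW = H * W, kk = k * k * Cin;

  arma::mat dWm(kk, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat cols(kk, HW);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * HW * Cin, H, W, Cin, k, pad, cols);
    arma::mat dYm(const_cast<double *>(dy.begin()) + (size_t)n * HW * Cout,
                  HW, Cout, false, true);
    dWm += cols * dYm;                        // kk x Cout
    db += arma::sum(dYm, 0).t();
  }
  NumericVector dw = alloc4(k, k, Cin, Cout);
  std::copy(dWm.begin(), dWm.end(), dw.begin());
  return List::create(_["dw"] = dw, _["db"] = NumericVector(db.begin(), db.end()));
}

// 2x2 stride-2 max pooling with argmax bookkeeping (0-based index into the HxW plane).
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x) {
  int dx[4];
  get_dim4(x, dx);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  if (H % 2 || W % 2) stop("max pooling requires even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xp = x.begin() + ((size_t)n * C + c) * HW;
      double *op = out.begin() + ((size_t)n * C + c) * Ho * Wo;
      int *ip = idx.begin() + ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          int base = 2 * i + H * 2 * j;
          int cand[4] = {base, base + 1, base + H, base + H + 1};
          int best = cand[0];
          double bv = xp[best];
          for (int q = 1; q < 4; ++q)
            if (xp[cand[q]] > bv) { bv = xp[cand[q]]; best = cand[q]; }
          op[i + (size_t)j * Ho] = bv;
          ip[i + (size_t)j * Ho] = best;
        }
    }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector dy, IntegerVector idx, int H, int W) {
  IntegerVector dm = dy.attr("dim");
  const int Ho = dm[0], Wo = dm[1], C = dm[2], N = dm[3];
  NumericVector dx = alloc4(H, W, C, N);
  const size_t HW = (size_t)H * W, HWo = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *dp = dy.begin() + ((size_t)n * C + c) * HWo;
      const int *ip = idx.begin() + ((size_t)n * C + c) * HWo;
      double *xp = dx.begin() + ((size_t)n * C + c) * HW;
      for (size_t p = 0; p < HWo; ++p) xp[ip[p]] += dp[p];
    }
  return dx;
}

// Insert zeros to double the spatial grid: out[2i, 2j] = x[i, j] (0-based).
// [[Rcpp::export]]
NumericVector upsample2_zero_cpp(NumericVector x) {
  int dx[4];
  get_dim4(x, dx);
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  NumericVector out = alloc4(2 * H, 2 * W, C, N);
  const size_t HW = (size_t)H * W, HW2 = (size_t)4 * H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xp = x.begin() + ((size_t)n * C + c) * HW;
      double *op = out.begin() + ((size_t)n * C + c) * HW2;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          op[2 * i + (size_t)(2 * H) * (2 * j)] = xp[i + (size_t)H * j];
    }
  return out;
}

// Reverse of upsample2_zero: sample the even (0-based) grid positions.
// [[Rcpp::export]]
NumericVector downsample2_zero_cpp(NumericVector x) {
  int dx[4];
  get_dim4(x, dx);
  const int H2 = dx[0], W2 = dx[1], C = dx[2], N = dx[3];
  const int H = H2 / 2, W = W2 / 2;
  NumericVector out = alloc4(H, W, C, N);
  const size_t HW = (size_t)H * W, HW2 = (size_t)H2 * W2;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *xp = x.begin() + ((size_t)n * C + c) * HW2;
      double *op = out.begin() + ((size_t)n * C + c) * HW;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          op[i + (size_t)H * j] = xp[2 * i + (size_t)H2 * (2 * j)];
    }
  return out;
}

// ---- exact anisotropic squared Euclidean distance transform (Felzenszwalb) ----

// "Unseeded" cells carry a huge finite sentinel instead of +Inf so parabola
// intersections never produce Inf - Inf.
static const double DT_BIG = 1e20;

static void dt1d(const double *f, double *d, int n, double s) {
  // lower envelope of parabolas rooted at (i*s, f[i])
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int kq = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  const double s2 = s * s;
  for (int q = 1; q < n; ++q) {
    double sget;
    while (true) {
      const int p = v[kq];
      sget = ((f[q] + s2 * q * q) - (f[p] + s2 * p * p)) / (2.0 * s2 * (q - p));
      if (sget <= z[kq] && kq > 0) { --kq; continue; }
      break;
    }
    if (sget <= z[kq]) { // kq == 0 and q dominates everywhere
      v[0] = q;
    } else {
      ++kq;
      v[kq] = q;
      z[kq] = sget;
    }
    z[kq + 1] = std::numeric_limits<double>::infinity();
  }
  int q2 = 0;
  for (int i = 0; i < n; ++i) {
    while (z[q2 + 1] < i) ++q2;
    const int p = v[q2];
    const double diff = s * (i - p);
    d[i] = diff * diff + f[p];
  }
}

// Squared distance (in mm^2) from every voxel to the nearest seed voxel.
// mask: integer array dim (nz, ny, nx), nonzero = seed; spacing (dz, dy, dx) in mm.
// [[Rcpp::export]]
NumericVector sedt3_cpp(IntegerVector mask, NumericVector spacing) {
  IntegerVector dm = mask.attr("dim");
  if (dm.size() != 3) stop("expected a 3-d array");
  const int nz = dm[0], ny = dm[1], nx = dm[2];
  NumericVector d(Dimension(nz, ny, nx));
  for (R_xlen_t i = 0; i < mask.size(); ++i) d[i] = mask[i] ? 0.0 : DT_BIG;

  std::vector<double> f(std::max(nz, std::max(ny, nx)));
  std::vector<double> g(f.size());
  // along z (fastest index)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      double *col = d.begin() + (size_t)nz * (y + (size_t)ny * x);
      dt1d(col, g.data(), nz, spacing[0]);
      std::copy(g.begin(), g.begin() + nz, col);
    }
  // along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) f[y] = d[z + (size_t)nz * (y + (size_t)ny * x)];
      dt1d(f.data(), g.data(), ny, spacing[1]);
      for (int y = 0; y < ny; ++y) d[z + (size_t)nz * (y + (size_t)ny * x)] = g[y];
    }
  // along x
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      for (int x = 0; x < nx; ++x) f[x] = d[z + (size_t)nz * (y + (size_t)ny * x)];
      dt1d(f.data(), g.data(), nx, spacing[2]);
      for (int x = 0; x < nx; ++x) d[z + (size_t)nz * (y + (size_t)ny * x)] = g[x];
    }
  return d;
}
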