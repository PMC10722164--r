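// Low-level numerical kernels: 2-D convolution (im2col + GEMM), max pooling,
// and an O(n log n) Kendall tau-b. Array layouts follow R's column-major
// convention: activations are (H, W, C, N), convolution weights (KH, KW, CIN, COUT).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline void get_dims4(const NumericVector &x, int out[4], const char *what) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("%s must be a 4-d array", what);
  for (int i = 0; i < 4; ++i) out[i] = d[i];
}

// Fill the im2col matrix K (KH*KW*CIN x HO*WO) for image n.
static void im2col(const double *x, int H, int W, int C, int n,
                   int KH, int KW, int pad, int HO, int WO, arma::mat &K) {
  const double *xn = x + (size_t)n * H * W * C;
  for (int wo = 0; wo < WO; ++wo) {
    for (int ho = 0; ho < HO; ++ho) {
      const int q = ho + HO * wo;
      double *col = K.colptr(q);
      for (int ci = 0; ci < C; ++ci) {
        for (int j = 0; j < KW; ++j) {
          const int w = wo + j - pad;
          for (int i = 0; i < KH; ++i) {
            const int h = ho + i - pad;
            const int r = i + KH * (j + KW * ci);
            col[r] = (h >= 0 && h < H && w >= 0 && w < W)
                       ? xn[h + H * ((size_t)w + W * ci)] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add dK (KH*KW*CIN x HO*WO) back onto the input gradient of image n.
static void col2im_add(const arma::mat &dK, double *dx, int H, int W, int C, int n,
                       int KH, int KW, int pad, int HO, int WO) {
  double *dxn = dx + (size_t)n * H * W * C;
  for (int wo = 0; wo < WO; ++wo) {
    for (int ho = 0; ho < HO; ++ho) {
      const int q = ho + HO * wo;
      const double *col = dK.colptr(q);
      for (int ci = 0; ci < C; ++ci) {
        for (int j = 0; j < KW; ++j) {
          const int w = wo + j - pad;
          if (w < 0 || w >= W) continue;
          for (int i = 0; i < KH; ++i) {
            const int h = ho + i - pad;
            if (h < 0 || h >= H) continue;
            dxn[h + H * ((size_t)w + W * ci)] += col[i + KH * (j + KW * ci)];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b, int pad) {
  int xd[4], wd[4];
  get_dims4(x, xd, "input"); get_dims4(w, wd, "weights");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], CIN = wd[2], COUT = wd[3];
  if (CIN != C) stop("input has %d channels but weights expect %d", C, CIN);
  const int HO = H + 2 * pad - KH + 1, WO = W + 2 * pad - KW + 1;
  if (HO < 1 || WO < 1) stop("kernel larger than padded input");
  if (b.size() != COUT) stop("bias length must equal out_channels");

  NumericVector out = alloc4(HO, WO, COUT, N);
  const arma::mat Wm(const_cast<double *>(w.begin()), KH * KW * CIN, COUT, false, true);
  arma::mat K(KH * KW * CIN, HO * WO);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin(), H, W, C, n, KH, KW, pad, HO, WO, K);
    arma::mat O = K.t() * Wm;                       // (HO*WO) x COUT
    double *on = out.begin() + (size_t)n * HO * WO * COUT;
    for (int co = 0; co < COUT; ++co) {
      const double *src = O.colptr(co);
      double *dst = on + (size_t)co * HO * WO;
      const double bias = b[co];
      for (int q = 0; q < HO * WO; ++q) dst[q] = src[q] + bias;
    }
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w,
                         NumericVector grad_out, int pad) {
  int xd[4], wd[4], gd[4];
  get_dims4(x, xd, "input"); get_dims4(w, wd, "weights");
  get_dims4(grad_out, gd, "grad_out");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], CIN = wd[2], COUT = wd[3];
  const int HO = gd[0], WO = gd[1];
  if (gd[2] != COUT || gd[3] != N) stop("grad_out shape inconsistent with weights/input");

  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dw = alloc4(KH, KW, CIN, COUT);
  NumericVector db(COUT);
  const arma::mat Wm(const_cast<double *>(w.begin()), KH * KW * CIN, COUT, false, true);
  arma::mat dWm(dw.begin(), KH * KW * CIN, COUT, false, true);
  arma::vec dbv(db.begin(), COUT, false, true);
  arma::mat K(KH * KW * CIN, HO * WO);
  for (int n = 0; n < N; ++n) {
    const arma::mat G(const_cast<double *>(grad_out.begin()) + (size_t)n * HO * WO * COUT,
                      HO * WO, COUT, false, true);
    im2col(x.begin(), H, W, C, n, KH, KW, pad, HO, WO, K);
    dWm += K * G;
    dbv += arma::sum(G, 0).t();
    arma::mat dK = Wm * G.t();                      // (KH*KW*CIN) x (HO*WO)
    col2im_add(dK, dx.begin(), H, W, C, n, KH, KW, pad, HO, WO);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_forward_cpp(NumericVector x, int size) {
  int xd[4];
  get_dims4(x, xd, "input");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % size != 0 || W % size != 0)
    stop("spatial size (%dx%d) not divisible by pool size %d", H, W, size);
  const int HO = H / size, WO = W / size;
  NumericVector out = alloc4(HO, WO, C, N);
  IntegerVector idx = alloc4i(HO, WO, C, N); // 0-based linear index into x
  const double *xp = x.begin();
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = H * ((size_t)W * (c + (size_t)C * n));
      for (int wo = 0; wo < WO; ++wo) {
        for (int ho = 0; ho < HO; ++ho) {
          double best = R_NegInf; size_t besti = 0;
          for (int j = 0; j < size; ++j) {
            for (int i = 0; i < size; ++i) {
              const size_t p = base + (ho * size + i) + (size_t)H * (wo * size + j);
              if (xp[p] > best) { best = xp[p]; besti = p; }
            }
          }
          const size_t q = ho + HO * ((size_t)WO * (c + (size_t)C * n) + wo);
          out[q] = best; idx[q] = (int)besti;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_backward_cpp(IntegerVector idx, NumericVector grad_out,
                                   IntegerVector xdim) {
  if (xdim.size() != 4) stop("xdim must have length 4");
  NumericVector dx = alloc4(xdim[0], xdim[1], xdim[2], xdim[3]);
  const R_xlen_t m = grad_out.size();
  if (idx.size() != m) stop("idx and grad_out sizes differ");
  for (R_xlen_t q = 0; q < m; ++q) dx[idx[q]] += grad_out[q];
  return dx;
}

// Merge sort that counts strict inversions in y (discordant pairs after
// sorting by x, ties in x broken by ascending y).
static double count_inversions(std::vector<double> &y, std::vector<double> &buf) {
  const size_t n = y.size();
  double inv = 0.0;
  for (size_t width = 1; width < n; width *= 2) {
    for (size_t lo = 0; lo + width < n; lo += 2 * width) {
      const size_t mid = lo + width, hi = std::min(lo + 2 * width, n);
      size_t i = lo, j = mid, k = lo;
      while (i < mid && j < hi) {
        if (y[j] < y[i]) { inv += (double)(mid - i); buf[k++] = y[j++]; }
        else buf[k++] = y[i++];
      }
      while (i < mid) buf[k++] = y[i++];
      while (j < hi) buf[k++] = y[j++];
      std::copy(buf.begin() + lo, buf.begin() + hi, y.begin() + lo);
    }
  }
  return inv;
}

// [[Rcpp::export]]
double kendall_taub_cpp(NumericVector x, NumericVector y) {
  const R_xlen_t n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  if (n < 2) return NA_REAL;
  for (R_xlen_t i = 0; i < n; ++i)
    if (NumericVector::is_na(x[i]) || NumericVector::is_na(y[i]))
      stop("missing values not supported");
  std::vector<size_t> ord(n);
  for (R_xlen_t i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return y[a] < y[b];
  });
  const double n0 = 0.5 * (double)n * (double)(n - 1);
  // tie corrections on x and joint (x, y) ties
  double n1 = 0.0, n3 = 0.0;
  {
    double tx = 1.0, txy = 1.0;
    for (R_xlen_t i = 1; i < n; ++i) {
      const bool ex = x[ord[i]] == x[ord[i - 1]];
      if (ex) tx += 1.0; else { n1 += 0.5 * tx * (tx - 1.0); tx = 1.0; }
      if (ex && y[ord[i]] == y[ord[i - 1]]) txy += 1.0;
      else { n3 += 0.5 * txy * (txy - 1.0); txy = 1.0; }
    }
    n1 += 0.5 * tx * (tx - 1.0);
    n3 += 0.5 * txy * (txy - 1.0);
  }
  std::vector<double> ys(n), buf(n);
  for (R_xlen_t i = 0; i < n; ++i) ys[i] = y[ord[i]];
  const double disc = count_inversions(ys, buf);
  // ys is now sorted: count tie correction on y
  double n2 = 0.0, ty = 1.0;
  for (R_xlen_t i = 1; i < n; ++i) {
    if (ys[i] == ys[i - 1]) ty += 1.0; else { n2 += 0.5 * ty * (ty - 1.0); ty = 1.0; }
  }
  n2 += 0.5 * ty * (ty - 1.0);
  const double S = n0 - n1 - n2 + n3 - 2.0 * disc;
  const double denom = std::sqrt(n0 - n1) * std::sqrt(n0 - n2);
  if (denom <= 0.0) return NA_REAL;
  return S / denom;
}
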