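// Strided 2-D convolution / transposed convolution kernels (im2col form).
//
// Array conventions follow R column-major storage:
//   activations  x : dim (H, W, C, N)      -- height fastest
//   conv weights w : dim (k, k, Cin, Cout)
//   tconv weights  : dim (k, k, Cout, Cin) -- i.e. the adjoint conv's weight
//
// Patch rows of the im2col matrix are ordered di + k*dj + k*k*c, matching the
// column-major flattening of the (k, k, C) weight block, so a convolution is a
// single GEMM per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int conv_out(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// M: (k*k*C) x (Ho*Wo); column q = io + Ho*jo
static void im2col(const double* x, int H, int W, int C,
                   int k, int s, int p, arma::mat& M, int Ho, int Wo) {
  M.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)H * W * c;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = di + k * dj + k * k * c;
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * s - p + dj;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * s - p + di;
            if (i < 0 || i >= H) continue;
            M(r, io + (std::size_t)Ho * jo) = xc[i + (std::size_t)H * j];
          }
        }
      }
    }
  }
}

// scatter-add adjoint of im2col; x must be zeroed by the caller
static void col2im(const arma::mat& M, int H, int W, int C,
                   int k, int s, int p, double* x, int Ho, int Wo) {
  for (int c = 0; c < C; ++c) {
    double* xc = x + (std::size_t)H * W * c;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int r = di + k * dj + k * k * c;
        for (int jo = 0; jo < Wo; ++jo) {
          const int j = jo * s - p + dj;
          if (j < 0 || j >= W) continue;
          for (int io = 0; io < Ho; ++io) {
            const int i = io * s - p + di;
            if (i < 0 || i >= H) continue;
            xc[i + (std::size_t)H * j] += M(r, io + (std::size_t)Ho * jo);
          }
        }
      }
    }
  }
}

static IntegerVector dims4(const NumericVector& a, const char* what) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 4) stop("%s must be a 4-d array", what);
  return d;
}

// [[Rcpp::export]]
NumericVector nn_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad) {
  IntegerVector dx = dims4(x, "x"), dw = dims4(w, "w");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cin = dw[2], Cout = dw[3];
  if (dw[1] != k) stop("kernel must be square");
  if (Cin != C) stop("channel mismatch: input has %d, weight expects %d", C, Cin);
  if (b.size() != Cout) stop("bias length must equal output channels");
  const int Ho = conv_out(H, k, stride, pad), Wo = conv_out(W, k, stride, pad);
  if (Ho < 1 || Wo < 1) stop("non-positive output size");

  arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)k * k * Cin, Cout, false, true);
  arma::mat M((std::size_t)k * k * Cin, (std::size_t)Ho * Wo);
  NumericVector out((std::size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)H * W * C * n, H, W, C, k, stride, pad, M, Ho, Wo);
    arma::mat O = M.t() * Wm;                       // (Ho*Wo) x Cout
    O.each_row() += arma::rowvec(b.begin(), Cout);
    std::copy(O.begin(), O.end(), out.begin() + (std::size_t)Ho * Wo * Cout * n);
  }
  return out;
}

// [[Rcpp::export]]
List nn_conv_bwd(NumericVector x, NumericVector w, NumericVector gout,
                 int stride, int pad) {
  IntegerVector dx = dims4(x, "x"), dw = dims4(w, "w"), dg = dims4(gout, "gout");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[3];
  const int Ho = dg[0], Wo = dg[1];
  if (dg[2] != Cout || dg[3] != N) stop("gout dims inconsistent with x/w");

  arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)k * k * C, Cout, false, true);
  arma::mat M((std::size_t)k * k * C, (std::size_t)Ho * Wo);
  arma::mat gW((std::size_t)k * k * C, Cout, arma::fill::zeros);
  arma::rowvec gb(Cout, arma::fill::zeros);

  NumericVector gx(x.size());
  gx.attr("dim") = dx;

  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)H * W * C * n, H, W, C, k, stride, pad, M, Ho, Wo);
    arma::mat G(const_cast<double*>(gout.begin()) + (std::size_t)Ho * Wo * Cout * n,
                (std::size_t)Ho * Wo, Cout, false, true);
    gW += M * G;
    gb += arma::sum(G, 0);
    arma::mat Gcol = Wm * G.t();                    // (k*k*C) x (Ho*Wo)
    col2im(Gcol, H, W, C, k, stride, pad, gx.begin() + (std::size_t)H * W * C * n, Ho, Wo);
  }

  NumericVector gWout(gW.begin(), gW.end());
  gWout.attr("dim") = dw;
  return List::create(_["gx"] = gx, _["gw"] = gWout,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// transposed convolution: out size s*(H-1) - 2p + k
// [[Rcpp::export]]
NumericVector nn_tconv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           int stride, int pad) {
  IntegerVector dx = dims4(x, "x"), dw = dims4(w, "w");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[2], Cin = dw[3];
  if (Cin != C) stop("channel mismatch: input has %d, weight expects %d", C, Cin);
  if (b.size() != Cout) stop("bias length must equal output channels");
  const int Ho = stride * (H - 1) - 2 * pad + k, Wo = stride * (W - 1) - 2 * pad + k;
  if (Ho < 1 || Wo < 1) stop("non-positive output size");

  arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)k * k * Cout, Cin, false, true);
  NumericVector out((std::size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  std::fill(out.begin(), out.end(), 0.0);

  for (int n = 0; n < N; ++n) {
    arma::mat X(const_cast<double*>(x.begin()) + (std::size_t)H * W * C * n,
                (std::size_t)H * W, C, false, true);
    arma::mat Gcol = Wm * X.t();                    // (k*k*Cout) x (H*W)
    double* o = out.begin() + (std::size_t)Ho * Wo * Cout * n;
    col2im(Gcol, Ho, Wo, Cout, k, stride, pad, o, H, W);
    for (int c = 0; c < Cout; ++c) {
      double* oc = o + (std::size_t)Ho * Wo * c;
      for (std::size_t q = 0; q < (std::size_t)Ho * Wo; ++q) oc[q] += b[c];
    }
  }
  return out;
}

// [[Rcpp::export]]
List nn_tconv_bwd(NumericVector x, NumericVector w, NumericVector gout,
                  int stride, int pad) {
  IntegerVector dx = dims4(x, "x"), dw = dims4(w, "w"), dg = dims4(gout, "gout");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[2];
  const int Ho = dg[0], Wo = dg[1];
  if (dg[2] != Cout || dg[3] != N) stop("gout dims inconsistent with x/w");

  arma::mat Wm(const_cast<double*>(w.begin()), (std::size_t)k * k * Cout, C, false, true);
  arma::mat M((std::size_t)k * k * Cout, (std::size_t)H * W);
  arma::mat gW((std::size_t)k * k * Cout, C, arma::fill::zeros);
  arma::rowvec gb(Cout, arma::fill::zeros);

  NumericVector gx(x.size());
  gx.attr("dim") = dx;

  for (int n = 0; n < N; ++n) {
    const double* g = gout.begin() + (std::size_t)Ho * Wo * Cout * n;
    im2col(g, Ho, Wo, Cout, k, stride, pad, M, H, W);
    arma::mat X(const_cast<double*>(x.begin()) + (std::size_t)H * W * C * n,
                (std::size_t)H * W, C, false, true);
    gW += M * X;
    arma::mat GX = M.t() * Wm;                      // (H*W) x C
    std::copy(GX.begin(), GX.end(), gx.begin() + (std::size_t)H * W * C * n);
    arma::mat Gm(const_cast<double*>(g), (std::size_t)Ho * Wo, Cout, false, true);
    gb += arma::sum(Gm, 0);
  }

  NumericVector gWout(gW.begin(), gW.end());
  gWout.attr("dim") = dw;
  return List::create(_["gx"] = gx, _["gw"] = gWout,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}
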