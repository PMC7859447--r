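// Low-level numerical kernels for the registration network.
//
// Array layout convention (shared with the R side): dense column-major
// R arrays with the channel axis LAST, i.e. a feature map has dim
// (D, H, W, C) and element (d,h,w,c) sits at d + D*(h + H*(w + W*c)).
// Deformation grids / displacement fields are (D, H, W, 3) in normalized
// [-1, 1] align-corners coordinates (component k addresses array axis k).

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline int conv_out_size(int n, int pad, int dil, int stride) {
  // kernel size fixed at 3
  return (n + 2 * pad - 2 * dil - 1) / stride + 1;
}

// Gather im2col patches (zero padding = dilation) into P (Nout x 27*Cin).
// Column order: kd fastest, then kh, kw, then input channel.
static void im2col_patches(const double* x, int D, int H, int W, int Cin,
                           int Do, int Ho, int Wo, int stride, int dil,
                           arma::mat& P) {
  const int pad = dil;
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (R_xlen_t)c * D * H * W;
    for (int kw = 0; kw < 3; ++kw)
      for (int kh = 0; kh < 3; ++kh)
        for (int kd = 0; kd < 3; ++kd) {
          const int col = kd + 3 * kh + 9 * kw + 27 * c;
          double* Pc = P.colptr(col);
          R_xlen_t r = 0;
          for (int ow = 0; ow < Wo; ++ow) {
            const int iw = ow * stride - pad + kw * dil;
            for (int oh = 0; oh < Ho; ++oh) {
              const int ih = oh * stride - pad + kh * dil;
              const bool okhw = iw >= 0 && iw < W && ih >= 0 && ih < H;
              const R_xlen_t off = okhw ? (R_xlen_t)D * (ih + (R_xlen_t)H * iw) : 0;
              for (int od = 0; od < Do; ++od, ++r) {
                const int id = od * stride - pad + kd * dil;
                Pc[r] = (okhw && id >= 0 && id < D) ? xc[id + off] : 0.0;
              }
            }
          }
        }
  }
}

// Stride-1, dilation-1 convolutions dominate the network's cost; they are
// computed as a single GEMM Y = X * Wcat (X the N x Cin voxel-by-channel
// matrix, Wcat the per-offset weight blocks side by side) followed by a
// cheap shift-gather out(p) = sum_k Y(p + o_k, block k), avoiding the
// im2col patch materialization entirely.

static NumericVector conv3d_fw_s1(NumericVector x, NumericMatrix w,
                                  NumericVector b) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int Cout = w.ncol();
  const R_xlen_t N = (R_xlen_t)D * H * W;
  arma::mat X((double*)REAL(x), N, Cin, false, true);
  arma::mat Wcat(Cin, 27 * Cout);
  for (int k = 0; k < 27; ++k)
    for (int co = 0; co < Cout; ++co)
      for (int c = 0; c < Cin; ++c)
        Wcat(c, k * Cout + co) = w(k + 27 * c, co);
  arma::mat Y = X * Wcat;  // N x 27*Cout
  NumericVector out(N * Cout);
  double* op = REAL(out);
  for (int co = 0; co < Cout; ++co) {
    double* oc = op + (R_xlen_t)co * N;
    for (R_xlen_t p = 0; p < N; ++p) oc[p] = b[co];
  }
  const R_xlen_t DH = (R_xlen_t)D * H;
  for (int kw = 0; kw < 3; ++kw)
    for (int kh = 0; kh < 3; ++kh)
      for (int kd = 0; kd < 3; ++kd) {
        const int k = kd + 3 * kh + 9 * kw;
        const int od = kd - 1, oh = kh - 1, ow = kw - 1;
        const int d0 = std::max(0, -od), d1 = std::min(D, D - od);
        const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
        const int w0 = std::max(0, -ow), w1 = std::min(W, W - ow);
        for (int co = 0; co < Cout; ++co) {
          const double* yc = Y.colptr(k * Cout + co);
          double* oc = op + (R_xlen_t)co * N;
          for (int iw = w0; iw < w1; ++iw)
            for (int ih = h0; ih < h1; ++ih) {
              const R_xlen_t dst = d0 + (R_xlen_t)D * ih + DH * iw;
              const R_xlen_t src = (d0 + od) + (R_xlen_t)D * (ih + oh) +
                                   DH * (iw + ow);
              const double* ys = yc + src;
              double* od_ = oc + dst;
              const int len = d1 - d0;
              for (int t = 0; t < len; ++t) od_[t] += ys[t];
            }
        }
      }
  out.attr("dim") = IntegerVector::create(D, H, W, Cout);
  return out;
}

static List conv3d_bw_s1(NumericVector x, NumericMatrix w,
                         NumericVector gout, bool need_gx) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int Cout = w.ncol();
  const R_xlen_t N = (R_xlen_t)D * H * W;
  const double* gp = REAL(gout);
  // scatter gout into per-offset blocks: G(p + o_k, k*Cout + co) = gout(p, co)
  arma::mat G(N, 27 * Cout, arma::fill::zeros);
  const R_xlen_t DH = (R_xlen_t)D * H;
  for (int kw = 0; kw < 3; ++kw)
    for (int kh = 0; kh < 3; ++kh)
      for (int kd = 0; kd < 3; ++kd) {
        const int k = kd + 3 * kh + 9 * kw;
        const int od = kd - 1, oh = kh - 1, ow = kw - 1;
        const int d0 = std::max(0, -od), d1 = std::min(D, D - od);
        const int h0 = std::max(0, -oh), h1 = std::min(H, H - oh);
        const int w0 = std::max(0, -ow), w1 = std::min(W, W - ow);
        for (int co = 0; co < Cout; ++co) {
          double* gc = G.colptr(k * Cout + co);
          const double* sc = gp + (R_xlen_t)co * N;
          for (int iw = w0; iw < w1; ++iw)
            for (int ih = h0; ih < h1; ++ih) {
              const R_xlen_t dst = (d0 + od) + (R_xlen_t)D * (ih + oh) +
                                   DH * (iw + ow);
              const R_xlen_t src = d0 + (R_xlen_t)D * ih + DH * iw;
              const double* ss = sc + src;
              double* dd = gc + dst;
              const int len = d1 - d0;
              for (int t = 0; t < len; ++t) dd[t] += ss[t];
            }
        }
      }
  arma::mat X((double*)REAL(x), N, Cin, false, true);
  arma::mat gWcat = X.t() * G;  // Cin x 27*Cout
  NumericMatrix gwR(27 * Cin, Cout);
  for (int k = 0; k < 27; ++k)
    for (int co = 0; co < Cout; ++co)
      for (int c = 0; c < Cin; ++c)
        gwR(k + 27 * c, co) = gWcat(c, k * Cout + co);
  NumericVector gbR(Cout);
  for (int co = 0; co < Cout; ++co) {
    const double* sc = gp + (R_xlen_t)co * N;
    double s = 0.0;
    for (R_xlen_t p = 0; p < N; ++p) s += sc[p];
    gbR[co] = s;
  }
  NumericVector gx;
  if (need_gx) {
    arma::mat Wstack(27 * Cout, Cin);
    for (int k = 0; k < 27; ++k)
      for (int co = 0; co < Cout; ++co)
        for (int c = 0; c < Cin; ++c)
          Wstack(k * Cout + co, c) = w(k + 27 * c, co);
    arma::mat gX = G * Wstack;  // N x Cin
    gx = NumericVector(N * Cin);
    std::copy(gX.begin(), gX.end(), REAL(gx));
    gx.attr("dim") = xd;
  }
  return List::create(_["gx"] = gx, _["gw"] = gwR, _["gb"] = gbR);
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fw(NumericVector x, NumericMatrix w, NumericVector b,
                            int stride, int dil) {
  if (stride == 1 && dil == 1) return conv3d_fw_s1(x, w, b);
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int pad = dil;
  const int Do = conv_out_size(D, pad, dil, stride);
  const int Ho = conv_out_size(H, pad, dil, stride);
  const int Wo = conv_out_size(W, pad, dil, stride);
  const int Cout = w.ncol();
  const R_xlen_t Nout = (R_xlen_t)Do * Ho * Wo;
  arma::mat P(Nout, 27 * Cin);
  im2col_patches(REAL(x), D, H, W, Cin, Do, Ho, Wo, stride, dil, P);
  arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false, true);
  arma::mat O = P * Wm;
  for (int co = 0; co < Cout; ++co) O.col(co) += b[co];
  NumericVector out(O.begin(), O.end());
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_bw(NumericVector x, NumericMatrix w, NumericVector gout,
                   int stride, int dil, bool need_gx) {
  if (stride == 1 && dil == 1) return conv3d_bw_s1(x, w, gout, need_gx);
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], Cin = xd[3];
  const int pad = dil;
  const int Do = conv_out_size(D, pad, dil, stride);
  const int Ho = conv_out_size(H, pad, dil, stride);
  const int Wo = conv_out_size(W, pad, dil, stride);
  const int Cout = w.ncol();
  const R_xlen_t Nout = (R_xlen_t)Do * Ho * Wo;
  arma::mat P(Nout, 27 * Cin);
  im2col_patches(REAL(x), D, H, W, Cin, Do, Ho, Wo, stride, dil, P);
  arma::mat Wm(w.begin(), w.nrow(), w.ncol(), false, true);
  arma::mat G((double*)REAL(gout), Nout, Cout, false, true);
  arma::mat gw = P.t() * G;
  arma::rowvec gb = arma::sum(G, 0);

  NumericMatrix gwR(gw.n_rows, gw.n_cols);
  std::copy(gw.begin(), gw.end(), gwR.begin());
  NumericVector gbR(gb.begin(), gb.end());

  NumericVector gx;
  if (need_gx) {
    arma::mat GP = G * Wm.t();  // Nout x 27*Cin
    gx = NumericVector((R_xlen_t)D * H * W * Cin);
    double* gxp = REAL(gx);
    for (int c = 0; c < Cin; ++c) {
      double* gxc = gxp + (R_xlen_t)c * D * H * W;
      for (int kw = 0; kw < 3; ++kw)
        for (int kh = 0; kh < 3; ++kh)
          for (int kd = 0; kd < 3; ++kd) {
            const int col = kd + 3 * kh + 9 * kw + 27 * c;
            const double* Gc = GP.colptr(col);
            R_xlen_t r = 0;
            for (int ow = 0; ow < Wo; ++ow) {
              const int iw = ow * stride - pad + kw * dil;
              for (int oh = 0; oh < Ho; ++oh) {
                const int ih = oh * stride - pad + kh * dil;
                const bool okhw = iw >= 0 && iw < W && ih >= 0 && ih < H;
                const R_xlen_t off = okhw ? (R_xlen_t)D * (ih + (R_xlen_t)H * iw) : 0;
                for (int od = 0; od < Do; ++od, ++r) {
                  const int id = od * stride - pad + kd * dil;
                  if (okhw && id >= 0 && id < D) gxc[id + off] += Gc[r];
                }
              }
            }
          }
    }
    gx.attr("dim") = xd;
  }
  return List::create(_["gx"] = gx, _["gw"] = gwR, _["gb"] = gbR);
}

// Precompute 1D align-corners interpolation support: for output index i,
// input base index i0[i], weight w1[i] for i0+1 (weight for i0 is 1-w1).
static void axis_coeffs(int n_in, int n_out, std::vector<int>& i0,
                        std::vector<double>& w1) {
  i0.resize(n_out);
  w1.resize(n_out);
  for (int i = 0; i < n_out; ++i) {
    double pos = (n_out == 1) ? 0.0
                              : (double)i * (n_in - 1) / (double)(n_out - 1);
    int b = (int)std::floor(pos);
    if (b > n_in - 2) b = n_in - 2;
    if (b < 0) b = 0;
    double f = pos - b;
    if (n_in == 1) { b = 0; f = 0.0; }
    i0[i] = b;
    w1[i] = f;
  }
}

// [[Rcpp::export]]
NumericVector cpp_resize3(NumericVector x, IntegerVector osp) {
  IntegerVector xd = x.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int Do = osp[0], Ho = osp[1], Wo = osp[2];
  std::vector<int> d0, h0, w0;
  std::vector<double> df, hf, wf;
  axis_coeffs(D, Do, d0, df);
  axis_coeffs(H, Ho, h0, hf);
  axis_coeffs(W, Wo, w0, wf);
  NumericVector out((R_xlen_t)Do * Ho * Wo * C);
  const double* xp = REAL(x);
  double* op = REAL(out);
  const R_xlen_t DH = (R_xlen_t)D * H;
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (R_xlen_t)c * D * H * W;
    R_xlen_t r = (R_xlen_t)c * Do * Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow) {
      const int iw = w0[ow];
      const double fw = wf[ow];
      const int iw1 = (W == 1) ? iw : iw + 1;
      for (int oh = 0; oh < Ho; ++oh) {
        const int ih = h0[oh];
        const double fh = hf[oh];
        const int ih1 = (H == 1) ? ih : ih + 1;
        const R_xlen_t b00 = (R_xlen_t)D * ih + DH * iw;
        const R_xlen_t b10 = (R_xlen_t)D * ih1 + DH * iw;
        const R_xlen_t b01 = (R_xlen_t)D * ih + DH * iw1;
        const R_xlen_t b11 = (R_xlen_t)D * ih1 + DH * iw1;
        for (int od = 0; od < Do; ++od, ++r) {
          const int id = d0[od];
          const double fd = df[od];
          const int id1 = (D == 1) ? id : id + 1;
          const double v00 = xc[id + b00] * (1 - fd) + xc[id1 + b00] * fd;
          const double v10 = xc[id + b10] * (1 - fd) + xc[id1 + b10] * fd;
          const double v01 = xc[id + b01] * (1 - fd) + xc[id1 + b01] * fd;
          const double v11 = xc[id + b11] * (1 - fd) + xc[id1 + b11] * fd;
          op[r] = (v00 * (1 - fh) + v10 * fh) * (1 - fw) +
                  (v01 * (1 - fh) + v11 * fh) * fw;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return out;
}

// Adjoint of cpp_resize3: scatter gradient from output grid back to input.
// [[Rcpp::export]]
NumericVector cpp_resize3_adj(NumericVector g, IntegerVector isp) {
  IntegerVector gd = g.attr("dim");
  const int Do = gd[0], Ho = gd[1], Wo = gd[2], C = gd[3];
  const int D = isp[0], H = isp[1], W = isp[2];
  std::vector<int> d0, h0, w0;
  std::vector<double> df, hf, wf;
  axis_coeffs(D, Do, d0, df);
  axis_coeffs(H, Ho, h0, hf);
  axis_coeffs(W, Wo, w0, wf);
  NumericVector out((R_xlen_t)D * H * W * C);
  const double* gp = REAL(g);
  double* op = REAL(out);
  const R_xlen_t DH = (R_xlen_t)D * H;
  for (int c = 0; c < C; ++c) {
    double* oc = op + (R_xlen_t)c * D * H * W;
    R_xlen_t r = (R_xlen_t)c * Do * Ho * Wo;
    for (int ow = 0; ow < Wo; ++ow) {
      const int iw = w0[ow];
      const double fw = wf[ow];
      const int iw1 = (W == 1) ? iw : iw + 1;
      for (int oh = 0; oh < Ho; ++oh) {
        const int ih = h0[oh];
        const double fh = hf[oh];
        const int ih1 = (H == 1) ? ih : ih + 1;
        const R_xlen_t b00 = (R_xlen_t)D * ih + DH * iw;
        const R_xlen_t b10 = (R_xlen_t)D * ih1 + DH * iw;
        const R_xlen_t b01 = (R_xlen_t)D * ih + DH * iw1;
        const R_xlen_t b11 = (R_xlen_t)D * ih1 + DH * iw1;
        for (int od = 0; od < Do; ++od, ++r) {
          const int id = d0[od];
          const double fd = df[od];
          const int id1 = (D == 1) ? id : id + 1;
          const double gv = gp[r];
          const double g00 = gv * (1 - fh) * (1 - fw);
          const double g10 = gv * fh * (1 - fw);
          const double g01 = gv * (1 - fh) * fw;
          const double g11 = gv * fh * fw;
          oc[id + b00] += g00 * (1 - fd); oc[id1 + b00] += g00 * fd;
          oc[id + b10] += g10 * (1 - fd); oc[id1 + b10] += g10 * fd;
          oc[id + b01] += g01 * (1 - fd); oc[id1 + b01] += g01 * fd;
          oc[id + b11] += g11 * (1 - fd); oc[id1 + b11] += g11 * fd;
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(D, H, W, C);
  return out;
}

struct GsCoord {
  int i0; double f; double scale; bool inside;
};

static inline GsCoord gs_axis(double t, int n) {
  GsCoord c;
  double pos = (t + 1.0) * 0.5 * (n - 1);
  c.inside = (pos >= 0.0 && pos <= (double)(n - 1));
  if (pos < 0.0) pos = 0.0;
  if (pos > (double)(n - 1)) pos = (double)(n - 1);
  int b = (int)std::floor(pos);
  if (b > n - 2) b = n - 2;
  if (b < 0) b = 0;
  c.i0 = b;
  c.f = (n == 1) ? 0.0 : pos - b;
  if (n == 1) c.i0 = 0;
  // snap to lattice nodes so sampling a voxel's exact location returns
  // its value bitwise (interpolation weights collapse)
  if (c.f < 1e-9) c.f = 0.0;
  if (c.f > 1.0 - 1e-9) c.f = 1.0;
  c.scale = 0.5 * (n - 1);
  return c;
}

// Trilinear sampling of x at grid coordinates (border-clamped).
// [[Rcpp::export]]
NumericVector cpp_grid_sample_fw(NumericVector x, NumericVector grid) {
  IntegerVector xd = x.attr("dim"), gd = grid.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int Do = gd[0], Ho = gd[1], Wo = gd[2];
  const R_xlen_t N = (R_xlen_t)Do * Ho * Wo;
  const R_xlen_t Nin = (R_xlen_t)D * H * W;
  const double* xp = REAL(x);
  const double* gp = REAL(grid);
  NumericVector out(N * C);
  double* op = REAL(out);
  const R_xlen_t DH = (R_xlen_t)D * H;
  for (R_xlen_t p = 0; p < N; ++p) {
    GsCoord cd = gs_axis(gp[p], D);
    GsCoord ch = gs_axis(gp[p + N], H);
    GsCoord cw = gs_axis(gp[p + 2 * N], W);
    const int id = cd.i0, id1 = (D == 1) ? id : id + 1;
    const int ih = ch.i0, ih1 = (H == 1) ? ih : ih + 1;
    const int iw = cw.i0, iw1 = (W == 1) ? iw : iw + 1;
    const double fd = cd.f, fh = ch.f, fw = cw.f;
    const R_xlen_t b000 = id + D * (R_xlen_t)ih + DH * iw;
    const R_xlen_t b100 = id1 + D * (R_xlen_t)ih + DH * iw;
    const R_xlen_t b010 = id + D * (R_xlen_t)ih1 + DH * iw;
    const R_xlen_t b110 = id1 + D * (R_xlen_t)ih1 + DH * iw;
    const R_xlen_t b001 = id + D * (R_xlen_t)ih + DH * iw1;
    const R_xlen_t b101 = id1 + D * (R_xlen_t)ih + DH * iw1;
    const R_xlen_t b011 = id + D * (R_xlen_t)ih1 + DH * iw1;
    const R_xlen_t b111 = id1 + D * (R_xlen_t)ih1 + DH * iw1;
    const double w000 = (1 - fd) * (1 - fh) * (1 - fw);
    const double w100 = fd * (1 - fh) * (1 - fw);
    const double w010 = (1 - fd) * fh * (1 - fw);
    const double w110 = fd * fh * (1 - fw);
    const double w001 = (1 - fd) * (1 - fh) * fw;
    const double w101 = fd * (1 - fh) * fw;
    const double w011 = (1 - fd) * fh * fw;
    const double w111 = fd * fh * fw;
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (R_xlen_t)c * Nin;
      op[p + (R_xlen_t)c * N] =
          w000 * xc[b000] + w100 * xc[b100] + w010 * xc[b010] +
          w110 * xc[b110] + w001 * xc[b001] + w101 * xc[b101] +
          w011 * xc[b011] + w111 * xc[b111];
    }
  }
  out.attr("dim") = IntegerVector::create(Do, Ho, Wo, C);
  return out;
}

// [[Rcpp::export]]
List cpp_grid_sample_bw(NumericVector x, NumericVector grid,
                        NumericVector gout, bool need_gx) {
  IntegerVector xd = x.attr("dim"), gd = grid.attr("dim");
  const int D = xd[0], H = xd[1], W = xd[2], C = xd[3];
  const int Do = gd[0], Ho = gd[1], Wo = gd[2];
  const R_xlen_t N = (R_xlen_t)Do * Ho * Wo;
  const R_xlen_t Nin = (R_xlen_t)D * H * W;
  const double* xp = REAL(x);
  const double* gp = REAL(grid);
  const double* go = REAL(gout);
  NumericVector ggrid(N * 3);
  double* gg = REAL(ggrid);
  NumericVector gx;
  double* gxp = NULL;
  if (need_gx) {
    gx = NumericVector(Nin * C);
    gx.attr("dim") = xd;
    gxp = REAL(gx);
  }
  const R_xlen_t DH = (R_xlen_t)D * H;
  for (R_xlen_t p = 0; p < N; ++p) {
    GsCoord cd = gs_axis(gp[p], D);
    GsCoord ch = gs_axis(gp[p + N], H);
    GsCoord cw = gs_axis(gp[p + 2 * N], W);
    const int id = cd.i0, id1 = (D == 1) ? id : id + 1;
    const int ih = ch.i0, ih1 = (H == 1) ? ih : ih + 1;
    const int iw = cw.i0, iw1 = (W == 1) ? iw : iw + 1;
    const double fd = cd.f, fh = ch.f, fw = cw.f;
    const R_xlen_t b000 = id + D * (R_xlen_t)ih + DH * iw;
    const R_xlen_t b100 = id1 + D * (R_xlen_t)ih + DH * iw;
    const R_xlen_t b010 = id + D * (R_xlen_t)ih1 + DH * iw;
    const R_xlen_t b110 = id1 + D * (R_xlen_t)ih1 + DH * iw;
    const R_xlen_t b001 = id + D * (R_xlen_t)ih + DH * iw1;
    const R_xlen_t b101 = id1 + D * (R_xlen_t)ih + DH * iw1;
    const R_xlen_t b011 = id + D * (R_xlen_t)ih1 + DH * iw1;
    const R_xlen_t b111 = id1 + D * (R_xlen_t)ih1 + DH * iw1;
    double dd = 0.0, dh = 0.0, dw = 0.0;
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + (R_xlen_t)c * Nin;
      const double g = go[p + (R_xlen_t)c * N];
      const double x000 = xc[b000], x100 = xc[b100], x010 = xc[b010],
                   x110 = xc[b110], x001 = xc[b001], x101 = xc[b101],
                   x011 = xc[b011], x111 = xc[b111];
      dd += g * (((x100 - x000) * (1 - fh) + (x110 - x010) * fh) * (1 - fw) +
                 ((x101 - x001) * (1 - fh) + (x111 - x011) * fh) * fw);
      dh += g * (((x010 - x000) * (1 - fd) + (x110 - x100) * fd) * (1 - fw) +
                 ((x011 - x001) * (1 - fd) + (x111 - x101) * fd) * fw);
      dw += g * (((x001 - x000) * (1 - fd) + (x101 - x100) * fd) * (1 - fh) +
                 ((x011 - x010) * (1 - fd) + (x111 - x110) * fd) * fh);
      if (need_gx) {
        double* gxc = gxp + (R_xlen_t)c * Nin;
        gxc[b000] += g * (1 - fd) * (1 - fh) * (1 - fw);
        gxc[b100] += g * fd * (1 - fh) * (1 - fw);
        gxc[b010] += g * (1 - fd) * fh * (1 - fw);
        gxc[b110] += g * fd * fh * (1 - fw);
        gxc[b001] += g * (1 - fd) * (1 - fh) * fw;
        gxc[b101] += g * fd * (1 - fh) * fw;
        gxc[b011] += g * (1 - fd) * fh * fw;
        gxc[b111] += g * fd * fh * fw;
      }
    }
    gg[p] = cd.inside ? dd * cd.scale : 0.0;
    gg[p + N] = ch.inside ? dh * ch.scale : 0.0;
    gg[p + 2 * N] = cw.inside ? dw * cw.scale : 0.0;
  }
  ggrid.attr("dim") = IntegerVector::create(Do, Ho, Wo, 3);
  return List::create(_["gx"] = gx, _["ggrid"] = ggrid);
}

// 1D box-window sum along `axis` (1-based) with replicate padding; the
// adjoint scatters instead of gathering. Window length v (odd).
// [[Rcpp::export]]
NumericVector cpp_box_axis(NumericVector x, int axis, int v, bool adjoint) {
  IntegerVector xd = x.attr("dim");
  const int nd = xd.size();
  R_xlen_t npre = 1, npost = 1;
  for (int k = 0; k < axis - 1; ++k) npre *= xd[k];
  const int n = xd[axis - 1];
  for (int k = axis; k < nd; ++k) npost *= xd[k];
  const int r = (v - 1) / 2;
  NumericVector out(x.size());
  const double* xp = REAL(x);
  double* op = REAL(out);
  for (R_xlen_t post = 0; post < npost; ++post) {
    const R_xlen_t base = post * n * npre;
    for (int i = 0; i < n; ++i) {
      for (int k = -r; k <= r; ++k) {
        int j = i + k;
        if (j < 0) j = 0;
        if (j > n - 1) j = n - 1;
        const R_xlen_t src = base + (R_xlen_t)(adjoint ? i : j) * npre;
        const R_xlen_t dst = base + (R_xlen_t)(adjoint ? j : i) * npre;
        const double* xs = xp + src;
        double* od = op + dst;
        for (R_xlen_t p = 0; p < npre; ++p) od[p] += xs[p];
      }
    }
  }
  out.attr("dim") = xd;
  return out;
}

// Minimum Euclidean distance from each row of A to the point set B.
// [[Rcpp::export]]
NumericVector cpp_nn_min_dist(NumericMatrix A, NumericMatrix B) {
  const int na = A.nrow(), nb = B.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    const double a1 = A(i, 0), a2 = A(i, 1), a3 = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double d1 = a1 - B(j, 0), d2 = a2 - B(j, 1), d3 = a3 - B(j, 2);
      const double d = d1 * d1 + d2 * d2 + d3 * d3;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
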