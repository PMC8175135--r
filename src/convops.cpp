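// Low-level numerical kernels for the CNN engine and the mask connector.
// Tensor layout: column-major R arrays dim (H, W, C, N); element (h,w,c,n)
// sits at h + H*(w + W*(c + C*n)). Convolution is stride-1 with symmetric
// zero padding; downsampling is done by pooling nodes.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C,
                             int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-D (H,W,C,N) array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

static inline NumericVector make4(int H, int W, int C, int N) {
  NumericVector v((R_xlen_t)H * W * C * N);
  v.attr("dim") = IntegerVector::create(H, W, C, N);
  return v;
}

static inline IntegerVector make4i(int H, int W, int C, int N) {
  IntegerVector v((R_xlen_t)H * W * C * N);
  v.attr("dim") = IntegerVector::create(H, W, C, N);
  return v;
}

// Build the im2col matrix (H*W) x (k*k*Cg) for one sample and channel range
// [c0, c0+Cg). Column q = a + k*b + k*k*(c-c0) for kernel offset (a,b).
static void im2col(const double* x, int H, int W, int c0, int Cg, int k,
                   int pad, arma::mat& M) {
  const int HW = H * W;
  M.zeros(HW, k * k * Cg);
  for (int c = 0; c < Cg; ++c) {
    const double* xc = x + (size_t)(c0 + c) * HW;
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const int q = a + k * b + k * k * c;
        double* Mq = M.colptr(q);
        for (int j = 0; j < W; ++j) {
          const int jin = j + b - pad;
          if (jin < 0 || jin >= W) continue;
          const double* xcol = xc + (size_t)jin * H;
          double* Mcol = Mq + (size_t)j * H;
          const int i0 = std::max(0, pad - a);
          const int i1 = std::min(H, H + pad - a);
          for (int i = i0; i < i1; ++i) Mcol[i] = xcol[i + a - pad];
        }
      }
    }
  }
}

// Scatter-add of a column-matrix gradient back onto the input plane
// (transpose of im2col).
static void col2im(const arma::mat& dM, int H, int W, int c0, int Cg, int k,
                   int pad, double* dx) {
  const int HW = H * W;
  for (int c = 0; c < Cg; ++c) {
    double* dxc = dx + (size_t)(c0 + c) * HW;
    for (int b = 0; b < k; ++b) {
      for (int a = 0; a < k; ++a) {
        const int q = a + k * b + k * k * c;
        const double* Mq = dM.colptr(q);
        for (int j = 0; j < W; ++j) {
          const int jin = j + b - pad;
          if (jin < 0 || jin >= W) continue;
          double* xcol = dxc + (size_t)jin * H;
          const double* Mcol = Mq + (size_t)j * H;
          const int i0 = std::max(0, pad - a);
          const int i1 = std::min(H, H + pad - a);
          for (int i = i0; i < i1; ++i) xcol[i + a - pad] += Mcol[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector Wt,
                            NumericVector bias, int k, int pad, int groups) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = Wt.attr("dim");
  const int Cg = wd[2];        // input channels per group
  const int Cout = wd[3];
  if (C != Cg * groups) stop("input channels inconsistent with weight/groups");
  if (Cout % groups != 0) stop("output channels not divisible by groups");
  const int Og = Cout / groups;
  const int HW = H * W;

  NumericVector out = make4(H, W, Cout, N);
  arma::mat Wmat(const_cast<double*>(Wt.begin()), k * k * Cg, Cout, false);
  arma::mat M;
  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * HW * C;
    double* on = out.begin() + (size_t)n * HW * Cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, g * Cg, Cg, k, pad, M);
      arma::mat Og_mat = M * Wmat.cols(g * Og, (g + 1) * Og - 1);
      for (int o = 0; o < Og; ++o) {
        double* oc = on + (size_t)(g * Og + o) * HW;
        const double bo = bias[g * Og + o];
        const double* src = Og_mat.colptr(o);
        for (int p = 0; p < HW; ++p) oc[p] = src[p] + bo;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector Wt, NumericVector dout,
                   int k, int pad, int groups) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  IntegerVector wd = Wt.attr("dim");
  const int Cg = wd[2];
  const int Cout = wd[3];
  const int Og = Cout / groups;
  const int HW = H * W;

  NumericVector dx = make4(H, W, C, N);
  NumericVector dW = make4(k, k, Cg, Cout);
  NumericVector db(Cout);
  arma::mat Wmat(const_cast<double*>(Wt.begin()), k * k * Cg, Cout, false);
  arma::mat dWmat(dW.begin(), k * k * Cg, Cout, false);
  arma::mat M;

  for (int n = 0; n < N; ++n) {
    const double* xn = x.begin() + (size_t)n * HW * C;
    const double* dn = dout.begin() + (size_t)n * HW * Cout;
    double* dxn = dx.begin() + (size_t)n * HW * C;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, H, W, g * Cg, Cg, k, pad, M);
      arma::mat D(const_cast<double*>(dn) + (size_t)g * Og * HW, HW, Og,
                  false);
      dWmat.cols(g * Og, (g + 1) * Og - 1) += M.t() * D;
      arma::mat dM = D * Wmat.cols(g * Og, (g + 1) * Og - 1).t();
      col2im(dM, H, W, g * Cg, Cg, k, pad, dxn);
    }
    for (int o = 0; o < Cout; ++o) {
      const double* dc = dn + (size_t)o * HW;
      double s = 0.0;
      for (int p = 0; p < HW; ++p) s += dc[p];
      db[o] += s;
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k, int stride, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int HW = H * W;

  NumericVector out = make4(Ho, Wo, C, N);
  IntegerVector arg = make4i(Ho, Wo, C, N);  // linear index in input plane
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(n * C + c) * HW;
      double* oc = out.begin() + (size_t)(n * C + c) * Ho * Wo;
      int* ac = arg.begin() + (size_t)(n * C + c) * Ho * Wo;
      for (int jo = 0; jo < Wo; ++jo)
        for (int io = 0; io < Ho; ++io) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int b = 0; b < k; ++b) {
            const int j = jo * stride + b - pad;
            if (j < 0 || j >= W) continue;
            for (int a = 0; a < k; ++a) {
              const int i = io * stride + a - pad;
              if (i < 0 || i >= H) continue;
              const double v = xc[i + (size_t)j * H];
              if (v > best) { best = v; besti = i + j * H; }
            }
          }
          if (besti < 0) { best = 0.0; besti = 0; }  // fully-padded window
          oc[io + (size_t)jo * Ho] = best;
          ac[io + (size_t)jo * Ho] = besti;
        }
    }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dout, IntegerVector argmax, int H,
                             int W) {
  IntegerVector d = dout.attr("dim");
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  NumericVector dx = make4(H, W, C, N);
  const int HWo = Ho * Wo, HW = H * W;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* dc = dout.begin() + (size_t)(n * C + c) * HWo;
      const int* ac = argmax.begin() + (size_t)(n * C + c) * HWo;
      double* xc = dx.begin() + (size_t)(n * C + c) * HW;
      for (int p = 0; p < HWo; ++p) xc[ac[p]] += dc[p];
    }
  return dx;
}

// Connected-component labeling of a binary matrix, 4- or 8-connectivity.
// Labels are assigned in column-major scan order starting at 1.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> qi, qj;
  int next = 0;
  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = (connectivity == 8) ? 8 : 4;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      qi.clear(); qj.clear();
      qi.push_back(i); qj.push_back(j);
      lab(i, j) = next;
      while (!qi.empty()) {
        const int ci = qi.back(), cj = qj.back();
        qi.pop_back(); qj.pop_back();
        for (int t = 0; t < nn; ++t) {
          const int ni = ci + di8[t], nj = cj + dj8[t];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            qi.push_back(ni); qj.push_back(nj);
          }
        }
      }
    }
  return lab;
}
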