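// Low-level numeric kernels for the small CNNs and mask post-processing.
// Arrays follow R's column-major layout; image batches are [H, W, C, B].

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for a 3x3 kernel with zero padding 1, stride 1.
// Output column index: kh + 3*kw + 9*ic  (matches matrix(w, nrow = 9*C) in R).
static void im2col3(const double* x, int H, int W, int C, arma::mat& out) {
  for (int ic = 0; ic < C; ++ic) {
    const double* xc = x + (std::size_t)H * W * ic;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        double* o = out.colptr(kh + 3 * kw + 9 * ic);
        for (int w = 0; w < W; ++w) {
          int iw = w + kw - 1;
          double* ocol = o + (std::size_t)H * w;
          if (iw < 0 || iw >= W) {
            std::fill(ocol, ocol + H, 0.0);
            continue;
          }
          const double* src = xc + (std::size_t)H * iw;
          for (int h = 0; h < H; ++h) {
            int ih = h + kh - 1;
            ocol[h] = (ih < 0 || ih >= H) ? 0.0 : src[ih];
          }
        }
      }
    }
  }
}

// Adjoint of im2col3: scatter-add columns back onto the padded image grid.
static void col2im3(const arma::mat& cols, int H, int W, int C, double* dx) {
  for (int ic = 0; ic < C; ++ic) {
    double* xc = dx + (std::size_t)H * W * ic;
    for (int kw = 0; kw < 3; ++kw) {
      for (int kh = 0; kh < 3; ++kh) {
        const double* o = cols.colptr(kh + 3 * kw + 9 * ic);
        for (int w = 0; w < W; ++w) {
          int iw = w + kw - 1;
          if (iw < 0 || iw >= W) continue;
          const double* ocol = o + (std::size_t)H * w;
          double* dst = xc + (std::size_t)H * iw;
          for (int h = 0; h < H; ++h) {
            int ih = h + kh - 1;
            if (ih >= 0 && ih < H) dst[ih] += ocol[h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3], OC = wd[3];
  arma::mat Wm(w.begin(), 9 * C, OC, false, true);
  arma::rowvec bv(b.begin(), OC);
  NumericVector y((std::size_t)H * W * OC * B);
  y.attr("dim") = IntegerVector::create(H, W, OC, B);
  arma::mat cols(H * W, 9 * C);
  for (int bi = 0; bi < B; ++bi) {
    im2col3(x.begin() + (std::size_t)H * W * C * bi, H, W, C, cols);
    arma::mat Y = cols * Wm;
    Y.each_row() += bv;
    std::copy(Y.begin(), Y.end(), y.begin() + (std::size_t)H * W * OC * bi);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3], OC = wd[3];
  arma::mat Wm(w.begin(), 9 * C, OC, false, true);
  NumericVector dx((std::size_t)H * W * C * B);
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(OC);
  arma::mat dWm(dw.begin(), 9 * C, OC, false, true);
  arma::rowvec dbv(db.begin(), OC, false, true);
  arma::mat cols(H * W, 9 * C);
  for (int bi = 0; bi < B; ++bi) {
    im2col3(x.begin() + (std::size_t)H * W * C * bi, H, W, C, cols);
    arma::mat dYm(dy.begin() + (std::size_t)H * W * OC * bi, H * W, OC, false, true);
    dWm += cols.t() * dYm;
    dbv += arma::sum(dYm, 0);
    arma::mat dCols = dYm * Wm.t();
    col2im3(dCols, H, W, C, dx.begin() + (std::size_t)H * W * C * bi);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2. Ties keep the first element in column-major
// scan order so results are reproducible. idx holds 0-based linear offsets
// into x for the backward pass.
// [[Rcpp::export]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((std::size_t)Ho * Wo * C * B);
  IntegerVector idx(y.size());
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  const double* xp = x.begin();
  std::size_t o = 0;
  for (int bi = 0; bi < B; ++bi)
    for (int c = 0; c < C; ++c) {
      std::size_t base = (std::size_t)H * W * (c + (std::size_t)C * bi);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho, ++o) {
          std::size_t best = base + 2 * ho + (std::size_t)H * (2 * wo);
          double bv = xp[best];
          const int dh[3] = {1, 0, 1}, dw_[3] = {0, 1, 1};
          for (int k = 0; k < 3; ++k) {
            std::size_t cand = base + (2 * ho + dh[k]) + (std::size_t)H * (2 * wo + dw_[k]);
            if (xp[cand] > bv) { bv = xp[cand]; best = cand; }
          }
          y[o] = bv;
          idx[o] = (int)best;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  std::size_t n = (std::size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// Nearest-neighbour upsampling by integer factor f.
// [[Rcpp::export]]
NumericVector upsample_fwd(NumericVector x, int f) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Ho = H * f, Wo = W * f;
  NumericVector y((std::size_t)Ho * Wo * C * B);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  for (int bi = 0; bi < B; ++bi)
    for (int c = 0; c < C; ++c) {
      std::size_t xb = (std::size_t)H * W * (c + (std::size_t)C * bi);
      std::size_t yb = (std::size_t)Ho * Wo * (c + (std::size_t)C * bi);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          y[yb + ho + (std::size_t)Ho * wo] = x[xb + ho / f + (std::size_t)H * (wo / f)];
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample_bwd(NumericVector dy, int f) {
  IntegerVector yd = dy.attr("dim");
  int Ho = yd[0], Wo = yd[1], C = yd[2], B = yd[3];
  int H = Ho / f, W = Wo / f;
  NumericVector dx((std::size_t)H * W * C * B);
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  for (int bi = 0; bi < B; ++bi)
    for (int c = 0; c < C; ++c) {
      std::size_t xb = (std::size_t)H * W * (c + (std::size_t)C * bi);
      std::size_t yb = (std::size_t)Ho * Wo * (c + (std::size_t)C * bi);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          dx[xb + ho / f + (std::size_t)H * (wo / f)] += dy[yb + ho + (std::size_t)Ho * wo];
    }
  return dx;
}

// Connected components of a binary raster, 8-connectivity, labels assigned
// in raster (column-major) first-encounter order starting at 1.
// [[Rcpp::export]]
IntegerMatrix label_components8(LogicalMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      if (!mask(h, w) || lab(h, w) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(h, w));
      lab(h, w) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dw = -1; dw <= 1; ++dw)
          for (int dh = -1; dh <= 1; ++dh) {
            int nh = p.first + dh, nw = p.second + dw;
            if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            if (mask(nh, nw) && lab(nh, nw) == 0) {
              lab(nh, nw) = next;
              stack.push_back(std::make_pair(nh, nw));
            }
          }
      }
    }
  return lab;
}
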