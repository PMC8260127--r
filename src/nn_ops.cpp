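// Low-level numerical kernels for the two-stage detector: im2col-based 2-D
// convolution with its gradient, bilinear ROI crop-and-resize with its
// gradient, and greedy non-maximum suppression. Feature volumes are R
// arrays dim c(H, W, C) (column-major), weights dim c(kh, kw, cin, cout);
// the flattened patch index ky + kh*(kx + kw*c) therefore matches the R
// array memory layout of the weight tensor exactly.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& X, int kh, int kw,
                        int stride, int pad, int oh, int ow) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int K = kh * kw * C, N = oh * ow;
  arma::mat cols(K, N, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& Xc = X.slice(c);
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const int krow = ky + kh * (kx + kw * c);
        for (int ox = 0; ox < ow; ++ox) {
          const int ix = ox * stride - pad + kx;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < oh; ++oy) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= H) continue;
            cols(krow, oy + oh * ox) = Xc(iy, ix);
          }
        }
      }
    }
  }
  return cols;
}

static void col2im(const arma::mat& cols, arma::cube& dX, int kh, int kw,
                   int stride, int pad, int oh, int ow) {
  const int H = dX.n_rows, W = dX.n_cols, C = dX.n_slices;
  for (int c = 0; c < C; ++c) {
    arma::mat& Dc = dX.slice(c);
    for (int kx = 0; kx < kw; ++kx) {
      for (int ky = 0; ky < kh; ++ky) {
        const int krow = ky + kh * (kx + kw * c);
        for (int ox = 0; ox < ow; ++ox) {
          const int ix = ox * stride - pad + kx;
          if (ix < 0 || ix >= W) continue;
          for (int oy = 0; oy < oh; ++oy) {
            const int iy = oy * stride - pad + ky;
            if (iy < 0 || iy >= H) continue;
            Dc(iy, ix) += cols(krow, oy + oh * ox);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_forward(const arma::cube& X, const arma::vec& Wflat,
                          const arma::vec& b, int kh, int kw, int cout,
                          int stride, int pad) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int oh = (H + 2 * pad - kh) / stride + 1;
  const int ow = (W + 2 * pad - kw) / stride + 1;
  const int K = kh * kw * C;
  arma::mat W2(const_cast<double*>(Wflat.memptr()), K, cout, false, true);
  arma::mat cols = im2col(X, kh, kw, stride, pad, oh, ow);
  arma::mat Yt = cols.t() * W2;               // (N, cout)
  Yt.each_row() += b.t();
  arma::cube Y(oh, ow, cout);
  std::memcpy(Y.memptr(), Yt.memptr(), sizeof(double) * Yt.n_elem);
  return Y;
}

// [[Rcpp::export]]
List conv2d_backward(const arma::cube& X, const arma::vec& Wflat,
                     const arma::cube& dY, int kh, int kw, int cout,
                     int stride, int pad, bool need_dx = true) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int oh = dY.n_rows, ow = dY.n_cols;
  const int K = kh * kw * C, N = oh * ow;
  arma::mat W2(const_cast<double*>(Wflat.memptr()), K, cout, false, true);
  arma::mat dYt(const_cast<double*>(dY.memptr()), N, cout, false, true);
  arma::mat cols = im2col(X, kh, kw, stride, pad, oh, ow);
  arma::mat dW2 = cols * dYt;                 // (K, cout)
  arma::vec db = arma::sum(dYt, 0).t();
  arma::cube dX(need_dx ? H : 0, need_dx ? W : 0, need_dx ? C : 0,
                arma::fill::zeros);
  if (need_dx) {
    arma::mat dcols = W2 * dYt.t();           // (K, N)
    col2im(dcols, dX, kh, kw, stride, pad, oh, ow);
  }
  return List::create(_["dX"] = dX, _["dW"] = dW2, _["db"] = db);
}

// Bilinear crop-and-resize of `pool x pool` grids from a feature volume.
// Boxes are in image pixel coordinates (half-open); `stride` maps them to
// feature coordinates. Returns cube (pool, pool, C * n_rois).
// [[Rcpp::export]]
arma::cube roi_crop_forward(const arma::cube& F, const arma::mat& rois,
                            double stride, int pool) {
  const int h = F.n_rows, w = F.n_cols, C = F.n_slices;
  const int n = rois.n_rows;
  arma::cube out(pool, pool, C * n, arma::fill::zeros);
  for (int r = 0; r < n; ++r) {
    const double x0 = rois(r, 0) / stride, y0 = rois(r, 1) / stride;
    const double x1 = rois(r, 2) / stride, y1 = rois(r, 3) / stride;
    const double bw = (x1 - x0) / pool, bh = (y1 - y0) / pool;
    for (int j = 0; j < pool; ++j) {
      double fx = x0 + (j + 0.5) * bw - 0.5;
      fx = std::min(std::max(fx, 0.0), (double)(w - 1));
      const int ix = std::min((int)std::floor(fx), w - 2 >= 0 ? w - 2 : 0);
      const double tx = w > 1 ? fx - ix : 0.0;
      for (int i = 0; i < pool; ++i) {
        double fy = y0 + (i + 0.5) * bh - 0.5;
        fy = std::min(std::max(fy, 0.0), (double)(h - 1));
        const int iy = std::min((int)std::floor(fy), h - 2 >= 0 ? h - 2 : 0);
        const double ty = h > 1 ? fy - iy : 0.0;
        for (int c = 0; c < C; ++c) {
          const arma::mat& Fc = F.slice(c);
          const double v =
            (1 - ty) * (1 - tx) * Fc(iy, ix) +
            (1 - ty) * tx * Fc(iy, std::min(ix + 1, w - 1)) +
            ty * (1 - tx) * Fc(std::min(iy + 1, h - 1), ix) +
            ty * tx * Fc(std::min(iy + 1, h - 1), std::min(ix + 1, w - 1));
          out(i, j, c + C * r) = v;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube roi_crop_backward(const arma::cube& F, const arma::mat& rois,
                             double stride, int pool, const arma::cube& dOut) {
  const int h = F.n_rows, w = F.n_cols, C = F.n_slices;
  const int n = rois.n_rows;
  arma::cube dF(h, w, C, arma::fill::zeros);
  for (int r = 0; r < n; ++r) {
    const double x0 = rois(r, 0) / stride, y0 = rois(r, 1) / stride;
    const double x1 = rois(r, 2) / stride, y1 = rois(r, 3) / stride;
    const double bw = (x1 - x0) / pool, bh = (y1 - y0) / pool;
    for (int j = 0; j < pool; ++j) {
      double fx = x0 + (j + 0.5) * bw - 0.5;
      fx = std::min(std::max(fx, 0.0), (double)(w - 1));
      const int ix = std::min((int)std::floor(fx), w - 2 >= 0 ? w - 2 : 0);
      const double tx = w > 1 ? fx - ix : 0.0;
      for (int i = 0; i < pool; ++i) {
        double fy = y0 + (i + 0.5) * bh - 0.5;
        fy = std::min(std::max(fy, 0.0), (double)(h - 1));
        const int iy = std::min((int)std::floor(fy), h - 2 >= 0 ? h - 2 : 0);
        const double ty = h > 1 ? fy - iy : 0.0;
        for (int c = 0; c < C; ++c) {
          const double g = dOut(i, j, c + C * r);
          arma::mat& Dc = dF.slice(c);
          Dc(iy, ix) += (1 - ty) * (1 - tx) * g;
          Dc(iy, std::min(ix + 1, w - 1)) += (1 - ty) * tx * g;
          Dc(std::min(iy + 1, h - 1), ix) += ty * (1 - tx) * g;
          Dc(std::min(iy + 1, h - 1), std::min(ix + 1, w - 1)) += ty * tx * g;
        }
      }
    }
  }
  return dF;
}

// Greedy NMS on one class: keep the highest-scoring box, drop boxes whose
// IoU with a kept box exceeds `thr`. Returns 1-based kept indices in
// descending score order.
// [[Rcpp::export]]
IntegerVector nms_indices(const arma::mat& boxes, const arma::vec& scores,
                          double thr) {
  const int n = boxes.n_rows;
  arma::uvec ord = arma::sort_index(scores, "descend");
  std::vector<bool> removed(n, false);
  std::vector<int> keep;
  arma::vec area = (boxes.col(2) - boxes.col(0)) % (boxes.col(3) - boxes.col(1));
  for (int oi = 0; oi < n; ++oi) {
    const int i = ord(oi);
    if (removed[i]) continue;
    keep.push_back(i + 1);
    for (int oj = oi + 1; oj < n; ++oj) {
      const int j = ord(oj);
      if (removed[j]) continue;
      const double ix = std::min(boxes(i, 2), boxes(j, 2)) -
                        std::max(boxes(i, 0), boxes(j, 0));
      const double iy = std::min(boxes(i, 3), boxes(j, 3)) -
                        std::max(boxes(i, 1), boxes(j, 1));
      if (ix <= 0 || iy <= 0) continue;
      const double inter = ix * iy;
      const double u = area(i) + area(j) - inter;
      if (u > 0 && inter / u > thr) removed[j] = true;
    }
  }
  return wrap(keep);
}
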