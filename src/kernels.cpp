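// Low-level numerical kernels: same-padding 2-D convolution (im2col + GEMM)
// with its gradients, 2x2 max pooling, 2x2 nearest-neighbour upsampling,
// seeded region growing, and truncated-window local statistics.
//
// Array convention: images are H x W matrices (row = y, top-left origin);
// feature maps are H x W x C cubes. Convolution weights are stored as a
// (k*k*Cin) x Cout matrix whose rows follow the im2col column order laid
// out below (channel-major, then dy, then dx).

#include <RcppArmadillo.h>
#include <deque>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices, p = (k - 1) / 2;
  arma::mat col(H * W, k * k * Cin, arma::fill::zeros);
  int idx = 0;
  for (int c = 0; c < Cin; ++c) {
    for (int dj = -p; dj <= p; ++dj) {
      for (int di = -p; di <= p; ++di) {
        arma::mat sh(H, W, arma::fill::zeros);
        const int r0 = std::max(0, -di), r1 = std::min(H, H - di);
        const int c0 = std::max(0, -dj), c1 = std::min(W, W - dj);
        if (r1 > r0 && c1 > c0)
          sh.submat(r0, c0, r1 - 1, c1 - 1) =
            x.slice(c).submat(r0 + di, c0 + dj, r1 - 1 + di, c1 - 1 + dj);
        col.col(idx++) = arma::vectorise(sh);
      }
    }
  }
  return col;
}

// [[Rcpp::export(name = ".conv_fw")]]
arma::cube conv_fw(const arma::cube& x, const arma::mat& w,
                   const arma::rowvec& b, const int k) {
  const int H = x.n_rows, W = x.n_cols, Cout = w.n_cols;
  arma::mat y = im2col(x, k) * w;
  y.each_row() += b;
  arma::cube out(H, W, Cout);
  for (int c = 0; c < Cout; ++c) out.slice(c) = arma::reshape(y.col(c), H, W);
  return out;
}

// [[Rcpp::export(name = ".conv_bw")]]
List conv_bw(const arma::cube& x, const arma::mat& w, const arma::cube& dy,
             const int k, const bool need_dx) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int Cout = dy.n_slices, p = (k - 1) / 2;
  arma::mat dym(H * W, Cout);
  for (int c = 0; c < Cout; ++c) dym.col(c) = arma::vectorise(dy.slice(c));
  arma::mat dW = im2col(x, k).t() * dym;
  arma::rowvec db = arma::sum(dym, 0);
  arma::cube dx(H, W, Cin, arma::fill::zeros);
  if (need_dx) {
    arma::mat dcol = dym * w.t();   // (H*W) x (k*k*Cin)
    int idx = 0;
    for (int c = 0; c < Cin; ++c) {
      for (int dj = -p; dj <= p; ++dj) {
        for (int di = -p; di <= p; ++di) {
          arma::mat g = arma::reshape(dcol.col(idx++), H, W);
          const int r0 = std::max(0, -di), r1 = std::min(H, H - di);
          const int c0 = std::max(0, -dj), c1 = std::min(W, W - dj);
          if (r1 > r0 && c1 > c0)
            dx.slice(c).submat(r0 + di, c0 + dj, r1 - 1 + di, c1 - 1 + dj) +=
              g.submat(r0, c0, r1 - 1, c1 - 1);
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling, stride 2; H and W must be even. idx records the argmax
// position within each 2x2 block (0 = tl, 1 = bl, 2 = tr, 3 = br,
// column-major within the block) for the backward pass.
// [[Rcpp::export(name = ".maxpool_fw")]]
List maxpool_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(H / 2, W / 2, C), idx(H / 2, W / 2, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W / 2; ++j) {
      for (int i = 0; i < H / 2; ++i) {
        double v[4] = {x(2 * i, 2 * j, c), x(2 * i + 1, 2 * j, c),
                       x(2 * i, 2 * j + 1, c), x(2 * i + 1, 2 * j + 1, c)};
        int a = 0;
        for (int t = 1; t < 4; ++t) if (v[t] > v[a]) a = t;
        y(i, j, c) = v[a];
        idx(i, j, c) = a;
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool_bw")]]
arma::cube maxpool_bw(const arma::cube& dy, const arma::cube& idx) {
  const int h = dy.n_rows, w = dy.n_cols, C = dy.n_slices;
  arma::cube dx(2 * h, 2 * w, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        const int a = (int) idx(i, j, c);
        dx(2 * i + (a % 2), 2 * j + (a / 2), c) += dy(i, j, c);
      }
  return dx;
}

// [[Rcpp::export(name = ".upsample_fw")]]
arma::cube upsample_fw(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v; y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export(name = ".upsample_bw")]]
arma::cube upsample_bw(const arma::cube& dy) {
  const int H = dy.n_rows / 2, W = dy.n_cols / 2, C = dy.n_slices;
  arma::cube dx(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

// Seeded region growing with a 4-connected FIFO queue. Seeds are accepted
// unconditionally; a candidate is accepted when |I - mean(region)| <= tol,
// where the mean is either the running mean of all accepted pixels
// (running = true) or the fixed mean of the seed set. Determinism: seeds are
// processed in the row-major order given; neighbours are examined in
// row-major order (up, left, right, down); each pixel is examined at most
// once. The comparison carries a 1e-12 guard so that accumulation rounding
// of the running mean cannot break exact (tolerance 0) growth.
// [[Rcpp::export(name = ".region_grow")]]
LogicalMatrix region_grow(const arma::mat& img, const IntegerMatrix seeds,
                          const double tol, const bool running) {
  const int H = img.n_rows, W = img.n_cols;
  LogicalMatrix out(H, W);
  std::vector<char> seen((size_t) H * W, 0);
  std::deque<long> q;
  double sum = 0.0; long n = 0;
  for (int s = 0; s < seeds.nrow(); ++s) {
    const int r = seeds(s, 0), c = seeds(s, 1);
    if (r < 0 || r >= H || c < 0 || c >= W) stop("seed outside image bounds");
    const long id = (long) r * W + c;
    if (seen[id]) continue;
    seen[id] = 1; out(r, c) = true;
    sum += img(r, c); n += 1;
    q.push_back(id);
  }
  double mean = sum / n;
  while (!q.empty()) {
    const long id = q.front(); q.pop_front();
    const int r = (int) (id / W), c = (int) (id % W);
    const int nr[4] = {r - 1, r, r, r + 1};
    const int nc[4] = {c, c - 1, c + 1, c};
    for (int t = 0; t < 4; ++t) {
      const int rr = nr[t], cc = nc[t];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      const long nid = (long) rr * W + cc;
      if (seen[nid]) continue;
      seen[nid] = 1;
      if (std::abs(img(rr, cc) - mean) <= tol + 1e-12) {
        out(rr, cc) = true;
        if (running) { sum += img(rr, cc); n += 1; mean = sum / n; }
        q.push_back(nid);
      }
    }
  }
  return out;
}

// Local mean / min / max over a square window of odd side `win`, truncated
// at the image border (statistics are taken over window ∩ image domain).
// [[Rcpp::export(name = ".local_stats")]]
List local_stats(const arma::mat& img, const int win) {
  const int H = img.n_rows, W = img.n_cols, p = (win - 1) / 2;
  // integral image for the truncated-window mean
  arma::mat S(H + 1, W + 1, arma::fill::zeros);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      S(i + 1, j + 1) = img(i, j) + S(i, j + 1) + S(i + 1, j) - S(i, j);
  arma::mat mu(H, W), mn(H, W), mx(H, W);
  for (int j = 0; j < W; ++j) {
    const int c0 = std::max(0, j - p), c1 = std::min(W - 1, j + p);
    for (int i = 0; i < H; ++i) {
      const int r0 = std::max(0, i - p), r1 = std::min(H - 1, i + p);
      const double s = S(r1 + 1, c1 + 1) - S(r0, c1 + 1) - S(r1 + 1, c0) + S(r0, c0);
      mu(i, j) = s / ((r1 - r0 + 1) * (c1 - c0 + 1));
    }
  }
  // separable truncated min/max: rows then columns
  arma::mat rmn(H, W), rmx(H, W);
  for (int i = 0; i < H; ++i)
    for (int j = 0; j < W; ++j) {
      const int c0 = std::max(0, j - p), c1 = std::min(W - 1, j + p);
      double lo = img(i, c0), hi = img(i, c0);
      for (int t = c0 + 1; t <= c1; ++t) {
        lo = std::min(lo, img(i, t)); hi = std::max(hi, img(i, t));
      }
      rmn(i, j) = lo; rmx(i, j) = hi;
    }
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      const int r0 = std::max(0, i - p), r1 = std::min(H - 1, i + p);
      double lo = rmn(r0, j), hi = rmx(r0, j);
      for (int t = r0 + 1; t <= r1; ++t) {
        lo = std::min(lo, rmn(t, j)); hi = std::max(hi, rmx(t, j));
      }
      mn(i, j) = lo; mx(i, j) = hi;
    }
  return List::create(_["mean"] = mu, _["min"] = mn, _["max"] = mx);
}
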