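// Forward pass of the random-kernel convolutional feature extractor.
// Convolution is implemented as im2col + GEMM so the per-patch cost is
// dominated by BLAS matrix products. Indexing follows the printed node
// formula c_{x,y} = sum_{m,n} Theta_{x+m-1, y+n-1} * p_{m,n}: a plain
// cross-correlation, no kernel flip.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Valid cross-correlation of a (h x w x cin) stack with a kernel matrix
// W of shape (r*r*cin x cout), column order (kr fast, kc, cin), followed
// by bias add and ReLU.
static arma::cube conv_relu_core(const arma::cube& x, const arma::mat& W,
                                 const arma::vec& b, int r) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int oh = h - r + 1, ow = w - r + 1;
  if (oh < 1 || ow < 1)
    stop("input spatial size (%d x %d) smaller than kernel (%d x %d)", h, w, r, r);
  if ((int)W.n_rows != r * r * cin)
    stop("kernel matrix rows (%d) do not match r*r*cin (%d)", (int)W.n_rows, r * r * cin);

  arma::mat cols(oh * ow, r * r * cin);
  for (int ci = 0; ci < cin; ++ci)
    for (int kc = 0; kc < r; ++kc)
      for (int kr = 0; kr < r; ++kr)
        cols.col(kr + r * kc + r * r * ci) =
          arma::vectorise(x.slice(ci).submat(kr, kc, kr + oh - 1, kc + ow - 1));

  arma::mat out = cols * W;
  out.each_row() += b.t();
  out.transform([](double v) { return v > 0.0 ? v : 0.0; });

  arma::cube y(oh, ow, W.n_cols);
  for (arma::uword j = 0; j < W.n_cols; ++j)
    y.slice(j) = arma::reshape(out.col(j), oh, ow);
  return y;
}

// Per-channel block maximum; trailing rows/cols that do not fill a full
// window are dropped (floor semantics).
static arma::cube max_pool_core(const arma::cube& x, int size, int stride) {
  const int oh = (int)((x.n_rows - size) / stride) + 1;
  const int ow = (int)((x.n_cols - size) / stride) + 1;
  if (oh < 1 || ow < 1) stop("pooling window larger than input");
  arma::cube y(oh, ow, x.n_slices);
  for (arma::uword c = 0; c < x.n_slices; ++c)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i)
        y(i, j, c) = x.slice(c)
          .submat(i * stride, j * stride, i * stride + size - 1, j * stride + size - 1)
          .max();
  return y;
}

static arma::vec gap_core(const arma::cube& x) {
  arma::vec v(x.n_slices);
  for (arma::uword c = 0; c < x.n_slices; ++c) v(c) = arma::mean(arma::mean(x.slice(c)));
  return v;
}

// One siamese branch: conv/ReLU + max-pool alternating, pooling after
// every convolution except the last, then global average pooling.
static arma::vec branch_core(const arma::mat& patch, const std::vector<arma::mat>& Ws,
                             const std::vector<arma::vec>& bs, int r,
                             int pool_size, int pool_stride) {
  arma::cube x(patch.n_rows, patch.n_cols, 1);
  x.slice(0) = patch;
  const size_t L = Ws.size();
  for (size_t l = 0; l < L; ++l) {
    x = conv_relu_core(x, Ws[l], bs[l], r);
    if (l + 1 < L) x = max_pool_core(x, pool_size, pool_stride);
  }
  return gap_core(x);
}

static void unpack_bank(List Ws_r, List bs_r, std::vector<arma::mat>& Ws,
                        std::vector<arma::vec>& bs) {
  for (int l = 0; l < Ws_r.size(); ++l) {
    Ws.push_back(as<arma::mat>(Ws_r[l]));
    bs.push_back(as<arma::vec>(bs_r[l]));
  }
}

// [[Rcpp::export]]
arma::cube cpp_conv_relu(const arma::cube& x, const arma::mat& W,
                         const arma::vec& b, int r) {
  return conv_relu_core(x, W, b, r);
}

// [[Rcpp::export]]
arma::cube cpp_max_pool(const arma::cube& x, int size, int stride) {
  return max_pool_core(x, size, stride);
}

// [[Rcpp::export]]
arma::vec cpp_gap(const arma::cube& x) { return gap_core(x); }

// [[Rcpp::export]]
arma::vec cpp_branch(const arma::mat& patch, List Ws_r, List bs_r, int r,
                     int pool_size, int pool_stride) {
  std::vector<arma::mat> Ws; std::vector<arma::vec> bs;
  unpack_bank(Ws_r, bs_r, Ws, bs);
  return branch_core(patch, Ws, bs, r, pool_size, pool_stride);
}

// Feature matrix for a batch of patch pairs: row i is the concatenation
// [branch(A_i), branch(B_i)], both branches sharing the same kernels.
// [[Rcpp::export]]
arma::mat cpp_pair_features(const arma::cube& pa, const arma::cube& pb,
                            List Ws_r, List bs_r, int r,
                            int pool_size, int pool_stride) {
  std::vector<arma::mat> Ws; std::vector<arma::vec> bs;
  unpack_bank(Ws_r, bs_r, Ws, bs);
  const arma::uword n = pa.n_slices;
  const arma::uword d = Ws.back().n_cols;
  arma::mat H(n, 2 * d);
  for (arma::uword i = 0; i < n; ++i) {
    H(i, arma::span(0, d - 1)) =
      branch_core(pa.slice(i), Ws, bs, r, pool_size, pool_stride).t();
    H(i, arma::span(d, 2 * d - 1)) =
      branch_core(pb.slice(i), Ws, bs, r, pool_size, pool_stride).t();
  }
  return H;
}

// Shared-pyramid dense scoring. Patch windows whose origins agree
// modulo the cumulative pooling factor see pooling grids at identical
// alignment, so one conv/pool pyramid over the whole (cropped) padded
// image serves every such patch: its GAP features are box sums over the
// last conv map, and the per-branch score contribution is the same box
// sum applied to the beta-weighted channel combination. Identical
// arithmetic to per-patch evaluation at a fraction of the cost.
static arma::mat branch_contrib_map(const arma::mat& img,
                                    const std::vector<arma::mat>& Ws,
                                    const std::vector<arma::vec>& bs, int r,
                                    int pool_size, int pool_stride,
                                    const arma::vec& w, int gap_win) {
  arma::cube x(img.n_rows, img.n_cols, 1);
  x.slice(0) = img;
  const size_t L = Ws.size();
  for (size_t l = 0; l + 1 < L; ++l) {
    x = conv_relu_core(x, Ws[l], bs[l], r);
    x = max_pool_core(x, pool_size, pool_stride);
  }
  x = conv_relu_core(x, Ws[L - 1], bs[L - 1], r);
  arma::mat m(x.n_rows, x.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < x.n_slices; ++c) m += w(c) * x.slice(c);
  // valid box sum over gap_win x gap_win windows via integral image
  arma::mat sat = arma::cumsum(arma::cumsum(m, 0), 1);
  const int oh = m.n_rows - gap_win + 1, ow = m.n_cols - gap_win + 1;
  arma::mat out(oh, ow);
  for (int j = 0; j < ow; ++j)
    for (int i = 0; i < oh; ++i) {
      double s = sat(i + gap_win - 1, j + gap_win - 1);
      if (i > 0) s -= sat(i - 1, j + gap_win - 1);
      if (j > 0) s -= sat(i + gap_win - 1, j - 1);
      if (i > 0 && j > 0) s += sat(i - 1, j - 1);
      out(i, j) = s;
    }
  return out / (double)(gap_win * gap_win);
}

// [[Rcpp::export]]
arma::mat cpp_dense_scores(const arma::mat& apad, const arma::mat& bpad,
                           List Ws_r, List bs_r, int r,
                           int pool_size, int pool_stride, int patch,
                           const arma::uvec& orows, const arma::uvec& ocols,
                           const arma::vec& beta) {
  std::vector<arma::mat> Ws; std::vector<arma::vec> bs;
  unpack_bank(Ws_r, bs_r, Ws, bs);
  const size_t L = Ws.size();
  const arma::uword d = Ws.back().n_cols;
  if (beta.n_elem != 2 * d) stop("beta length does not match feature dimension");

  int factor = 1, t = patch;
  for (size_t l = 0; l < L; ++l) {
    t = t - r + 1;
    if (l + 1 < L) { t = (t - pool_size) / pool_stride + 1; factor *= pool_stride; }
  }
  const int gap_win = t;
  if (gap_win < 1) stop("patch too small for the network depth");

  arma::mat scores(orows.n_elem, ocols.n_elem);
  std::vector<int> rcls(orows.n_elem), ccls(ocols.n_elem);
  for (arma::uword i = 0; i < orows.n_elem; ++i) rcls[i] = orows(i) % factor;
  for (arma::uword j = 0; j < ocols.n_elem; ++j) ccls[j] = ocols(j) % factor;

  for (int sr = 0; sr < factor; ++sr) {
    bool any_r = false;
    for (int c : rcls) if (c == sr) { any_r = true; break; }
    if (!any_r) continue;
    for (int sc = 0; sc < factor; ++sc) {
      bool any_c = false;
      for (int c : ccls) if (c == sc) { any_c = true; break; }
      if (!any_c) continue;
      arma::mat suba = apad.submat(sr, sc, apad.n_rows - 1, apad.n_cols - 1);
      arma::mat subb = bpad.submat(sr, sc, bpad.n_rows - 1, bpad.n_cols - 1);
      arma::mat ca = branch_contrib_map(suba, Ws, bs, r, pool_size, pool_stride,
                                        beta.subvec(0, d - 1), gap_win);
      arma::mat cb = branch_contrib_map(subb, Ws, bs, r, pool_size, pool_stride,
                                        beta.subvec(d, 2 * d - 1), gap_win);
      for (arma::uword j = 0; j < ocols.n_elem; ++j) {
        if (ccls[j] != sc) continue;
        const arma::uword pj = (ocols(j) - sc) / factor;
        for (arma::uword i = 0; i < orows.n_elem; ++i) {
          if (rcls[i] != sr) continue;
          const arma::uword pi = (orows(i) - sr) / factor;
          if (pi >= ca.n_rows || pj >= ca.n_cols) stop("dense grid out of range");
          double s = ca(pi, pj) + cb(pi, pj);
          scores(i, j) = std::min(1.0, std::max(0.0, s));
        }
      }
    }
  }
  return scores;
}

// Dense scoring over a grid of patch positions on pre-padded sources.
// rows/cols are 0-based top-left corners of patch windows in the padded
// images; returns raw scores features' * beta clamped to [0,1].
// [[Rcpp::export]]
arma::mat cpp_score_grid(const arma::mat& apad, const arma::mat& bpad,
                         List Ws_r, List bs_r, int r,
                         int pool_size, int pool_stride, int patch,
                         const arma::uvec& rows, const arma::uvec& cols,
                         const arma::vec& beta) {
  std::vector<arma::mat> Ws; std::vector<arma::vec> bs;
  unpack_bank(Ws_r, bs_r, Ws, bs);
  const arma::uword d = Ws.back().n_cols;
  if (beta.n_elem != 2 * d) stop("beta length does not match feature dimension");
  arma::mat scores(rows.n_elem, cols.n_elem);
  for (arma::uword jc = 0; jc < cols.n_elem; ++jc) {
    for (arma::uword ir = 0; ir < rows.n_elem; ++ir) {
      const arma::uword i0 = rows(ir), j0 = cols(jc);
      arma::vec fa = branch_core(apad.submat(i0, j0, i0 + patch - 1, j0 + patch - 1),
                                 Ws, bs, r, pool_size, pool_stride);
      arma::vec fb = branch_core(bpad.submat(i0, j0, i0 + patch - 1, j0 + patch - 1),
                                 Ws, bs, r, pool_size, pool_stride);
      double s = arma::dot(fa, beta.subvec(0, d - 1)) +
                 arma::dot(fb, beta.subvec(d, 2 * d - 1));
      scores(ir, jc) = std::min(1.0, std::max(0.0, s));
    }
  }
  return scores;
}
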