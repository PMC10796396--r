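// Compute kernel for the 15-layer scalogram CNN.
//
// Layer stack (stride-1 'same' convolutions, 2x2/2 max pooling):
//   [conv -> ReLU -> cross-channel LRN -> pool] x2,
//   [conv -> ReLU -> pool], dropout, fully-connected(2), softmax.
// Forward and backward passes run per sample; convolutions use im2col plus
// one matrix product so BLAS does the heavy lifting. The R side owns weight
// initialisation, shuffling, dropout masks and the SGD-with-momentum update,
// keeping all randomness in R's seeded RNG.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using namespace arma;

// im2col for stride-1 convolution with zero padding.
// Row layout: c * k*k + dj * k + di  (channel-major, then kernel column, row).
static mat im2col(const cube& in, int k, int pad) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  mat cols(k * k * C, H * W, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int row = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, pad - di);
          const int i1 = std::min(H - 1, H - 1 + pad - di);
          for (int i = i0; i <= i1; ++i) {
            cols(row, j * H + i) = in(i + di - pad, sj, c);
          }
        }
      }
    }
  }
  return cols;
}

static void col2im_add(const mat& dcols, cube& din, int k, int pad) {
  const int H = din.n_rows, W = din.n_cols, C = din.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int row = c * k * k + dj * k + di;
        for (int j = 0; j < W; ++j) {
          const int sj = j + dj - pad;
          if (sj < 0 || sj >= W) continue;
          const int i0 = std::max(0, pad - di);
          const int i1 = std::min(H - 1, H - 1 + pad - di);
          for (int i = i0; i <= i1; ++i) {
            din(i + di - pad, sj, c) += dcols(row, j * H + i);
          }
        }
      }
    }
  }
}

// out(:,:,f) from row f of Wm * cols (columns indexed j*H + i, column-major).
static cube conv_fwd(const mat& cols, const mat& Wm, const vec& bias,
                     int H, int W) {
  mat o = Wm * cols;
  o.each_col() += bias;
  const int F = Wm.n_rows;
  cube out(H, W, F);
  for (int f = 0; f < F; ++f) out.slice(f) = reshape(o.row(f), H, W);
  return out;
}

// Cross-channel (local response) normalisation:
//   b_c = a_c / (k0 + (alpha/n) * sum_{|j-c| <= n/2} a_j^2)^beta
static cube lrn_fwd(const cube& a, cube& den, int win, double k0,
                    double alpha, double beta) {
  const int C = a.n_slices, half = win / 2;
  cube sq = a % a;
  den.set_size(size(a));
  for (int c = 0; c < C; ++c) {
    mat s(a.n_rows, a.n_cols, fill::zeros);
    for (int j = std::max(0, c - half); j <= std::min(C - 1, c + half); ++j)
      s += sq.slice(j);
    den.slice(c) = k0 + (alpha / win) * s;
  }
  return a % pow(den, -beta);
}

static cube lrn_bwd(const cube& a, const cube& b, const cube& den,
                    const cube& db, int win, double alpha, double beta) {
  const int C = a.n_slices, half = win / 2;
  cube t = db % b / den;
  cube da(size(a));
  for (int c = 0; c < C; ++c) {
    mat s(a.n_rows, a.n_cols, fill::zeros);
    for (int j = std::max(0, c - half); j <= std::min(C - 1, c + half); ++j)
      s += t.slice(j);
    da.slice(c) = db.slice(c) % pow(den.slice(c), -beta)
      - (2.0 * alpha * beta / win) * (a.slice(c) % s);
  }
  return da;
}

static cube maxpool_fwd(const cube& in, umat& idx, int p) {
  const int H = in.n_rows, W = in.n_cols, C = in.n_slices;
  const int Ho = H / p, Wo = W / p;
  cube out(Ho, Wo, C);
  idx.set_size(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        double best = -datum::inf;
        uword bi = 0;
        for (int dj = 0; dj < p; ++dj) {
          for (int di = 0; di < p; ++di) {
            const uword ii = i * p + di, jj = j * p + dj;
            const double v = in(ii, jj, c);
            if (v > best) { best = v; bi = jj * H + ii; }
          }
        }
        out(i, j, c) = best;
        idx(j * Ho + i, c) = bi;
      }
    }
  }
  return out;
}

static cube maxpool_bwd(const cube& dout, const umat& idx, int H, int W) {
  const int C = dout.n_slices, Ho = dout.n_rows, Wo = dout.n_cols;
  cube din(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        din.slice(c)(idx(j * Ho + i, c)) += dout(i, j, c);
  return din;
}

static mat grad_rows(const cube& d) {
  const int F = d.n_slices, HW = d.n_rows * d.n_cols;
  mat out(F, HW);
  for (int f = 0; f < F; ++f)
    out.row(f) = vectorise(d.slice(f)).t();
  return out;
}

// x: H x W x B input batch (single channel), pixels already scaled to [0,1].
// labels: 0 = non-intake, 1 = intake (ignored when compute_grad is false).
// dropout_mask: D x B inverted-dropout multipliers (all ones at inference).
// sample_w: per-sample loss weights (inverse class frequency, mean ~1).
// [[Rcpp::export]]
List cnn_batch(const arma::cube& x, const arma::ivec& labels, List weights,
               List par, const arma::mat& dropout_mask,
               const arma::vec& sample_w, bool compute_grad) {
  const int B = x.n_slices, H = x.n_rows, W = x.n_cols;

  const mat W1 = weights["W1"]; const vec b1 = weights["b1"];
  const mat W2 = weights["W2"]; const vec b2 = weights["b2"];
  const mat W3 = weights["W3"]; const vec b3 = weights["b3"];
  const mat Wf = weights["Wf"]; const vec bf = weights["bf"];

  const int k1 = par["k1"], k2 = par["k2"], k3 = par["k3"];
  const int pool = par["pool"], lrn_win = par["lrn_window"];
  const double lrn_k = par["lrn_k"], lrn_a = par["lrn_alpha"],
               lrn_b = par["lrn_beta"];
  const int p1 = (k1 - 1) / 2, p2 = (k2 - 1) / 2, p3 = (k3 - 1) / 2;

  mat gW1(size(W1), fill::zeros), gW2(size(W2), fill::zeros),
      gW3(size(W3), fill::zeros), gWf(size(Wf), fill::zeros);
  vec gb1(size(b1), fill::zeros), gb2(size(b2), fill::zeros),
      gb3(size(b3), fill::zeros), gbf(size(bf), fill::zeros);

  mat probs(B, 2);
  double loss = 0.0, wsum = 0.0;

  for (int s = 0; s < B; ++s) {
    cube a0(H, W, 1);
    a0.slice(0) = x.slice(s);

    // block 1: conv -> ReLU -> LRN -> pool
    mat cols1 = im2col(a0, k1, p1);
    cube z1 = conv_fwd(cols1, W1, b1, H, W);
    cube r1 = clamp(z1, 0.0, datum::inf);
    cube den1;
    cube l1 = lrn_fwd(r1, den1, lrn_win, lrn_k, lrn_a, lrn_b);
    umat idx1;
    cube q1 = maxpool_fwd(l1, idx1, pool);

    // block 2
    mat cols2 = im2col(q1, k2, p2);
    cube z2 = conv_fwd(cols2, W2, b2, q1.n_rows, q1.n_cols);
    cube r2 = clamp(z2, 0.0, datum::inf);
    cube den2;
    cube l2 = lrn_fwd(r2, den2, lrn_win, lrn_k, lrn_a, lrn_b);
    umat idx2;
    cube q2 = maxpool_fwd(l2, idx2, pool);

    // block 3: conv -> ReLU -> pool
    mat cols3 = im2col(q2, k3, p3);
    cube z3 = conv_fwd(cols3, W3, b3, q2.n_rows, q2.n_cols);
    cube r3 = clamp(z3, 0.0, datum::inf);
    umat idx3;
    cube q3 = maxpool_fwd(r3, idx3, pool);

    // dropout (inverted) -> fully connected -> softmax
    vec v = vectorise(q3);
    vec vd = v % dropout_mask.col(s);
    vec z = Wf * vd + bf;
    const double m = z.max();
    vec e = exp(z - m);
    vec p = e / accu(e);
    probs(s, 0) = p(0);
    probs(s, 1) = p(1);

    if (!compute_grad) continue;

    const int y = labels(s);
    const double w = sample_w(s);
    loss += -w * std::log(std::max(p(y), 1e-12));
    wsum += w;

    vec dz = p;
    dz(y) -= 1.0;
    dz *= w;
    gWf += dz * vd.t();
    gbf += dz;
    vec dv = (Wf.t() * dz) % dropout_mask.col(s);
    cube dq3(dv.memptr(), q3.n_rows, q3.n_cols, q3.n_slices);

    cube dr3 = maxpool_bwd(dq3, idx3, r3.n_rows, r3.n_cols);
    cube dz3 = dr3;
    dz3.elem(find(z3 <= 0)).zeros();
    mat d3 = grad_rows(dz3);
    gW3 += d3 * cols3.t();
    gb3 += sum(d3, 1);
    mat dcols3 = W3.t() * d3;
    cube dq2(q2.n_rows, q2.n_cols, q2.n_slices, fill::zeros);
    col2im_add(dcols3, dq2, k3, p3);

    cube dl2 = maxpool_bwd(dq2, idx2, l2.n_rows, l2.n_cols);
    cube dr2 = lrn_bwd(r2, l2, den2, dl2, lrn_win, lrn_a, lrn_b);
    cube dz2 = dr2;
    dz2.elem(find(z2 <= 0)).zeros();
    mat d2 = grad_rows(dz2);
    gW2 += d2 * cols2.t();
    gb2 += sum(d2, 1);
    mat dcols2 = W2.t() * d2;
    cube dq1(q1.n_rows, q1.n_cols, q1.n_slices, fill::zeros);
    col2im_add(dcols2, dq1, k2, p2);

    cube dl1 = maxpool_bwd(dq1, idx1, l1.n_rows, l1.n_cols);
    cube dr1 = lrn_bwd(r1, l1, den1, dl1, lrn_win, lrn_a, lrn_b);
    cube dz1 = dr1;
    dz1.elem(find(z1 <= 0)).zeros();
    mat d1 = grad_rows(dz1);
    gW1 += d1 * cols1.t();
    gb1 += sum(d1, 1);
  }

  if (!compute_grad) return List::create(_["probs"] = probs);

  const double denom = std::max(wsum, 1e-12);
  List grads = List::create(
    _["W1"] = gW1 / B, _["b1"] = gb1 / B,
    _["W2"] = gW2 / B, _["b2"] = gb2 / B,
    _["W3"] = gW3 / B, _["b3"] = gb3 / B,
    _["Wf"] = gWf / B, _["bf"] = gbf / B);
  return List::create(_["loss"] = loss / denom,
                      _["probs"] = probs,
                      _["grads"] = grads);
}
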