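// Vectorized building blocks for the small convolutional regressor:
// im2col 3x3 valid convolutions and 2x2 max-pooling, forward and backward.
// Layout convention (shared with the R level): activations are N x
// (positions * channels) matrices, channel-major with row-major positions
// inside each channel; idx matrices hold 1-based input column indices per
// (output position, kernel element * input channel).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_conv_fwd(const arma::mat& x, const arma::imat& idx,
                  const arma::mat& w, const arma::vec& b) {
  const arma::uword n = x.n_rows;
  const arma::uword p_out = idx.n_rows;
  const arma::uword k = idx.n_cols;
  const arma::uword f = w.n_cols;

  arma::mat P(n * p_out, k);
  for (arma::uword kk = 0; kk < k; ++kk) {
    for (arma::uword p = 0; p < p_out; ++p) {
      P.submat(n * p, kk, n * p + n - 1, kk) = x.col(idx(p, kk) - 1);
    }
  }
  arma::mat Z = P * w;
  Z.each_row() += b.t();
  arma::mat A = arma::clamp(Z, 0.0, arma::datum::inf);
  // reshape (n*p_out) x f -> n x (p_out*f); column-major memory already
  // matches, so just reinterpret
  arma::mat Amat(A.memptr(), n, p_out * f);
  return List::create(_["P"] = P, _["Z"] = Z, _["A"] = Amat);
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::mat& da_mat, const arma::mat& Z,
                  const arma::mat& P, const arma::imat& idx,
                  const arma::mat& w, int n_in, bool need_dx,
                  int ncol_x) {
  const arma::uword n = (arma::uword)n_in;
  const arma::uword p_out = idx.n_rows;
  const arma::uword k = idx.n_cols;
  const arma::uword f = w.n_cols;

  arma::mat dz(const_cast<double*>(da_mat.memptr()), n * p_out, f);
  dz = dz % (Z > 0);
  arma::mat dW = P.t() * dz;
  arma::rowvec db = arma::sum(dz, 0);

  List out = List::create(_["dW"] = dW, _["db"] = db);
  if (need_dx) {
    arma::mat dp = dz * w.t();
    arma::mat dx(n, (arma::uword)ncol_x, arma::fill::zeros);
    for (arma::uword kk = 0; kk < k; ++kk) {
      for (arma::uword p = 0; p < p_out; ++p) {
        dx.col(idx(p, kk) - 1) += dp.submat(n * p, kk, n * p + n - 1, kk);
      }
    }
    out["dx"] = dx;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_pool_fwd(const arma::mat& x, const arma::imat& gathers) {
  // gathers: (p_out*c) x 4 matrix of 1-based input columns
  const arma::uword n = x.n_rows;
  const arma::uword m = gathers.n_rows;
  arma::mat A(n, m);
  arma::imat which(n, m);
  for (arma::uword j = 0; j < m; ++j) {
    for (arma::uword i = 0; i < n; ++i) {
      double best = x(i, gathers(j, 0) - 1);
      int bg = 1;
      for (int g = 1; g < 4; ++g) {
        double v = x(i, gathers(j, g) - 1);
        if (v > best) { best = v; bg = g + 1; }
      }
      A(i, j) = best;
      which(i, j) = bg;
    }
  }
  return List::create(_["A"] = A, _["which"] = which);
}

// [[Rcpp::export]]
arma::mat cpp_pool_bwd(const arma::mat& dm, const arma::imat& which,
                       const arma::imat& gathers, int ncol_x) {
  const arma::uword n = dm.n_rows;
  const arma::uword m = gathers.n_rows;
  arma::mat dx(n, (arma::uword)ncol_x, arma::fill::zeros);
  for (arma::uword j = 0; j < m; ++j) {
    for (arma::uword i = 0; i < n; ++i) {
      dx(i, gathers(j, which(i, j) - 1) - 1) += dm(i, j);
    }
  }
  return dx;
}

// ---- fused batch step -------------------------------------------------
// Full forward + backward for one minibatch, entirely in C++, returning
// only the loss and the (small) weight gradients. Mirrors the modular R
// path (conv_forward/pool_forward/cnn_backward) exactly; the R path is
// retained for gradient checking.

namespace {

struct ConvCache { arma::mat P, Z, A; };

ConvCache conv_fwd_c(const arma::mat& x, const arma::imat& idx,
                     const arma::mat& w, const arma::vec& b) {
  const arma::uword n = x.n_rows, p_out = idx.n_rows, k = idx.n_cols,
                    f = w.n_cols;
  ConvCache cc;
  cc.P.set_size(n * p_out, k);
  for (arma::uword kk = 0; kk < k; ++kk)
    for (arma::uword p = 0; p < p_out; ++p)
      cc.P.submat(n * p, kk, n * p + n - 1, kk) = x.col(idx(p, kk) - 1);
  cc.Z = cc.P * w;
  cc.Z.each_row() += b.t();
  arma::mat A = arma::clamp(cc.Z, 0.0, arma::datum::inf);
  cc.A = arma::mat(A.memptr(), n, p_out * f);
  return cc;
}

arma::mat pool_fwd_c(const arma::mat& x, const arma::imat& gathers,
                     arma::imat& which) {
  const arma::uword n = x.n_rows, m = gathers.n_rows;
  arma::mat A(n, m);
  which.set_size(n, m);
  for (arma::uword j = 0; j < m; ++j) {
    const double* c0 = x.colptr(gathers(j, 0) - 1);
    const double* c1 = x.colptr(gathers(j, 1) - 1);
    const double* c2 = x.colptr(gathers(j, 2) - 1);
    const double* c3 = x.colptr(gathers(j, 3) - 1);
    for (arma::uword i = 0; i < n; ++i) {
      double best = c0[i]; int bg = 1;
      if (c1[i] > best) { best = c1[i]; bg = 2; }
      if (c2[i] > best) { best = c2[i]; bg = 3; }
      if (c3[i] > best) { best = c3[i]; bg = 4; }
      A(i, j) = best; which(i, j) = bg;
    }
  }
  return A;
}

arma::mat pool_bwd_c(const arma::mat& dm, const arma::imat& which,
                     const arma::imat& gathers, arma::uword ncol_x) {
  const arma::uword n = dm.n_rows, m = gathers.n_rows;
  arma::mat dx(n, ncol_x, arma::fill::zeros);
  for (arma::uword j = 0; j < m; ++j)
    for (arma::uword i = 0; i < n; ++i)
      dx(i, gathers(j, which(i, j) - 1) - 1) += dm(i, j);
  return dx;
}

void conv_bwd_c(const arma::mat& da_mat, const ConvCache& cc,
                const arma::imat& idx, const arma::mat& w, arma::uword n,
                arma::mat& dW, arma::rowvec& db, arma::mat* dx,
                arma::uword ncol_x) {
  const arma::uword p_out = idx.n_rows, k = idx.n_cols, f = w.n_cols;
  arma::mat dz(const_cast<double*>(da_mat.memptr()), n * p_out, f);
  dz = dz % (cc.Z > 0);
  dW = cc.P.t() * dz;
  db = arma::sum(dz, 0);
  if (dx) {
    arma::mat dp = dz * w.t();
    dx->zeros(n, ncol_x);
    for (arma::uword kk = 0; kk < k; ++kk)
      for (arma::uword p = 0; p < p_out; ++p)
        dx->col(idx(p, kk) - 1) += dp.submat(n * p, kk, n * p + n - 1, kk);
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_cnn_step(const List& w, const arma::mat& x, const arma::mat& y,
                  const List& arch_idx, bool hybrid, bool frozen_conv,
                  const Nullable<NumericMatrix>& phen_) {
  const arma::imat idx1 = as<arma::imat>(arch_idx["idx1"]);
  const arma::imat g1 = as<arma::imat>(arch_idx["g1"]);
  const arma::imat idx2 = as<arma::imat>(arch_idx["idx2"]);
  const arma::imat g2 = as<arma::imat>(arch_idx["g2"]);
  const arma::uword nc1 = as<int>(arch_idx["ncol1"]);   // conv1 input width
  const arma::uword nc2 = as<int>(arch_idx["ncol2"]);   // conv2 input width
  const arma::uword n = x.n_rows;

  ConvCache c1 = conv_fwd_c(x, idx1, as<arma::mat>(w["W1"]), as<arma::vec>(w["b1"]));
  arma::imat wh1;
  arma::mat a1 = pool_fwd_c(c1.A, g1, wh1);
  ConvCache c2 = conv_fwd_c(a1, idx2, as<arma::mat>(w["W2"]), as<arma::vec>(w["b2"]));
  arma::imat wh2;
  arma::mat flat = pool_fwd_c(c2.A, g2, wh2);

  List g;
  arma::mat pred, dflat;
  if (hybrid) {
    arma::mat phen = as<arma::mat>(phen_.get());
    arma::mat hin = arma::join_rows(flat, phen);
    arma::mat Wh1 = as<arma::mat>(w["Wh1"]), Wh2 = as<arma::mat>(w["Wh2"]),
              Wo = as<arma::mat>(w["Wo"]);
    arma::mat z1 = hin * Wh1; z1.each_row() += as<arma::rowvec>(w["bh1"]);
    arma::mat aa1 = arma::clamp(z1, 0.0, arma::datum::inf);
    arma::mat z2 = aa1 * Wh2; z2.each_row() += as<arma::rowvec>(w["bh2"]);
    arma::mat aa2 = arma::clamp(z2, 0.0, arma::datum::inf);
    pred = aa2 * Wo; pred.each_row() += as<arma::rowvec>(w["bo"]);

    arma::mat dpred = 2.0 * (pred - y) / (double)y.n_elem;
    g["dWo"] = arma::mat(aa2.t() * dpred);
    g["dbo"] = arma::rowvec(arma::sum(dpred, 0));
    arma::mat da2 = dpred * Wo.t(); da2 = da2 % (z2 > 0);
    g["dWh2"] = arma::mat(aa1.t() * da2);
    g["dbh2"] = arma::rowvec(arma::sum(da2, 0));
    arma::mat da1 = da2 * Wh2.t(); da1 = da1 % (z1 > 0);
    g["dWh1"] = arma::mat(hin.t() * da1);
    g["dbh1"] = arma::rowvec(arma::sum(da1, 0));
    arma::mat dhin = da1 * Wh1.t();
    dflat = dhin.cols(0, flat.n_cols - 1);
  } else {
    arma::mat Wd = as<arma::mat>(w["Wd"]), Wo = as<arma::mat>(w["Wo"]);
    arma::mat zd = flat * Wd; zd.each_row() += as<arma::rowvec>(w["bd"]);
    arma::mat ad = arma::clamp(zd, 0.0, arma::datum::inf);
    pred = ad * Wo; pred.each_row() += as<arma::rowvec>(w["bo"]);

    arma::mat dpred = 2.0 * (pred - y) / (double)y.n_elem;
    g["dWo"] = arma::mat(ad.t() * dpred);
    g["dbo"] = arma::rowvec(arma::sum(dpred, 0));
    arma::mat dad = dpred * Wo.t(); dad = dad % (zd > 0);
    g["dWd"] = arma::mat(flat.t() * dad);
    g["dbd"] = arma::rowvec(arma::sum(dad, 0));
    dflat = dad * Wd.t();
  }

  if (!frozen_conv) {
    arma::mat dp2 = pool_bwd_c(dflat, wh2, g2, c2.A.n_cols);
    arma::mat dW2; arma::rowvec db2; arma::mat dx2;
    conv_bwd_c(dp2, c2, idx2, as<arma::mat>(w["W2"]), n, dW2, db2, &dx2, nc2);
    g["dW2"] = dW2; g["db2"] = db2;
    arma::mat dp1 = pool_bwd_c(dx2, wh1, g1, c1.A.n_cols);
    arma::mat dW1; arma::rowvec db1;
    conv_bwd_c(dp1, c1, idx1, as<arma::mat>(w["W1"]), n, dW1, db1, nullptr, nc1);
    g["dW1"] = dW1; g["db1"] = db1;
  }

  double loss = arma::accu(arma::square(pred - y)) / (double)y.n_elem;
  return List::create(_["loss"] = loss, _["grads"] = g);
}

// [[Rcpp::export]]
arma::mat cpp_cnn_predict(const List& w, const arma::mat& x,
                          const List& arch_idx, bool hybrid,
                          const Nullable<NumericMatrix>& phen_) {
  const arma::imat idx1 = as<arma::imat>(arch_idx["idx1"]);
  const arma::imat g1 = as<arma::imat>(arch_idx["g1"]);
  const arma::imat idx2 = as<arma::imat>(arch_idx["idx2"]);
  const arma::imat g2 = as<arma::imat>(arch_idx["g2"]);
  ConvCache c1 = conv_fwd_c(x, idx1, as<arma::mat>(w["W1"]), as<arma::vec>(w["b1"]));
  arma::imat wh1;
  arma::mat a1 = pool_fwd_c(c1.A, g1, wh1);
  ConvCache c2 = conv_fwd_c(a1, idx2, as<arma::mat>(w["W2"]), as<arma::vec>(w["b2"]));
  arma::imat wh2;
  arma::mat flat = pool_fwd_c(c2.A, g2, wh2);
  arma::mat pred;
  if (hybrid) {
    arma::mat phen = as<arma::mat>(phen_.get());
    arma::mat hin = arma::join_rows(flat, phen);
    arma::mat z1 = hin * as<arma::mat>(w["Wh1"]); z1.each_row() += as<arma::rowvec>(w["bh1"]);
    arma::mat z2 = arma::clamp(z1, 0.0, arma::datum::inf) * as<arma::mat>(w["Wh2"]);
    z2.each_row() += as<arma::rowvec>(w["bh2"]);
    pred = arma::clamp(z2, 0.0, arma::datum::inf) * as<arma::mat>(w["Wo"]);
  } else {
    arma::mat zd = flat * as<arma::mat>(w["Wd"]); zd.each_row() += as<arma::rowvec>(w["bd"]);
    pred = arma::clamp(zd, 0.0, arma::datum::inf) * as<arma::mat>(w["Wo"]);
  }
  pred.each_row() += as<arma::rowvec>(w["bo"]);
  return pred;
}
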