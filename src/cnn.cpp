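// Convolutional optimal-temperature regressor: forward pass and analytic
// gradients. Architecture (valid-padding 1-d convolutions over the one-hot
// residue axis):
//   conv(k, F, relu) -> maxpool(p) -> conv(k, F, relu) -> maxpool(p)
//   -> flatten -> dense(H, relu) -> dropout -> dense(H, relu) -> dropout
//   -> dense(1, linear)
// Convolutions are evaluated as im2col + GEMM. All stochastic pieces
// (dropout masks, shuffling, initial weights) are supplied from R so the
// whole training run is reproducible from one R-side seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// X: P x C input; returns (P-k+1) x (k*C); row j holds X[j..j+k-1, ]
// flattened blockwise by kernel offset.
static mat im2col(const mat& X, int k) {
  const int P = X.n_rows, C = X.n_cols, Q = P - k + 1;
  mat out(Q, k * C);
  for (int o = 0; o < k; ++o)
    out.cols(o * C, o * C + C - 1) = X.rows(o, o + Q - 1);
  return out;
}

// Adjoint of im2col: scatter column-block gradients back onto the input.
static mat col2im(const mat& dC, int k, int P, int C) {
  const int Q = dC.n_rows;
  mat dX(P, C, fill::zeros);
  for (int o = 0; o < k; ++o)
    dX.rows(o, o + Q - 1) += dC.cols(o * C, o * C + C - 1);
  return dX;
}

// Non-overlapping max pooling along rows; records argmax rows for backprop.
static mat maxpool(const mat& A, int pool, umat& arg) {
  const int F = A.n_cols, Q = A.n_rows / pool;
  mat out(Q, F);
  arg.set_size(Q, F);
  for (int t = 0; t < Q; ++t)
    for (int f = 0; f < F; ++f) {
      int base = t * pool, bi = base;
      double best = A(base, f);
      for (int u = 1; u < pool; ++u)
        if (A(base + u, f) > best) { best = A(base + u, f); bi = base + u; }
      out(t, f) = best;
      arg(t, f) = bi;
    }
  return out;
}

struct Params {
  mat W1, W2, W3, W4;
  vec b1, b2, b3, b4, w5;
  double b5;
};

static Params unpack(const Rcpp::List& par) {
  Params p;
  p.W1 = Rcpp::as<mat>(par["W1"]); p.b1 = Rcpp::as<vec>(par["b1"]);
  p.W2 = Rcpp::as<mat>(par["W2"]); p.b2 = Rcpp::as<vec>(par["b2"]);
  p.W3 = Rcpp::as<mat>(par["W3"]); p.b3 = Rcpp::as<vec>(par["b3"]);
  p.W4 = Rcpp::as<mat>(par["W4"]); p.b4 = Rcpp::as<vec>(par["b4"]);
  p.w5 = Rcpp::as<vec>(par["w5"]); p.b5 = Rcpp::as<double>(par["b5"]);
  return p;
}

// Forward pass for one encoded sequence (L x 20), no dropout.
static double forward_one(const mat& X, const Params& p, int k, int pool) {
  mat C1 = im2col(X, k);
  mat Z1 = C1 * p.W1;
  Z1.each_row() += p.b1.t();
  mat A1 = clamp(Z1, 0.0, datum::inf);
  umat arg1;
  mat M1 = maxpool(A1, pool, arg1);
  mat C2 = im2col(M1, k);
  mat Z2 = C2 * p.W2;
  Z2.each_row() += p.b2.t();
  mat A2 = clamp(Z2, 0.0, datum::inf);
  umat arg2;
  mat M2 = maxpool(A2, pool, arg2);
  vec z = vectorise(M2.t());  // position-major flatten
  vec h1 = clamp(p.W3.t() * z + p.b3, 0.0, datum::inf);
  vec h2 = clamp(p.W4.t() * h1 + p.b4, 0.0, datum::inf);
  return dot(p.w5, h2) + p.b5;
}

// [[Rcpp::export]]
arma::vec cnn_forward_cpp(const arma::cube& X, const Rcpp::List& par,
                          int kernel, int pool) {
  const Params p = unpack(par);
  const int n = X.n_slices;
  vec out(n);
  for (int i = 0; i < n; ++i)
    out(i) = forward_one(X.slice(i), p, kernel, pool);
  return out;
}

// Mean-squared-error loss and its gradients over a minibatch.
// D1, D2: n x H inverted-dropout masks (entries 0 or 1/(1-rate)).
// [[Rcpp::export]]
Rcpp::List cnn_grad_cpp(const arma::cube& X, const arma::vec& y,
                        const Rcpp::List& par, int kernel, int pool,
                        const arma::mat& D1, const arma::mat& D2) {
  const Params p = unpack(par);
  const int n = X.n_slices, k = kernel;

  mat gW1(size(p.W1), fill::zeros), gW2(size(p.W2), fill::zeros);
  mat gW3(size(p.W3), fill::zeros), gW4(size(p.W4), fill::zeros);
  vec gb1(size(p.b1), fill::zeros), gb2(size(p.b2), fill::zeros);
  vec gb3(size(p.b3), fill::zeros), gb4(size(p.b4), fill::zeros);
  vec gw5(size(p.w5), fill::zeros);
  double gb5 = 0.0, loss = 0.0;

  for (int i = 0; i < n; ++i) {
    const mat Xi = X.slice(i);
    // forward with caches
    mat C1 = im2col(Xi, k);
    mat Z1 = C1 * p.W1;
    Z1.each_row() += p.b1.t();
    mat A1 = clamp(Z1, 0.0, datum::inf);
    umat arg1;
    mat M1 = maxpool(A1, pool, arg1);
    mat C2 = im2col(M1, k);
    mat Z2 = C2 * p.W2;
    Z2.each_row() += p.b2.t();
    mat A2 = clamp(Z2, 0.0, datum::inf);
    umat arg2;
    mat M2 = maxpool(A2, pool, arg2);
    vec z = vectorise(M2.t());
    vec d1 = D1.row(i).t(), d2 = D2.row(i).t();
    vec a3 = p.W3.t() * z + p.b3;
    vec h1 = clamp(a3, 0.0, datum::inf) % d1;
    vec a4 = p.W4.t() * h1 + p.b4;
    vec h2 = clamp(a4, 0.0, datum::inf) % d2;
    double yhat = dot(p.w5, h2) + p.b5;

    double err = yhat - y(i);
    loss += err * err / n;
    double dy = 2.0 * err / n;

    // backward
    gw5 += dy * h2;
    gb5 += dy;
    vec dh2 = (dy * p.w5) % d2;
    vec da4 = dh2 % conv_to<vec>::from(a4 > 0);
    gW4 += h1 * da4.t();
    gb4 += da4;
    vec dh1 = (p.W4 * da4) % d1;
    vec da3 = dh1 % conv_to<vec>::from(a3 > 0);
    gW3 += z * da3.t();
    gb3 += da3;
    vec dz = p.W3 * da3;
    const int P4 = M2.n_rows, F = M2.n_cols;
    mat dM2(P4, F);
    for (int t = 0; t < P4; ++t)
      for (int f = 0; f < F; ++f) dM2(t, f) = dz(t * F + f);
    mat dA2(A2.n_rows, F, fill::zeros);
    for (int t = 0; t < P4; ++t)
      for (int f = 0; f < F; ++f) dA2(arg2(t, f), f) += dM2(t, f);
    mat dZ2 = dA2 % conv_to<mat>::from(Z2 > 0);
    gW2 += C2.t() * dZ2;
    gb2 += sum(dZ2, 0).t();
    mat dC2 = dZ2 * p.W2.t();
    mat dM1 = col2im(dC2, k, M1.n_rows, F);
    mat dA1(A1.n_rows, F, fill::zeros);
    const int P2 = M1.n_rows;
    for (int t = 0; t < P2; ++t)
      for (int f = 0; f < F; ++f) dA1(arg1(t, f), f) += dM1(t, f);
    mat dZ1 = dA1 % conv_to<mat>::from(Z1 > 0);
    gW1 += C1.t() * dZ1;
    gb1 += sum(dZ1, 0).t();
  }

  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("grads") = Rcpp::List::create(
      Rcpp::Named("W1") = gW1, Rcpp::Named("b1") = gb1,
      Rcpp::Named("W2") = gW2, Rcpp::Named("b2") = gb2,
      Rcpp::Named("W3") = gW3, Rcpp::Named("b3") = gb3,
      Rcpp::Named("W4") = gW4, Rcpp::Named("b4") = gb4,
      Rcpp::Named("w5") = gw5, Rcpp::Named("b5") = gb5));
}
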