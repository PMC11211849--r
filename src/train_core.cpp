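// Training core for the residual hypergraph convolutional network.
//
// The propagation operator A = Dv^{-1/2} H W De^{-1} H^T Dv^{-1/2} is
// applied through its bipartite factor B (A = B B^T), i.e. as the two-stage
// genes -> sets -> genes message passing, which is far cheaper than the
// materialized n x n product. Dropout masks are drawn from R's RNG in the
// same order as the R reference engine, so both engines are reproducible
// and comparable under one seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

inline mat propagate(const sp_mat& B, const mat& X) {
  return B * (B.t() * X);
}

inline void activate_inplace(mat& X, const int act) {
  if (act == 0) {                       // relu
    X.transform([](double v) { return v > 0.0 ? v : 0.0; });
  } else {                              // elu
    X.transform([](double v) { return v > 0.0 ? v : std::expm1(v); });
  }
}

// gradient of the activation expressed through its output y = sigma(x)
inline mat activate_grad(const mat& Y, const int act) {
  mat G(size(Y));
  if (act == 0) {
    G = conv_to<mat>::from(Y > 0.0);
  } else {
    G = Y;
    G.transform([](double v) { return v > 0.0 ? 1.0 : v + 1.0; });
  }
  return G;
}

struct Adam {
  mat m, v;
  explicit Adam(const mat& shape) : m(size(shape), fill::zeros),
                                    v(size(shape), fill::zeros) {}
  void step(mat& theta, const mat& g, double lr, int t) {
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    m = b1 * m + (1.0 - b1) * g;
    v = b2 * v + (1.0 - b2) * square(g);
    theta -= lr * (m / (1.0 - std::pow(b1, t))) /
             (sqrt(v / (1.0 - std::pow(b2, t))) + eps);
  }
};

}  // namespace

// [[Rcpp::export(name = ".train_core")]]
Rcpp::List train_core(const arma::sp_mat& B, arma::mat input_fc,
                      Rcpp::List thetas_in, arma::mat output_fc,
                      arma::vec output_bias,
                      const arma::uvec& label_idx,  // 0-based labeled genes
                      const arma::uvec& label_cls,  // 0/1 class per gene
                      const arma::vec& label_wts, double lr, int epochs,
                      double dropout, int act, double patience) {
  const uword n = input_fc.n_rows;
  const int L = thetas_in.size();
  std::vector<mat> thetas(L);
  for (int l = 0; l < L; ++l) thetas[l] = Rcpp::as<mat>(thetas_in[l]);

  Adam st_in(input_fc), st_out(output_fc), st_b(output_bias);
  std::vector<Adam> st_th;
  for (int l = 0; l < L; ++l) st_th.emplace_back(thetas[l]);

  const double wsum = accu(label_wts);
  std::vector<double> loss_trace;
  loss_trace.reserve(epochs);
  double best = datum::inf;
  int since_best = 0;

  std::vector<mat> layer_in(L), layer_prop(L);

  for (int epoch = 1; epoch <= epochs; ++epoch) {
    // forward
    mat X = input_fc;
    activate_inplace(X, act);
    mat mask;
    if (dropout > 0.0) {
      const double keep = 1.0 - dropout;
      mask.set_size(size(X));
      for (uword j = 0; j < mask.n_cols; ++j)
        for (uword i = 0; i < mask.n_rows; ++i)
          mask(i, j) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
      X %= mask;
    }
    for (int l = 0; l < L; ++l) {
      layer_in[l] = X;
      layer_prop[l] = propagate(B, X);
      X = layer_prop[l] * thetas[l] + X;
      activate_inplace(X, act);
    }
    mat logits = X * output_fc;
    logits.each_row() += output_bias.t();
    logits.each_col() -= max(logits, 1);
    mat Z = exp(logits);
    Z.each_col() /= sum(Z, 1);
    if (!Z.is_finite()) Rcpp::stop("non-finite values in forward pass");

    double loss = 0.0;
    for (uword k = 0; k < label_idx.n_elem; ++k) {
      double p = Z(label_idx[k], label_cls[k]);
      loss -= label_wts[k] * std::log(std::max(p, 1e-12));
    }
    loss /= wsum;
    if (!std::isfinite(loss)) Rcpp::stop("non-finite training loss");
    loss_trace.push_back(loss);

    // backward: dL/dlogits on labeled rows only
    mat dZ(n, 2, fill::zeros);
    for (uword k = 0; k < label_idx.n_elem; ++k) {
      const uword i = label_idx[k];
      const double w = label_wts[k] / wsum;
      dZ(i, 0) = Z(i, 0) * w;
      dZ(i, 1) = Z(i, 1) * w;
      dZ(i, label_cls[k]) -= w;
    }
    mat d_output_fc = X.t() * dZ;
    vec d_output_bias = sum(dZ, 0).t();
    mat dX = dZ * output_fc.t();
    std::vector<mat> d_thetas(L);
    for (int l = L - 1; l >= 0; --l) {
      const mat& Xout = (l == L - 1) ? X : layer_in[l + 1];
      mat dY = dX % activate_grad(Xout, act);
      d_thetas[l] = layer_prop[l].t() * dY;
      dX = propagate(B, dY * thetas[l].t()) + dY;
    }
    if (dropout > 0.0) dX %= mask;
    mat X1 = input_fc;
    activate_inplace(X1, act);
    mat d_input = dX % activate_grad(X1, act);

    st_in.step(input_fc, d_input, lr, epoch);
    for (int l = 0; l < L; ++l)
      st_th[l].step(thetas[l], d_thetas[l], lr, epoch);
    st_out.step(output_fc, d_output_fc, lr, epoch);
    {
      mat b = output_bias, g = d_output_bias;
      st_b.step(b, g, lr, epoch);
      output_bias = b;
    }

    if (std::isfinite(patience)) {
      if (loss < best - 1e-6) { best = loss; since_best = 0; }
      else if (++since_best >= patience) break;
    }
  }

  Rcpp::List thetas_out(L);
  for (int l = 0; l < L; ++l) thetas_out[l] = thetas[l];
  return Rcpp::List::create(
      Rcpp::Named("input_fc") = input_fc,
      Rcpp::Named("residual_thetas") = thetas_out,
      Rcpp::Named("output_fc") = output_fc,
      Rcpp::Named("output_bias") = Rcpp::NumericVector(output_bias.begin(),
                                                       output_bias.end()),
      Rcpp::Named("loss_trace") = loss_trace);
}
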