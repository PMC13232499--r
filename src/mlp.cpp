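// Single-hidden-layer ReLU multilayer perceptron for regression, trained by
// minibatch gradient descent with either AdamW (decoupled weight decay) or
// RMSprop, matching the two dataset presets.  Inputs are expected already
// standardised.  A dedicated Mersenne Twister (weight init, dropout masks,
// epoch shuffling) makes training deterministic for a given seed.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Opt {       // per-parameter optimiser state
  arma::mat m, v;
  Opt(int r, int c) : m(r, c, arma::fill::zeros), v(r, c, arma::fill::zeros) {}
};

static void step_adamw(arma::mat& w, const arma::mat& g, Opt& o, double lr,
                       double wd, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  o.m = b1 * o.m + (1 - b1) * g;
  o.v = b2 * o.v + (1 - b2) * (g % g);
  arma::mat mh = o.m / (1 - std::pow(b1, t));
  arma::mat vh = o.v / (1 - std::pow(b2, t));
  w -= lr * (mh / (arma::sqrt(vh) + eps) + wd * w);
}

static void step_rmsprop(arma::mat& w, const arma::mat& g, Opt& o, double lr) {
  const double alpha = 0.99, eps = 1e-8;
  o.v = alpha * o.v + (1 - alpha) * (g % g);
  w -= lr * g / (arma::sqrt(o.v) + eps);
}

// [[Rcpp::export]]
List train_mlp_cpp(const arma::mat& X, const arma::vec& y, int n_hidden,
                   double dropout, int epochs, double lr,
                   std::string optimizer, int batch_size, double weight_decay,
                   int seed) {
  const int n = X.n_rows, p = X.n_cols;
  std::mt19937 rng(static_cast<unsigned>(seed));
  auto runif = [&](double a, double b) {
    std::uniform_real_distribution<double> U(a, b);
    return U(rng);
  };
  // Kaiming-uniform initialisation
  arma::mat W1(p, n_hidden), w2(n_hidden, 1);
  arma::rowvec b1(n_hidden, arma::fill::zeros);
  double b2s = 0.0;
  const double lim1 = std::sqrt(6.0 / p), lim2 = std::sqrt(6.0 / n_hidden);
  for (arma::uword i = 0; i < W1.n_elem; ++i) W1(i) = runif(-lim1, lim1);
  for (arma::uword i = 0; i < w2.n_elem; ++i) w2(i) = runif(-lim2, lim2);

  Opt oW1(p, n_hidden), ob1(1, n_hidden), ow2(n_hidden, 1), ob2(1, 1);
  arma::mat b1m(1, n_hidden), b2m(1, 1);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  int t = 0;
  const bool adamw = (optimizer == "adamw");

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    for (int start = 0; start < n; start += batch_size) {
      const int end = std::min(start + batch_size, n);
      const int m = end - start;
      arma::uvec bi(m);
      for (int k = 0; k < m; ++k) bi[k] = order[start + k];
      arma::mat Xb = X.rows(bi);
      arma::vec yb = y.elem(bi);

      arma::mat Z = Xb * W1;
      Z.each_row() += b1;
      arma::mat H = arma::clamp(Z, 0.0, arma::datum::inf);
      arma::mat mask;
      if (dropout > 0) {                 // inverted dropout
        mask.set_size(H.n_rows, H.n_cols);
        std::uniform_real_distribution<double> U(0.0, 1.0);
        for (arma::uword i = 0; i < mask.n_elem; ++i)
          mask(i) = (U(rng) >= dropout) ? 1.0 / (1.0 - dropout) : 0.0;
        H %= mask;
      }
      arma::vec pred = H * w2 + b2s;
      arma::vec d = 2.0 * (pred - yb) / m;          // dMSE/dpred

      arma::mat gw2 = H.t() * d;
      double gb2 = arma::accu(d);
      arma::mat dH = d * w2.t();
      if (dropout > 0) dH %= mask;
      dH %= arma::conv_to<arma::mat>::from(Z > 0);
      arma::mat gW1 = Xb.t() * dH;
      arma::rowvec gb1 = arma::sum(dH, 0);

      ++t;
      b1m = arma::mat(b1); b2m(0, 0) = b2s;
      arma::mat gb1m = arma::mat(gb1), gb2m(1, 1); gb2m(0, 0) = gb2;
      if (adamw) {
        step_adamw(W1, gW1, oW1, lr, weight_decay, t);
        step_adamw(w2, gw2, ow2, lr, weight_decay, t);
        step_adamw(b1m, gb1m, ob1, lr, 0.0, t);
        step_adamw(b2m, gb2m, ob2, lr, 0.0, t);
      } else {
        step_rmsprop(W1, gW1, oW1, lr);
        step_rmsprop(w2, gw2, ow2, lr);
        step_rmsprop(b1m, gb1m, ob1, lr);
        step_rmsprop(b2m, gb2m, ob2, lr);
      }
      b1 = b1m.row(0); b2s = b2m(0, 0);
    }
  }
  return List::create(_["W1"] = W1, _["b1"] = arma::vec(b1.t()),
                      _["w2"] = arma::vec(w2.col(0)), _["b2"] = b2s);
}

// [[Rcpp::export]]
arma::vec predict_mlp_cpp(const arma::mat& X, const arma::mat& W1,
                          const arma::vec& b1, const arma::vec& w2,
                          double b2) {
  arma::mat Z = X * W1;
  Z.each_row() += b1.t();
  arma::mat H = arma::clamp(Z, 0.0, arma::datum::inf);
  return H * w2 + b2;
}
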