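#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Single-hidden-layer ReLU regression network trained with Adam on
// mean-squared error. Early stopping monitors validation MSE with a
// patience counter; the weights returned are those of the best
// validation epoch. All randomness (He-style scaled-uniform init,
// per-epoch minibatch shuffles) comes from a std::mt19937_64 seeded
// from R, so results are reproducible given the seed.

static double mse(const mat& X, const vec& y,
                  const mat& W1, const vec& b1,
                  const vec& w2, double b2) {
  mat H = X * W1.t();
  H.each_row() += b1.t();
  H.transform([](double v) { return v > 0.0 ? v : 0.0; });
  vec yhat = H * w2 + b2;
  vec r = yhat - y;
  return dot(r, r) / r.n_elem;
}

// [[Rcpp::export]]
Rcpp::List mlp_train_cpp(const arma::mat& Xtr, const arma::vec& ytr,
                         const arma::mat& Xval, const arma::vec& yval,
                         int hidden, double lr, int batch,
                         int max_epochs, int patience,
                         unsigned int seed) {
  const int n = Xtr.n_rows, p = Xtr.n_cols;
  std::mt19937_64 rng(seed);

  auto runif_pm = [&](double lim) {
    std::uniform_real_distribution<double> u(-lim, lim);
    return u(rng);
  };

  // He-style scaled uniform fan-in initialisation
  mat W1(hidden, p);
  double lim1 = std::sqrt(6.0 / p);
  for (uword i = 0; i < W1.n_elem; ++i) W1(i) = runif_pm(lim1);
  vec b1(hidden, fill::zeros);
  vec w2(hidden);
  double lim2 = std::sqrt(6.0 / hidden);
  for (uword i = 0; i < w2.n_elem; ++i) w2(i) = runif_pm(lim2);
  double b2 = 0.0;

  // Adam state
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  mat mW1(size(W1), fill::zeros), vW1(size(W1), fill::zeros);
  vec mb1(hidden, fill::zeros), vb1(hidden, fill::zeros);
  vec mw2(hidden, fill::zeros), vw2(hidden, fill::zeros);
  double mb2 = 0.0, vb2 = 0.0;
  long t = 0;

  std::vector<uword> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  std::vector<double> tr_curve, val_curve;
  double best_val = datum::inf;
  mat bW1 = W1; vec bb1 = b1, bw2 = w2; double bb2 = b2;
  int best_epoch = 0, wait = 0, epoch = 0;
  long n_iter = 0;

  for (epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    for (int start = 0; start < n; start += batch) {
      int stop = std::min(start + batch, n);
      int m = stop - start;
      uvec rows(m);
      for (int k = 0; k < m; ++k) rows[k] = idx[start + k];
      mat Xb = Xtr.rows(rows);
      vec yb = ytr.elem(rows);

      mat Z = Xb * W1.t();
      Z.each_row() += b1.t();
      mat H = Z;
      H.transform([](double v) { return v > 0.0 ? v : 0.0; });
      vec yhat = H * w2 + b2;
      vec d = (2.0 / m) * (yhat - yb);        // dL/dyhat

      vec gw2 = H.t() * d;
      double gb2 = accu(d);
      mat dH = d * w2.t();                    // m x hidden
      dH.elem(find(Z <= 0.0)).zeros();        // ReLU mask
      mat gW1 = dH.t() * Xb;
      vec gb1 = sum(dH, 0).t();

      ++t;
      double c1 = 1.0 - std::pow(beta1, (double)t);
      double c2 = 1.0 - std::pow(beta2, (double)t);
      auto adam_m = [&](mat& mm, mat& vv, const mat& g, mat& w) {
        mm = beta1 * mm + (1 - beta1) * g;
        vv = beta2 * vv + (1 - beta2) * square(g);
        w -= lr * (mm / c1) / (sqrt(vv / c2) + eps);
      };
      auto adam_v = [&](vec& mm, vec& vv, const vec& g, vec& w) {
        mm = beta1 * mm + (1 - beta1) * g;
        vv = beta2 * vv + (1 - beta2) * square(g);
        w -= lr * (mm / c1) / (sqrt(vv / c2) + eps);
      };
      adam_m(mW1, vW1, gW1, W1);
      adam_v(mb1, vb1, gb1, b1);
      adam_v(mw2, vw2, gw2, w2);
      mb2 = beta1 * mb2 + (1 - beta1) * gb2;
      vb2 = beta2 * vb2 + (1 - beta2) * gb2 * gb2;
      b2 -= lr * (mb2 / c1) / (std::sqrt(vb2 / c2) + eps);
      ++n_iter;
    }

    double trl = mse(Xtr, ytr, W1, b1, w2, b2);
    double vll = mse(Xval, yval, W1, b1, w2, b2);
    if (!std::isfinite(trl) || !std::isfinite(vll))
      Rcpp::stop("non-finite loss during training");
    tr_curve.push_back(trl);
    val_curve.push_back(vll);

    if (vll < best_val - 1e-12) {
      best_val = vll;
      bW1 = W1; bb1 = b1; bw2 = w2; bb2 = b2;
      best_epoch = epoch;
      wait = 0;
    } else {
      if (++wait >= patience) break;
    }
  }
  int stopped = std::min(epoch, max_epochs);

  return Rcpp::List::create(
    Rcpp::Named("W1") = bW1,
    Rcpp::Named("b1") = bb1,
    Rcpp::Named("w2") = bw2,
    Rcpp::Named("b2") = bb2,
    Rcpp::Named("train_loss") = tr_curve,
    Rcpp::Named("val_loss") = val_curve,
    Rcpp::Named("best_val") = best_val,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("stop_epoch") = stopped,
    Rcpp::Named("n_iter") = n_iter);
}
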