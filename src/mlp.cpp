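// One-hidden-layer binary MLP (ReLU hidden, sigmoid output) trained with
// minibatch Adam on binary cross-entropy. The whole training loop stays in
// compiled code with preallocated batch buffers; all randomness (weight
// init, epoch shuffling) comes from one std::mt19937 seeded from R.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace Rcpp;

namespace {

const double kProbEps = 1e-7; // clamp for the cross-entropy log

double bce(const arma::vec &p, const arma::vec &y) {
  arma::vec pc = arma::clamp(p, kProbEps, 1.0 - kProbEps);
  return -arma::mean(y % arma::log(pc) + (1.0 - y) % arma::log(1.0 - pc));
}

arma::vec forward(const arma::mat &X, const arma::mat &W1, const arma::rowvec &b1,
                  const arma::vec &w2, double b2) {
  arma::mat A1 = X * W1;
  A1.each_row() += b1;
  A1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  arma::vec z2 = A1 * w2 + b2;
  return 1.0 / (1.0 + arma::exp(-z2));
}

// element-wise Adam step with bias correction, in place
struct Adam {
  arma::mat m, v;
  Adam(arma::uword r, arma::uword c)
      : m(r, c, arma::fill::zeros), v(r, c, arma::fill::zeros) {}
  void step(arma::mat &w, const arma::mat &g, double lr, double b1, double b2,
            double eps, long t) {
    m *= b1;
    m += (1.0 - b1) * g;
    v *= b2;
    v += (1.0 - b2) * (g % g);
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    w -= (lr / c1) * (m / (arma::sqrt(v / c2) + eps));
  }
};

} // namespace

// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat &X, const arma::vec &y, int hidden,
                   int epochs, int batch_size, double lr, double beta1,
                   double beta2, double adam_eps, int seed,
                   const arma::mat &Xval, const arma::vec &yval) {
  const arma::uword n = X.n_rows, p = X.n_cols;
  const arma::uword h = (arma::uword)hidden;
  std::mt19937 rng((unsigned)seed);

  // Glorot-uniform initialization (column-major fill, so draws are
  // reproducible for a given seed and layer shape)
  auto runif = [&](double lim) {
    std::uniform_real_distribution<double> d(-lim, lim);
    return d(rng);
  };
  arma::mat W1(p, h);
  const double lim1 = std::sqrt(6.0 / (double)(p + h));
  for (arma::uword j = 0; j < h; ++j)
    for (arma::uword i = 0; i < p; ++i) W1(i, j) = runif(lim1);
  arma::rowvec b1(h, arma::fill::zeros);
  arma::vec w2(h);
  const double lim2 = std::sqrt(6.0 / (double)(h + 1));
  for (arma::uword i = 0; i < h; ++i) w2[i] = runif(lim2);
  double b2 = 0.0;

  Adam aW1(p, h), ab1(1, h), aw2(h, 1), ab2(1, 1);
  arma::mat b1m(1, h), w2m(h, 1), b2m(1, 1);
  b1m.row(0) = b1;
  w2m.col(0) = w2;
  b2m(0, 0) = b2;

  std::vector<arma::uword> idx(n);
  for (arma::uword i = 0; i < n; ++i) idx[i] = i;

  const arma::uword B0 = std::min<arma::uword>(n, (arma::uword)batch_size);
  arma::mat Xb(B0, p), Z1(B0, h), dZ1(B0, h), dW1(p, h), dW2(h, 1), db1m(1, h),
      db2m(1, 1);
  arma::vec yb(B0), z2(B0), prob(B0), dz2(B0);

  arma::vec loss_hist(epochs, arma::fill::zeros);
  arma::vec val_hist(epochs);
  val_hist.fill(NA_REAL);
  long t = 0;
  for (int e = 0; e < epochs; ++e) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double loss_sum = 0.0;
    for (arma::uword start = 0; start < n; start += B0) {
      const arma::uword stop = std::min(n, start + B0);
      const arma::uword B = stop - start;
      if (Xb.n_rows != B) {
        Xb.set_size(B, p);
        Z1.set_size(B, h);
        dZ1.set_size(B, h);
        yb.set_size(B);
      }
      for (arma::uword r = 0; r < B; ++r) {
        Xb.row(r) = X.row(idx[start + r]);
        yb[r] = y[idx[start + r]];
      }

      Z1 = Xb * W1;
      Z1.each_row() += b1m.row(0);
      dZ1 = Z1; // reuse as the ReLU activation buffer
      dZ1.transform([](double v) { return v > 0.0 ? v : 0.0; });
      z2 = dZ1 * w2m.col(0) + b2m(0, 0);
      prob = 1.0 / (1.0 + arma::exp(-z2));
      loss_sum += bce(prob, yb) * B;

      dz2 = (prob - yb) / (double)B;
      dW2 = dZ1.t() * dz2;
      db2m(0, 0) = arma::accu(dz2);
      // dZ1 = (dz2 * w2') masked by Z1 > 0
      for (arma::uword r = 0; r < B; ++r) {
        const double g = dz2[r];
        for (arma::uword c = 0; c < h; ++c) {
          dZ1(r, c) = Z1(r, c) > 0.0 ? g * w2m(c, 0) : 0.0;
        }
      }
      dW1 = Xb.t() * dZ1;
      db1m.row(0) = arma::sum(dZ1, 0);

      ++t;
      aW1.step(W1, dW1, lr, beta1, beta2, adam_eps, t);
      ab1.step(b1m, db1m, lr, beta1, beta2, adam_eps, t);
      aw2.step(w2m, dW2, lr, beta1, beta2, adam_eps, t);
      ab2.step(b2m, db2m, lr, beta1, beta2, adam_eps, t);
    }
    loss_hist[e] = loss_sum / (double)n;
    if (Xval.n_rows > 0)
      val_hist[e] =
          bce(forward(Xval, W1, b1m.row(0), w2m.col(0), b2m(0, 0)), yval);
  }

  return List::create(_["W1"] = W1, _["b1"] = arma::vec(b1m.row(0).t()),
                      _["w2"] = arma::vec(w2m.col(0)), _["b2"] = b2m(0, 0),
                      _["loss"] = loss_hist, _["val_loss"] = val_hist);
}

// [[Rcpp::export]]
arma::vec mlp_forward_cpp(const arma::mat &X, const arma::mat &W1,
                          const arma::vec &b1, const arma::vec &w2, double b2) {
  return forward(X, W1, arma::rowvec(b1.t()), w2, b2);
}
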