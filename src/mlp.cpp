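#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Self-contained PRNG (splitmix64 seeding + xorshift64*) so that training is
// bit-reproducible for a given integer seed, independent of R's RNG state and
// of the platform's rand().
namespace {

struct Xrng {
  uint64_t s;
  explicit Xrng(uint64_t seed) {
    // splitmix64 scrambles small/sequential seeds into well-mixed state
    uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x2545F4914F6CDD1DULL;
  }
  uint64_t next() {
    s ^= s >> 12;
    s ^= s << 25;
    s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform in [0, 1)
  double unif() {
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
  // uniform in [-h, h]
  double unif_sym(double h) { return (2.0 * unif() - 1.0) * h; }
  // integer in [0, n)
  int below(int n) { return (int)(unif() * n); }
};

inline double sigmoid_c(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// forward pass for one sample; returns output activation, fills hidden
inline double forward_one(const std::vector<double>& W,   // (n_in+1) x n_h, col-major
                          const std::vector<double>& V,   // n_h + 1
                          const double* x, int n_in, int n_h,
                          std::vector<double>& hidden) {
  for (int j = 0; j < n_h; ++j) {
    const double* wj = &W[(size_t)j * (n_in + 1)];
    double a = wj[n_in];  // bias row is last
    for (int i = 0; i < n_in; ++i) a += wj[i] * x[i];
    hidden[j] = sigmoid_c(a);
  }
  double a = V[n_h];
  for (int j = 0; j < n_h; ++j) a += V[j] * hidden[j];
  return sigmoid_c(a);
}

inline double mse_over(const std::vector<double>& W, const std::vector<double>& V,
                       const NumericMatrix& X, const NumericVector& y,
                       const IntegerVector& idx, int n_in, int n_h,
                       std::vector<double>& hidden, std::vector<double>& xbuf) {
  double acc = 0.0;
  for (int k = 0; k < idx.size(); ++k) {
    int r = idx[k];
    for (int i = 0; i < n_in; ++i) xbuf[i] = X(r, i);
    double out = forward_one(W, V, xbuf.data(), n_in, n_h, hidden);
    double e = out - y[r];
    acc += e * e;
  }
  return acc / idx.size();
}

}  // namespace

// Train a 3-layer (n_in - n_h - 1) sigmoid MLP by online backpropagation with
// momentum.  train_idx / test_idx are 0-based row indices into X.  Training
// stops at max_epochs, or once the best test-set MSE has failed to improve by
// at least min_improve over a sliding window of `window` epochs.  The model
// returned is the snapshot with the lowest test-set MSE.
// [[Rcpp::export(name = ".mlp_train_cpp")]]
List mlp_train_cpp(NumericMatrix X, NumericVector y,
                   IntegerVector train_idx, IntegerVector test_idx,
                   int n_hidden, int max_epochs, int window,
                   double min_improve, double lr, double momentum,
                   double init_halfwidth, double seed) {
  const int n_in = X.ncol();
  const int n_h = n_hidden;
  const int n_tr = train_idx.size();
  if (n_tr < 1 || test_idx.size() < 1)
    stop("training and test partitions must each be non-empty");

  Xrng rng((uint64_t)seed);

  const size_t nW = (size_t)(n_in + 1) * n_h;
  std::vector<double> W(nW), V(n_h + 1);
  std::vector<double> dW(nW, 0.0), dV(n_h + 1, 0.0);  // momentum terms
  for (size_t i = 0; i < nW; ++i) W[i] = rng.unif_sym(init_halfwidth);
  for (int j = 0; j <= n_h; ++j) V[j] = rng.unif_sym(init_halfwidth);

  std::vector<double> hidden(n_h), xbuf(n_in);
  std::vector<int> order(train_idx.begin(), train_idx.end());

  std::vector<double> train_mse, test_mse;
  train_mse.reserve(max_epochs);
  test_mse.reserve(max_epochs);

  std::vector<double> bestW = W, bestV = V;
  double best_test = R_PosInf;
  // early-stop anchor: the last epoch at which best test MSE improved by
  // >= min_improve relative to the anchored value
  double anchor = R_PosInf;
  int anchor_epoch = 0, stop_epoch = 0;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    // Fisher-Yates shuffle of the training order
    for (int k = n_tr - 1; k > 0; --k) {
      int j = rng.below(k + 1);
      std::swap(order[k], order[j]);
    }
    for (int k = 0; k < n_tr; ++k) {
      int r = order[k];
      for (int i = 0; i < n_in; ++i) xbuf[i] = X(r, i);
      double out = forward_one(W, V, xbuf.data(), n_in, n_h, hidden);
      double delta_out = (out - y[r]) * out * (1.0 - out);
      // output layer
      for (int j = 0; j < n_h; ++j) {
        double g = delta_out * hidden[j];
        dV[j] = -lr * g + momentum * dV[j];
      }
      double gb = delta_out;
      double dVb = -lr * gb + momentum * dV[n_h];
      // hidden layer (uses pre-update V)
      for (int j = 0; j < n_h; ++j) {
        double delta_h = delta_out * V[j] * hidden[j] * (1.0 - hidden[j]);
        double* wj = &W[(size_t)j * (n_in + 1)];
        double* dwj = &dW[(size_t)j * (n_in + 1)];
        for (int i = 0; i < n_in; ++i) {
          dwj[i] = -lr * delta_h * xbuf[i] + momentum * dwj[i];
          wj[i] += dwj[i];
        }
        dwj[n_in] = -lr * delta_h + momentum * dwj[n_in];
        wj[n_in] += dwj[n_in];
      }
      for (int j = 0; j < n_h; ++j) V[j] += dV[j];
      dV[n_h] = dVb;
      V[n_h] += dVb;
      if (!std::isfinite(out))
        stop("non-finite network output at epoch %d (learning rate %g)", epoch, lr);
    }

    double tr = mse_over(W, V, X, y, train_idx, n_in, n_h, hidden, xbuf);
    double te = mse_over(W, V, X, y, test_idx, n_in, n_h, hidden, xbuf);
    if (!std::isfinite(tr) || !std::isfinite(te))
      stop("non-finite MSE at epoch %d (learning rate %g)", epoch, lr);
    train_mse.push_back(tr);
    test_mse.push_back(te);

    if (te < best_test) {
      best_test = te;
      bestW = W;
      bestV = V;
    }
    if (epoch == 1 || anchor - best_test >= min_improve) {
      anchor = best_test;
      anchor_epoch = epoch;
    } else if (epoch - anchor_epoch >= window) {
      stop_epoch = epoch;
      break;
    }
    stop_epoch = epoch;
  }

  NumericMatrix Wout(n_in + 1, n_h);
  for (int j = 0; j < n_h; ++j)
    for (int i = 0; i <= n_in; ++i) Wout(i, j) = bestW[(size_t)j * (n_in + 1) + i];
  NumericVector Vout(n_h + 1);
  for (int j = 0; j <= n_h; ++j) Vout[j] = bestV[j];

  return List::create(
      _["input_weights"] = Wout, _["output_weights"] = Vout,
      _["train_mse_by_epoch"] = NumericVector(train_mse.begin(), train_mse.end()),
      _["test_mse_by_epoch"] = NumericVector(test_mse.begin(), test_mse.end()),
      _["stop_epoch"] = stop_epoch, _["best_test_mse"] = best_test);
}

// Forward pass of a trained model over the rows of X.
// [[Rcpp::export(name = ".mlp_predict_cpp")]]
NumericVector mlp_predict_cpp(NumericMatrix input_weights,
                              NumericVector output_weights, NumericMatrix X) {
  const int n_in = input_weights.nrow() - 1;
  const int n_h = input_weights.ncol();
  if (X.ncol() != n_in) stop("input has %d features; model expects %d", X.ncol(), n_in);
  std::vector<double> W((size_t)(n_in + 1) * n_h), V(n_h + 1);
  for (int j = 0; j < n_h; ++j)
    for (int i = 0; i <= n_in; ++i) W[(size_t)j * (n_in + 1) + i] = input_weights(i, j);
  for (int j = 0; j <= n_h; ++j) V[j] = output_weights[j];
  std::vector<double> hidden(n_h), xbuf(n_in);
  NumericVector out(X.nrow());
  for (int r = 0; r < X.nrow(); ++r) {
    for (int i = 0; i < n_in; ++i) xbuf[i] = X(r, i);
    out[r] = forward_one(W, V, xbuf.data(), n_in, n_h, hidden);
  }
  return out;
}
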