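#include <Rcpp.h>
using namespace Rcpp;

// Logistic activation.
static inline double sigm(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Forward pass of the 3-layer perceptron for one sample.
// W1: p x h, b1: h, W2: h, b2 scalar.
static double forward_one(const double* x, int p, int h,
                          const NumericMatrix& W1, const NumericVector& b1,
                          const NumericVector& W2, double b2,
                          std::vector<double>& hid) {
  double z = b2;
  for (int j = 0; j < h; ++j) {
    double a = b1[j];
    for (int i = 0; i < p; ++i) a += x[i] * W1(i, j);
    hid[j] = sigm(a);
    z += hid[j] * W2[j];
  }
  return sigm(z);
}

static double mse_on(const NumericMatrix& X, const NumericVector& y, int h,
                     const NumericMatrix& W1, const NumericVector& b1,
                     const NumericVector& W2, double b2) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> hid(h), xrow(p);
  double s = 0.0;
  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < p; ++i) xrow[i] = X(r, i);
    double o = forward_one(xrow.data(), p, h, W1, b1, W2, b2, hid);
    double e = o - y[r];
    s += e * e;
  }
  return s / n;
}

// Online backpropagation with momentum on squared error E = 0.5 (o - y)^2,
// logistic hidden and output units. The per-epoch sample order is a
// Fisher-Yates shuffle drawn from R's RNG stream (RNGScope), so training is
// fully determined by the R seed in force at the call. Tracks the test-set
// MSE per epoch and returns the weights at the best test error (early
// stopping with `patience` epochs of no improvement).
// [[Rcpp::export]]
List mlp_train_cpp(NumericMatrix Xtr, NumericVector ytr,
                   NumericMatrix Xte, NumericVector yte,
                   NumericMatrix W1, NumericVector b1,
                   NumericVector W2, double b2,
                   double eta, double alpha,
                   int max_epochs, int patience, bool early_stop) {
  int n = Xtr.nrow(), p = Xtr.ncol(), h = W1.ncol();
  // work on copies: never mutate the caller's weight objects in place
  W1 = clone(W1); b1 = clone(b1); W2 = clone(W2);
  NumericMatrix vW1(p, h); NumericVector vb1(h), vW2(h); double vb2 = 0.0;
  NumericMatrix bW1 = clone(W1); NumericVector bb1 = clone(b1);
  NumericVector bW2 = clone(W2); double bb2 = b2;
  std::vector<double> hid(h), xrow(p), dh(h);
  NumericVector trace(max_epochs, NA_REAL);
  double best = R_PosInf;
  int best_epoch = -1, since = 0, epochs_run = 0;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  RNGScope rng;

  for (int ep = 0; ep < max_epochs; ++ep) {
    // Fisher-Yates shuffle via R's RNG (matches sample.int semantics closely
    // enough for our purposes; determinism comes from the R seed)
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int s = 0; s < n; ++s) {
      int r = order[s];
      for (int i = 0; i < p; ++i) xrow[i] = Xtr(r, i);
      double o = forward_one(xrow.data(), p, h, W1, b1, W2, b2, hid);
      double dout = (o - ytr[r]) * o * (1.0 - o);
      for (int j = 0; j < h; ++j)
        dh[j] = dout * W2[j] * hid[j] * (1.0 - hid[j]);
      // momentum update: v <- alpha v - eta grad; w <- w + v
      for (int j = 0; j < h; ++j) {
        vW2[j] = alpha * vW2[j] - eta * dout * hid[j];
        W2[j] += vW2[j];
      }
      vb2 = alpha * vb2 - eta * dout;
      b2 += vb2;
      for (int j = 0; j < h; ++j) {
        for (int i = 0; i < p; ++i) {
          vW1(i, j) = alpha * vW1(i, j) - eta * dh[j] * xrow[i];
          W1(i, j) += vW1(i, j);
        }
        vb1[j] = alpha * vb1[j] - eta * dh[j];
        b1[j] += vb1[j];
      }
    }
    epochs_run = ep + 1;
    double te = (Xte.nrow() > 0)
      ? mse_on(Xte, yte, h, W1, b1, W2, b2)
      : mse_on(Xtr, ytr, h, W1, b1, W2, b2);
    trace[ep] = te;
    if (te < best - 1e-12) {
      best = te; best_epoch = ep; since = 0;
      bW1 = clone(W1); bb1 = clone(b1); bW2 = clone(W2); bb2 = b2;
    } else if (early_stop && ++since >= patience) {
      break;
    }
  }
  return List::create(_["W1"] = bW1, _["b1"] = bb1, _["W2"] = bW2,
                      _["b2"] = bb2, _["test_trace"] = trace[Range(0, epochs_run - 1)],
                      _["best_epoch"] = best_epoch + 1,
                      _["epochs_run"] = epochs_run,
                      _["final_W1"] = W1, _["final_b1"] = b1,
                      _["final_W2"] = W2, _["final_b2"] = b2);
}

// Batch prediction.
// [[Rcpp::export]]
NumericVector mlp_forward_cpp(NumericMatrix X, NumericMatrix W1,
                              NumericVector b1, NumericVector W2, double b2) {
  int n = X.nrow(), p = X.ncol(), h = W1.ncol();
  std::vector<double> hid(h), xrow(p);
  NumericVector out(n);
  for (int r = 0; r < n; ++r) {
    for (int i = 0; i < p; ++i) xrow[i] = X(r, i);
    out[r] = forward_one(xrow.data(), p, h, W1, b1, W2, b2, hid);
  }
  return out;
}
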