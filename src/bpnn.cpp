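// Core numerics for the 3-layer back-propagation network.
//
// Weight layout (bias row last):
//   Wih: (n_input + 1) x n_hidden   -- row n_input+1 holds hidden biases
//   Who: (n_hidden + 1) x n_output  -- row n_hidden+1 holds output biases
// Hidden activation is logistic sigmoid or ReLU; the output layer is always
// logistic sigmoid so outputs live in (0,1) and match {1,0} one-hot targets.
//
// All randomness (epoch shuffling) is drawn from R's RNG stream so that a
// single set.seed() on the R side makes training bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int ACT_LOGISTIC = 0;
static const int ACT_RELU = 1;

static inline vec sigmoid(const vec& z) { return 1.0 / (1.0 + exp(-z)); }

// hidden activation and its derivative w.r.t. the pre-activation
static inline vec hact(const vec& z, int act) {
  if (act == ACT_RELU) return clamp(z, 0.0, datum::inf);
  return sigmoid(z);
}
static inline vec hact_prime(const vec& z, const vec& h, int act) {
  if (act == ACT_RELU) return conv_to<vec>::from(z > 0.0);
  return h % (1.0 - h);
}

struct FwdPass {
  vec zh, h, o;
};

static FwdPass forward_one(const mat& Wih, const mat& Who, const vec& x,
                           int act) {
  FwdPass f;
  const uword ni = Wih.n_rows - 1;
  f.zh = Wih.rows(0, ni - 1).t() * x + Wih.row(ni).t();
  f.h = hact(f.zh, act);
  const uword nh = Who.n_rows - 1;
  f.o = sigmoid(Who.rows(0, nh - 1).t() * f.h + Who.row(nh).t());
  return f;
}

// [[Rcpp::export(name = ".cpp_forward")]]
Rcpp::List cpp_forward(const arma::mat& Wih, const arma::mat& Who,
                       const arma::vec& x, int act) {
  FwdPass f = forward_one(Wih, Who, x, act);
  return Rcpp::List::create(Rcpp::Named("hidden") = f.h,
                            Rcpp::Named("output") = f.o);
}

// One online update: delta rule with momentum.
//   delta_k = (t_k - o_k) * o_k (1 - o_k)
//   dW(t)   = eta * delta * activation + alpha * dW(t-1)
static void step_inplace(mat& Wih, mat& Who, mat& pdih, mat& pdho,
                         const vec& x, const vec& t, double lr, double mom,
                         int act, bool use_bias) {
  FwdPass f = forward_one(Wih, Who, x, act);
  const uword nh = Who.n_rows - 1;

  vec delta_o = (t - f.o) % f.o % (1.0 - f.o);
  vec delta_h = (Who.rows(0, nh - 1) * delta_o) % hact_prime(f.zh, f.h, act);

  mat dWho(Who.n_rows, Who.n_cols);
  dWho.rows(0, nh - 1) = lr * (f.h * delta_o.t());
  dWho.row(nh) = lr * delta_o.t();
  dWho += mom * pdho;

  const uword ni = Wih.n_rows - 1;
  mat dWih(Wih.n_rows, Wih.n_cols);
  dWih.rows(0, ni - 1) = lr * (x * delta_h.t());
  dWih.row(ni) = lr * delta_h.t();
  dWih += mom * pdih;

  if (!use_bias) {  // biases frozen at zero when disabled
    dWho.row(nh).zeros();
    dWih.row(ni).zeros();
  }

  Who += dWho;
  Wih += dWih;
  pdho = dWho;
  pdih = dWih;
}

// [[Rcpp::export(name = ".cpp_backprop_step")]]
Rcpp::List cpp_backprop_step(arma::mat Wih, arma::mat Who, arma::mat pdih,
                             arma::mat pdho, const arma::vec& x,
                             const arma::vec& t, double lr, double mom,
                             int act, bool use_bias) {
  step_inplace(Wih, Who, pdih, pdho, x, t, lr, mom, act, use_bias);
  return Rcpp::List::create(
      Rcpp::Named("W_ih") = Wih, Rcpp::Named("W_ho") = Who,
      Rcpp::Named("prev_delta_ih") = pdih, Rcpp::Named("prev_delta_ho") = pdho);
}

// RMS over all patterns and output neurons with frozen weights:
// sqrt( sum_p sum_k (t_pk - o_pk)^2 / (P * K) )
static double rms_all(const mat& Wih, const mat& Who, const mat& X,
                      const mat& T, int act) {
  double ss = 0.0;
  for (uword p = 0; p < X.n_rows; ++p) {
    FwdPass f = forward_one(Wih, Who, X.row(p).t(), act);
    ss += accu(square(T.row(p).t() - f.o));
  }
  return std::sqrt(ss / (double)(X.n_rows * T.n_cols));
}

// [[Rcpp::export(name = ".cpp_rms")]]
double cpp_rms(const arma::mat& Wih, const arma::mat& Who, const arma::mat& X,
               const arma::mat& T, int act) {
  return rms_all(Wih, Who, X, T, act);
}

// [[Rcpp::export(name = ".cpp_predict")]]
Rcpp::IntegerVector cpp_predict(const arma::mat& Wih, const arma::mat& Who,
                                const arma::mat& X, int act) {
  Rcpp::IntegerVector out(X.n_rows);
  for (uword p = 0; p < X.n_rows; ++p) {
    FwdPass f = forward_one(Wih, Who, X.row(p).t(), act);
    // argmax with ties broken toward the lower index
    uword best = 0;
    for (uword k = 1; k < f.o.n_elem; ++k)
      if (f.o(k) > f.o(best)) best = k;
    out[p] = (int)best;
  }
  return out;
}

// Fisher-Yates permutation driven by R's RNG (reproducible via set.seed)
static uvec r_permutation(uword n) {
  uvec idx = regspace<uvec>(0, n - 1);
  for (uword i = n - 1; i >= 1; --i) {
    uword j = (uword)std::floor(unif_rand() * (double)(i + 1));
    if (j > i) j = i;  // guard against unif_rand() == 1.0
    std::swap(idx(i), idx(j));
  }
  return idx;
}

// Training loop. Mathematically identical to repeated step_inplace() calls
// (asserted by the test suite) but works on transposed weight copies with
// preallocated buffers so the per-pattern update does no heap allocation.
// [[Rcpp::export(name = ".cpp_train")]]
Rcpp::List cpp_train(arma::mat Wih, arma::mat Who, arma::mat pdih,
                     arma::mat pdho, const arma::mat& X, const arma::mat& T,
                     double lr, double mom, double min_rms, int max_epochs,
                     int act, bool use_bias, bool shuffle) {
  const uword P = X.n_rows;
  const uword ni = Wih.n_rows - 1;
  const uword nh = Who.n_rows - 1;
  const uword K = Who.n_cols;

  // transposed layout: neuron index varies fastest
  mat A = Wih.t();    // nh x (ni+1), col ni = hidden biases
  mat B = Who.t();    // K  x (nh+1), col nh = output biases
  mat pdA = pdih.t();
  mat pdB = pdho.t();
  const mat Xt = X.t();  // ni x P
  const mat Tt = T.t();  // K  x P

  vec zh(nh), h(nh), o(K), delta_o(K), delta_h(nh);
  std::vector<double> history;
  history.reserve(1024);
  bool converged = false;
  int epochs = 0;

  auto fwd = [&](uword p) {
    zh = A.cols(0, ni - 1) * Xt.col(p) + A.col(ni);
    h = hact(zh, act);
    o = 1.0 / (1.0 + exp(-(B.cols(0, nh - 1) * h + B.col(nh))));
  };

  for (int e = 0; e < max_epochs; ++e) {
    uvec ord = shuffle ? r_permutation(P) : regspace<uvec>(0, P - 1);
    for (uword i = 0; i < P; ++i) {
      const uword p = ord(i);
      fwd(p);
      delta_o = (Tt.col(p) - o) % o % (1.0 - o);
      delta_h = (B.cols(0, nh - 1).t() * delta_o) % hact_prime(zh, h, act);

      pdB *= mom;
      for (uword j = 0; j < nh; ++j) pdB.col(j) += (lr * h(j)) * delta_o;
      pdB.col(nh) += lr * delta_o;
      pdA *= mom;
      const double* xp = Xt.colptr(p);
      for (uword j = 0; j < ni; ++j) pdA.col(j) += (lr * xp[j]) * delta_h;
      pdA.col(ni) += lr * delta_h;
      if (!use_bias) {
        pdB.col(nh).zeros();
        pdA.col(ni).zeros();
      }
      B += pdB;
      A += pdA;
    }

    // epoch-end RMS with frozen weights
    double ss = 0.0;
    for (uword p = 0; p < P; ++p) {
      fwd(p);
      ss += accu(square(Tt.col(p) - o));
    }
    double r = std::sqrt(ss / (double)(P * K));
    history.push_back(r);
    epochs = e + 1;
    if (r <= min_rms) {
      converged = true;
      break;
    }
    if (e % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
      Rcpp::Named("W_ih") = A.t(), Rcpp::Named("W_ho") = B.t(),
      Rcpp::Named("prev_delta_ih") = pdA.t(),
      Rcpp::Named("prev_delta_ho") = pdB.t(),
      Rcpp::Named("rms_history") = history, Rcpp::Named("epochs_run") = epochs,
      Rcpp::Named("converged") = converged);
}
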