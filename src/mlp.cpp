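// Dense network forward/backward on top of BLAS, with ReLU or tanh hidden
// activations. The R layer owns the parameters. Only small objects cross
// the R/C++ boundary (the forward output and the parameter gradients); the
// backward pass recomputes the hidden activations internally, which is
// cheaper than shipping them to R and back at tens-of-thousands-of-points
// batch sizes.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static NumericMatrix fast_wrap(const arma::mat &A) {
  NumericMatrix out(A.n_rows, A.n_cols);
  std::memcpy(out.begin(), A.memptr(), sizeof(double) * A.n_elem);
  return out;
}

static arma::mat no_copy(const NumericMatrix &X) {
  return arma::mat(const_cast<double *>(X.begin()), X.nrow(), X.ncol(),
                   false, true);
}

// act: 0 = ReLU, 1 = tanh (hidden layers only; linear output)
static void forward_acts(const arma::mat &X, List W, List b, int act,
                         std::vector<arma::mat> &acts) {
  int nl = W.size();
  acts.resize(nl + 1);
  acts[0] = X;
  for (int i = 0; i < nl; ++i) {
    arma::mat Wi = as<arma::mat>(W[i]);
    arma::rowvec bi = as<arma::rowvec>(b[i]);
    acts[i + 1] = acts[i] * Wi;
    acts[i + 1].each_row() += bi;
    if (i < nl - 1) {
      if (act == 0)
        acts[i + 1].transform([](double v) { return v > 0.0 ? v : 0.0; });
      else
        acts[i + 1].transform([](double v) { return std::tanh(v); });
    }
  }
}

// Returns the K x d_out output only.
// [[Rcpp::export]]
NumericMatrix cpp_mlp_forward(NumericMatrix X, List W, List b, int act) {
  std::vector<arma::mat> acts;
  forward_acts(no_copy(X), W, b, act, acts);
  return fast_wrap(acts.back());
}

// Input gradient only (no parameter gradients): used when the network is
// frozen and only the chain rule to its inputs is needed.
// [[Rcpp::export]]
NumericMatrix cpp_mlp_input_grad(NumericMatrix X, List W, List b,
                                 NumericMatrix dout, int act) {
  int nl = W.size();
  std::vector<arma::mat> acts;
  forward_acts(no_copy(X), W, b, act, acts);
  arma::mat delta = as<arma::mat>(dout);
  for (int i = nl - 1; i >= 0; --i) {
    if (i < nl - 1) {
      if (act == 0)
        delta %= arma::conv_to<arma::mat>::from(acts[i + 1] > 0.0);
      else
        delta %= (1.0 - arma::square(acts[i + 1]));
    }
    arma::mat Wi = as<arma::mat>(W[i]);
    delta = delta * Wi.t();
  }
  return fast_wrap(delta);
}

// Recomputes the activations from X, then backpropagates dout.
// Returns dW, db lists and dX (K x d_in).
// [[Rcpp::export]]
List cpp_mlp_backward(NumericMatrix X, List W, List b, NumericMatrix dout,
                      int act) {
  int nl = W.size();
  std::vector<arma::mat> acts;
  forward_acts(no_copy(X), W, b, act, acts);
  List dW(nl), db(nl);
  arma::mat delta = as<arma::mat>(dout);  // owned: it is resized in the loop
  for (int i = nl - 1; i >= 0; --i) {
    if (i < nl - 1) {
      if (act == 0)
        delta %= arma::conv_to<arma::mat>::from(acts[i + 1] > 0.0);
      else
        delta %= (1.0 - arma::square(acts[i + 1]));
    }
    dW[i] = fast_wrap(acts[i].t() * delta);
    db[i] = NumericVector(wrap(arma::vec(arma::sum(delta, 0).t())));
    arma::mat Wi = as<arma::mat>(W[i]);
    delta = delta * Wi.t();
  }
  return List::create(Named("dW") = dW, Named("db") = db,
                      Named("dX") = fast_wrap(delta));
}
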