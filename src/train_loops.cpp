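// One-epoch mini-batch kernels for the RBM and the backprop networks.
// The epoch loop, seeding and shuffling stay in R; these kernels draw any
// Bernoulli noise from R's RNG in column-major order, so a compiled fit is
// bit-for-bit checkable against cd_update()/pcd_update()/net_gradients()
// driven reference loops in R.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline mat sigm(mat x) {
  return 1.0 / (1.0 + exp(-x));
}

// matches R's (runif(length(p)) < p) on a matrix
static mat bernoulli_draw(const mat& p) {
  mat out(p.n_rows, p.n_cols);
  for (uword j = 0; j < p.n_cols; ++j) {
    for (uword i = 0; i < p.n_rows; ++i) {
      out(i, j) = (R::unif_rand() < p(i, j)) ? 1.0 : 0.0;
    }
  }
  return out;
}

static mat hidden_probs(const mat& V, const mat& W, const vec& c) {
  mat a = V * W.t();
  a.each_row() += c.t();
  return sigm(a);
}

static mat visible_probs(const mat& H, const mat& W, const vec& b) {
  mat a = H * W;
  a.each_row() += b.t();
  return sigm(a);
}

// [[Rcpp::export]]
Rcpp::List rbm_epoch_cpp(arma::mat W, arma::vec b, arma::vec c,
                         const Rcpp::NumericMatrix& V_r,
                         const Rcpp::IntegerVector& perm, int batch_size,
                         double eta, int cd_steps, bool persistent,
                         Rcpp::Nullable<Rcpp::NumericMatrix> chain_r) {
  Rcpp::RNGScope scope;
  const mat V(const_cast<double*>(V_r.begin()), V_r.nrow(), V_r.ncol(),
              false, true);
  const int n = V.n_rows;
  mat chain_v;
  bool chain_started = false;
  if (chain_r.isNotNull()) {
    chain_v = Rcpp::as<mat>(chain_r.get());
    chain_started = true;
  }

  for (int s = 0; s < n; s += batch_size) {
    const int last = std::min(s + batch_size, n) - 1;
    uvec idx(last - s + 1);
    for (int k = s; k <= last; ++k) idx(k - s) = perm[k] - 1;
    const mat batch = V.rows(idx);
    const double nb = batch.n_rows;

    mat h0p = hidden_probs(batch, W, c);
    mat vk, hkp;
    if (persistent) {
      if (!chain_started) { chain_v = batch; chain_started = true; }
      vk = chain_v;
      for (int t = 0; t < cd_steps; ++t) {
        mat hs = bernoulli_draw(hidden_probs(vk, W, c));
        vk = visible_probs(hs, W, b);
      }
      hkp = hidden_probs(vk, W, c);
      chain_v = vk;
    } else {
      mat hs = bernoulli_draw(h0p);
      for (int t = 0; t < cd_steps; ++t) {
        vk = visible_probs(hs, W, b);
        hkp = hidden_probs(vk, W, c);
        if (t < cd_steps - 1) hs = bernoulli_draw(hkp);
      }
    }
    const double nc = vk.n_rows;
    W += eta * (h0p.t() * batch / nb - hkp.t() * vk / nc);
    b += eta * (mean(batch, 0).t() - mean(vk, 0).t());
    c += eta * (mean(h0p, 0).t() - mean(hkp, 0).t());
  }
  Rcpp::checkUserInterrupt();
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("b") = b,
                            Rcpp::Named("c") = c,
                            Rcpp::Named("chain_v") = chain_v);
}

static mat softmax_rows(mat z) {
  z.each_col() -= max(z, 1);
  mat e = exp(z);
  e.each_col() /= sum(e, 1);
  return e;
}

// One SGD epoch over the (already permuted) data for a one- or two-layer
// softmax network; exact gradients of the mean batch cross-entropy, all
// taken at the pre-update parameters.
// [[Rcpp::export]]
Rcpp::List net_epoch_cpp(Rcpp::List layers, const Rcpp::NumericMatrix& X_r,
                         const arma::ivec& y, const Rcpp::IntegerVector& perm,
                         int batch_size, double eta) {
  const mat X(const_cast<double*>(X_r.begin()), X_r.nrow(), X_r.ncol(),
              false, true);
  const int n = X.n_rows;
  const int n_layers = layers.size();

  Rcpp::List l1 = layers[0];
  mat W1 = Rcpp::as<mat>(l1["W"]);
  vec b1 = Rcpp::as<vec>(l1["b"]);
  mat W2;
  vec b2;
  if (n_layers == 2) {
    Rcpp::List l2 = layers[1];
    W2 = Rcpp::as<mat>(l2["W"]);
    b2 = Rcpp::as<vec>(l2["b"]);
  }

  for (int s = 0; s < n; s += batch_size) {
    const int last = std::min(s + batch_size, n) - 1;
    uvec idx(last - s + 1);
    for (int k = s; k <= last; ++k) idx(k - s) = perm[k] - 1;
    const mat Xb = X.rows(idx);
    const double nb = Xb.n_rows;

    mat hidden, logits;
    if (n_layers == 2) {
      hidden = Xb * W1;
      hidden.each_row() += b1.t();
      hidden = sigm(hidden);
      logits = hidden * W2;
      logits.each_row() += b2.t();
    } else {
      logits = Xb * W1;
      logits.each_row() += b1.t();
    }
    mat delta = softmax_rows(logits);
    for (uword r = 0; r < idx.n_elem; ++r) {
      delta(r, y(idx(r))) -= 1.0;
    }
    delta /= nb;

    if (n_layers == 2) {
      mat dh = (delta * W2.t()) % hidden % (1.0 - hidden);
      W2 -= eta * (hidden.t() * delta);
      b2 -= eta * sum(delta, 0).t();
      W1 -= eta * (Xb.t() * dh);
      b1 -= eta * sum(dh, 0).t();
    } else {
      W1 -= eta * (Xb.t() * delta);
      b1 -= eta * sum(delta, 0).t();
    }
  }
  Rcpp::checkUserInterrupt();

  Rcpp::List out(n_layers);
  out[0] = Rcpp::List::create(Rcpp::Named("W") = W1, Rcpp::Named("b") = b1);
  if (n_layers == 2) {
    out[1] = Rcpp::List::create(Rcpp::Named("W") = W2,
                                Rcpp::Named("b") = b2);
  }
  return out;
}
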