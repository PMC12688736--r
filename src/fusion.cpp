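// Attention-fusion training core.
//
// Each standardized scalar feature z_i is lifted to a value vector
// v_i = z_i * e_i + b_i; scaled dot-product scores between a learnable
// query q and per-feature keys k_i give softmax weights w; the fused
// representation is sum_i w_i v_i.  A linear-logistic head on the fused
// vector provides the training signal; the head is discarded afterwards
// and only (q, K, E, B) are kept for downstream use.
//
// Optimization: full-batch gradient descent with per-epoch backtracking
// (step halving on any loss increase), so the recorded loss trace is
// non-increasing up to the line-search floor.  Everything is deterministic
// given the initial parameter values.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

inline double log1pexp(double x) {
  if (x > 33.0) return x;
  if (x < -37.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

struct FusionState {
  vec q;    // d_k
  mat K;    // m x d_k
  mat E;    // m x d_v (value embeddings)
  mat B;    // m x d_v (value offsets)
  vec u;    // d_v (head weights)
  double u0;      // head intercept
  bool train_embed;
  double lambda;
};

vec softmax_weights(const FusionState& st) {
  vec s = st.K * st.q / std::sqrt((double)st.q.n_elem);
  s -= s.max();
  vec w = exp(s);
  return w / accu(w);
}

// fused features for all rows of Z under current params
mat fused_features(const FusionState& st, const mat& Z, const vec& w) {
  mat Zw = Z.each_row() % w.t();             // n x m
  rowvec off = w.t() * st.B;                 // 1 x d_v
  mat F = Zw * st.E;                         // n x d_v
  F.each_row() += off;
  return F;
}

struct FusionGrad {
  vec dq; mat dK; mat dE; mat dB; vec du; double du0;
};

// loss and gradient in one pass (shared w, F, g)
double eval_state(const FusionState& st, const mat& Z, const vec& y,
                  FusionGrad& gr) {
  const double n = (double)Z.n_rows;
  const double sq = std::sqrt((double)st.q.n_elem);
  vec w = softmax_weights(st);
  mat F = fused_features(st, Z, w);
  vec g = F * st.u + st.u0;

  double L = 0.0;
  vec r(Z.n_rows);   // r_i = dL/dg_i = -y_i * sigmoid(-y_i g_i) / n
  for (uword i = 0; i < Z.n_rows; ++i) {
    L += log1pexp(-y(i) * g(i));
    r(i) = -y(i) / (1.0 + std::exp(y(i) * g(i))) / n;
  }
  L /= n;
  double reg = dot(st.q, st.q) + accu(st.K % st.K) + dot(st.u, st.u);
  if (st.train_embed) reg += accu(st.E % st.E) + accu(st.B % st.B);
  L += st.lambda * reg;

  gr.du = F.t() * r + 2.0 * st.lambda * st.u;
  gr.du0 = accu(r);
  vec S1 = Z.t() * r;          // m: sum_i r_i z_i per feature
  double S0 = accu(r);
  if (st.train_embed) {
    gr.dE = (w % S1) * st.u.t() + 2.0 * st.lambda * st.E;
    gr.dB = (w * S0) * st.u.t() + 2.0 * st.lambda * st.B;
  }
  // backprop through the softmax
  vec dw = S1 % (st.E * st.u) + S0 * (st.B * st.u);
  vec ds = w % (dw - dot(w, dw));
  gr.dq = st.K.t() * ds / sq + 2.0 * st.lambda * st.q;
  gr.dK = ds * st.q.t() / sq + 2.0 * st.lambda * st.K;
  return L;
}

// One gradient-descent run; returns the per-epoch loss trace.
vec run_gd(FusionState& st, const mat& Z, const vec& y,
           int epochs, double step) {
  vec trace(epochs + 1);
  FusionGrad gr, gprop;
  double cur = eval_state(st, Z, y, gr);
  trace(0) = cur;
  FusionState prop = st;
  for (int ep = 0; ep < epochs; ++ep) {
    double lr = step;
    bool accepted = false;
    for (int half = 0; half < 40; ++half) {
      prop.q = st.q - lr * gr.dq;
      prop.K = st.K - lr * gr.dK;
      if (st.train_embed) {
        prop.E = st.E - lr * gr.dE;
        prop.B = st.B - lr * gr.dB;
      }
      prop.u = st.u - lr * gr.du;
      prop.u0 = st.u0 - lr * gr.du0;
      double newloss = eval_state(prop, Z, y, gprop);
      if (newloss <= cur + 1e-12) {
        st = prop;
        cur = newloss;
        gr = gprop;
        accepted = true;
        break;
      }
      lr *= 0.5;
    }
    (void)accepted;   // on total rejection the state (and trace) stay flat
    trace(ep + 1) = cur;
  }
  return trace;
}

FusionState make_state(const vec& q0, const mat& K0, const mat& E0,
                       const mat& B0, const vec& u0v, double u00,
                       bool train_embed, double lambda) {
  FusionState st;
  st.q = q0; st.K = K0; st.E = E0; st.B = B0; st.u = u0v; st.u0 = u00;
  st.train_embed = train_embed; st.lambda = lambda;
  return st;
}

} // namespace

// [[Rcpp::export(name = ".fusion_gd_cpp")]]
Rcpp::List fusion_gd_cpp(const arma::mat& Z, const arma::vec& y,
                         const arma::vec& q0, const arma::mat& K0,
                         const arma::mat& E0, const arma::mat& B0,
                         const arma::vec& u0v, double u00,
                         int epochs, double step, double lambda,
                         bool train_embed) {
  FusionState st = make_state(q0, K0, E0, B0, u0v, u00, train_embed, lambda);
  vec trace = run_gd(st, Z, y, epochs, step);
  vec w = softmax_weights(st);
  return Rcpp::List::create(
    Rcpp::Named("q") = st.q, Rcpp::Named("K") = st.K,
    Rcpp::Named("E") = st.E, Rcpp::Named("B") = st.B,
    Rcpp::Named("u") = st.u, Rcpp::Named("u0") = st.u0,
    Rcpp::Named("weights") = w, Rcpp::Named("loss") = trace);
}

// Leave-one-out driver: for every fold, standardize on the n-1 training
// rows only (sample SD, n-1 denominator), train the fusion layer from the
// shared initial parameters, and return fused features for the training
// rows and the held-out row.  Raises an R error naming the fold if a
// training fold has a zero-variance feature column.
// [[Rcpp::export(name = ".loocv_fused_cpp")]]
Rcpp::List loocv_fused_cpp(const arma::mat& X, const arma::vec& y,
                           const arma::vec& q0, const arma::mat& K0,
                           const arma::mat& E0, const arma::mat& B0,
                           const arma::vec& u0v, double u00,
                           int epochs, double step, double lambda,
                           bool train_embed) {
  const uword n = X.n_rows, m = X.n_cols, dv = E0.n_cols;
  Rcpp::List train_feats(n);
  mat test_feats(n, dv);
  mat att_weights(n, m);

  for (uword i = 0; i < n; ++i) {
    // training rows = all but i
    uvec idx(n - 1);
    uword k = 0;
    for (uword j = 0; j < n; ++j) if (j != i) idx(k++) = j;
    mat Xtr = X.rows(idx);
    vec ytr = y.elem(idx);
    rowvec mu = mean(Xtr, 0);
    rowvec sd = stddev(Xtr, 0, 0);   // n-1 denominator
    for (uword c = 0; c < m; ++c) {
      if (sd(c) <= 0.0)
        Rcpp::stop("zero-variance feature column %d in training fold %d",
                   (int)(c + 1), (int)(i + 1));
    }
    mat Ztr = (Xtr.each_row() - mu).each_row() / sd;
    rowvec zte = (X.row(i) - mu) / sd;

    FusionState st = make_state(q0, K0, E0, B0, u0v, u00, train_embed, lambda);
    run_gd(st, Ztr, ytr, epochs, step);
    vec w = softmax_weights(st);
    train_feats[i] = fused_features(st, Ztr, w);
    test_feats.row(i) = fused_features(st, mat(zte), w);
    att_weights.row(i) = w.t();
  }
  return Rcpp::List::create(
    Rcpp::Named("train_feats") = train_feats,
    Rcpp::Named("test_feats") = test_feats,
    Rcpp::Named("att_weights") = att_weights);
}
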