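// Epsilon-insensitive support vector regression with a radial-basis
// kernel, trained by sequential minimal optimization on the dual
//
//   min_s  1/2 s' Kbar s + c' s   s.t.  sum(s) = 0,  lb <= s <= ub
//
// where for n training points the 2n variables are s = (alpha, -alpha*),
// Kbar[i,j] = K(x_{i mod n}, x_{j mod n}), c_i = z_i*epsilon - y_{i mod n}
// with z = (+1...,-1...), box [0,C] for the first n and [-C,0] for the
// rest. Working-set selection is the second-order (maximal decrease)
// rule; the intercept is recovered from the free support vectors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static arma::mat rbf_kernel(const arma::mat& A, const arma::mat& B,
                            double gamma) {
  arma::vec a2 = arma::sum(arma::square(A), 1);
  arma::vec b2 = arma::sum(arma::square(B), 1);
  arma::mat D = arma::repmat(a2, 1, B.n_rows) +
    arma::repmat(b2.t(), A.n_rows, 1) - 2.0 * (A * B.t());
  D.for_each([](arma::mat::elem_type& v) { if (v < 0) v = 0; });
  return arma::exp(-gamma * D);
}

// [[Rcpp::export(name = ".svr_smo_fit")]]
Rcpp::List svr_smo_fit(const arma::mat& X, const arma::vec& y,
                       double cost, double epsilon, double gamma,
                       double tol, int max_iter) {
  const int n = X.n_rows;
  const int m = 2 * n;
  const double C = cost;
  arma::mat K = rbf_kernel(X, X, gamma);

  arma::vec s(m, arma::fill::zeros);
  arma::vec lb(m), ub(m), G(m);
  for (int i = 0; i < n; ++i) {
    lb[i] = 0.0;     ub[i] = C;   G[i] = epsilon - y[i];
    lb[i + n] = -C;  ub[i + n] = 0.0; G[i + n] = -epsilon - y[i];
  }

  const double bound_eps = 1e-12;
  int iter = 0;
  bool converged = false;
  double gmin = 0.0, gmax = 0.0;

  while (iter < max_iter) {
    // i: can increase (s_i < ub_i) with minimal gradient
    int i_sel = -1;
    gmin = arma::datum::inf;
    gmax = -arma::datum::inf;
    for (int t = 0; t < m; ++t) {
      if (s[t] < ub[t] - bound_eps && G[t] < gmin) { gmin = G[t]; i_sel = t; }
      if (s[t] > lb[t] + bound_eps && G[t] > gmax) gmax = G[t];
    }
    if (i_sel < 0 || gmax - gmin < tol) { converged = true; break; }

    // j: can decrease, second-order gain b^2/a maximal
    const int bi = i_sel % n;
    int j_sel = -1;
    double best = -1.0, best_b = 0.0, best_a = 1.0;
    for (int t = 0; t < m; ++t) {
      if (s[t] <= lb[t] + bound_eps) continue;
      double bgap = G[t] - gmin;
      if (bgap <= 0) continue;
      int bt = t % n;
      double a = K(bi, bi) + K(bt, bt) - 2.0 * K(bi, bt);
      if (a <= 0) a = 1e-12;
      double gain = bgap * bgap / a;
      if (gain > best) { best = gain; j_sel = t; best_b = bgap; best_a = a; }
    }
    if (j_sel < 0) { converged = true; break; }

    const int bj = j_sel % n;
    double d = best_b / best_a;
    d = std::min(d, ub[i_sel] - s[i_sel]);
    d = std::min(d, s[j_sel] - lb[j_sel]);
    s[i_sel] += d;
    s[j_sel] -= d;
    for (int l = 0; l < n; ++l) {
      double dv = d * (K(l, bi) - K(l, bj));
      G[l] += dv;
      G[l + n] += dv;
    }
    ++iter;
  }

  // beta = alpha - alpha*; intercept from free (strictly interior) duals
  arma::vec beta(n);
  for (int i = 0; i < n; ++i) beta[i] = s[i] + s[i + n];
  double bsum = 0.0; int bcount = 0;
  const double free_eps = 1e-8 * std::max(1.0, C);
  for (int t = 0; t < m; ++t) {
    if (s[t] > lb[t] + free_eps && s[t] < ub[t] - free_eps) {
      bsum += -G[t]; ++bcount;
    }
  }
  double b = bcount > 0 ? bsum / bcount : -(gmin + gmax) / 2.0;

  return Rcpp::List::create(
    Rcpp::Named("beta") = beta,
    Rcpp::Named("b") = b,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged);
}

// [[Rcpp::export(name = ".svr_rbf_predict")]]
arma::vec svr_rbf_predict(const arma::mat& Xtrain, const arma::vec& beta,
                          double b, double gamma, const arma::mat& Xnew) {
  arma::mat K = rbf_kernel(Xnew, Xtrain, gamma);
  return K * beta + b;
}
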