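// Gaussian-observation HMM core: log-densities, scaled forward-backward,
// Baum-Welch EM, and log-domain Viterbi. Kept in compiled code because the
// model is fitted on concatenated cohort envelopes (T ~ 1e5, M = 38, K = 10)
// with multiple restarts.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Per-state log N(x | mu_k, Sigma_k) for all time points. Returns T x K.
// Covariances are Cholesky-factorized once per call.
static mat log_dens(const mat& X, const mat& mu, const cube& Sigma) {
  const uword T = X.n_rows, M = X.n_cols, K = mu.n_cols;
  mat logB(T, K);
  const double c0 = -0.5 * (double)M * std::log(2.0 * datum::pi);
  for (uword k = 0; k < K; ++k) {
    mat L = chol(Sigma.slice(k), "lower");
    double logdet = accu(log(L.diag()));
    mat Xc = X.each_row() - mu.col(k).t();
    // rows of Z solve L Z' = Xc'  =>  Mahalanobis = rowwise squared norm
    mat Z = solve(trimatl(L), Xc.t());
    logB.col(k) = (c0 - logdet) - 0.5 * sum(square(Z), 0).t();
  }
  return logB;
}

// Scaled forward-backward. Fills gamma (T x K) and xi_sum (K x K);
// returns the log-likelihood.
static double forward_backward(const mat& logB, const mat& A, const rowvec& pi,
                               mat& gamma, mat& xi_sum) {
  const uword T = logB.n_rows, K = logB.n_cols;
  // per-row max shift keeps exp() in range
  vec shift = max(logB, 1);
  mat B = exp(logB.each_col() - shift);
  mat alpha(T, K), beta(T, K);
  vec c(T);
  rowvec a = pi % B.row(0);
  c(0) = accu(a);
  alpha.row(0) = a / c(0);
  for (uword t = 1; t < T; ++t) {
    a = (alpha.row(t - 1) * A) % B.row(t);
    c(t) = accu(a);
    alpha.row(t) = a / c(t);
  }
  beta.row(T - 1).ones();
  for (uword t = T - 1; t > 0; --t) {
    rowvec b = (beta.row(t) % B.row(t)) * A.t();
    beta.row(t - 1) = b / c(t);
  }
  gamma = alpha % beta;
  gamma.each_col() /= sum(gamma, 1);  // guard tiny drift
  xi_sum.zeros(K, K);
  for (uword t = 1; t < T; ++t) {
    // xi_t(i,j) ~ alpha(t-1,i) A(i,j) B(t,j) beta(t,j) / c(t)
    mat xi = (alpha.row(t - 1).t() * (B.row(t) % beta.row(t))) % A / c(t);
    xi_sum += xi;
  }
  return accu(log(c)) + accu(shift);
}

// Floor eigenvalues of a symmetric matrix and add a ridge; sets *collapsed
// when the eigenvalue floor had to act.
static mat regularize_cov(mat S, double ridge_scale, double eig_floor,
                          bool* collapsed) {
  S = symmatu(0.5 * (S + S.t()));
  double ridge = ridge_scale * mean(S.diag());
  S.diag() += ridge;
  vec ev; mat V;
  eig_sym(ev, V, S);
  if (ev.min() < eig_floor) {
    if (collapsed) *collapsed = true;
    ev.transform([&](double v) { return v < eig_floor ? eig_floor : v; });
    S = V * diagmat(ev) * V.t();
    S = symmatu(0.5 * (S + S.t()));
  }
  return S;
}

// [[Rcpp::export(name = ".ghmm_em")]]
Rcpp::List ghmm_em(const arma::mat& X, const arma::uvec& init_states, int K,
                   int max_iter, double tol, double ridge_scale,
                   double eig_floor) {
  const uword T = X.n_rows, M = X.n_cols;
  mat mu(M, K);
  cube Sigma(M, M, K);
  // initial M-step from hard assignments (1-based states from R)
  mat gamma0(T, K, fill::zeros);
  for (uword t = 0; t < T; ++t) gamma0(t, init_states(t) - 1) = 1.0;
  mat A(K, K, fill::value(1.0 / K));
  rowvec pi(K, fill::value(1.0 / K));
  mat gamma = gamma0, xi_sum(K, K);
  bool regularized = false;
  // M-step lambda shared by init and iterations
  auto m_step = [&](const mat& g) {
    rowvec Nk = sum(g, 0);
    for (int k = 0; k < K; ++k) {
      double nk = std::max(Nk(k), 1e-10);
      mu.col(k) = (X.t() * g.col(k)) / nk;
      mat Xc = X.each_row() - mu.col(k).t();
      Xc.each_col() %= sqrt(g.col(k));     // syrk form halves the flops
      mat S = Xc.t() * Xc / nk;
      Sigma.slice(k) = regularize_cov(S, ridge_scale, eig_floor,
                                      &regularized);
    }
  };
  m_step(gamma0);
  std::vector<double> trace;
  double ll_old = -datum::inf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    mat logB = log_dens(X, mu, Sigma);
    double ll = forward_backward(logB, A, pi, gamma, xi_sum);
    trace.push_back(ll);
    if (std::isfinite(ll_old) &&
        std::abs(ll - ll_old) < tol * std::abs(ll_old)) { ++it; break; }
    ll_old = ll;
    // M-step
    m_step(gamma);
    A = xi_sum.each_col() / sum(xi_sum, 1);
    pi = gamma.row(0);
  }
  return Rcpp::List::create(
      Rcpp::Named("mu") = mu, Rcpp::Named("Sigma") = Sigma,
      Rcpp::Named("A") = A, Rcpp::Named("pi") = pi.t(),
      Rcpp::Named("loglik") = trace.empty() ? NA_REAL : trace.back(),
      Rcpp::Named("trace") = trace, Rcpp::Named("n_iter") = it,
      Rcpp::Named("regularized") = regularized);
}

// [[Rcpp::export(name = ".ghmm_forward_backward")]]
Rcpp::List ghmm_forward_backward(const arma::mat& X, const arma::mat& mu,
                                 const arma::cube& Sigma, const arma::mat& A,
                                 const arma::rowvec& pi) {
  mat gamma, xi_sum;
  mat logB = log_dens(X, mu, Sigma);
  double ll = forward_backward(logB, A, pi, gamma, xi_sum);
  return Rcpp::List::create(Rcpp::Named("gamma") = gamma,
                            Rcpp::Named("xi_sum") = xi_sum,
                            Rcpp::Named("loglik") = ll);
}

// [[Rcpp::export(name = ".ghmm_loglik")]]
double ghmm_loglik(const arma::mat& X, const arma::mat& mu,
                   const arma::cube& Sigma, const arma::mat& A,
                   const arma::rowvec& pi) {
  mat gamma, xi_sum;
  mat logB = log_dens(X, mu, Sigma);
  return forward_backward(logB, A, pi, gamma, xi_sum);
}

// Log-domain Viterbi; ties broken toward the lowest state index.
// [[Rcpp::export(name = ".ghmm_viterbi")]]
Rcpp::IntegerVector ghmm_viterbi(const arma::mat& X, const arma::mat& mu,
                                 const arma::cube& Sigma, const arma::mat& A,
                                 const arma::rowvec& pi) {
  const uword T = X.n_rows, K = mu.n_cols;
  mat logB = log_dens(X, mu, Sigma);
  mat logA = log(A);
  rowvec delta = log(pi) + logB.row(0);
  umat psi(T, K, fill::zeros);
  for (uword t = 1; t < T; ++t) {
    rowvec nd(K);
    for (uword j = 0; j < K; ++j) {
      double best = -datum::inf;
      uword arg = 0;
      for (uword i = 0; i < K; ++i) {
        double v = delta(i) + logA(i, j);
        if (v > best) { best = v; arg = i; }  // strict > keeps lowest index
      }
      nd(j) = best + logB(t, j);
      psi(t, j) = arg;
    }
    delta = nd;
  }
  Rcpp::IntegerVector path(T);
  uword s = delta.index_max();
  // index_max returns the first maximum, i.e. the lowest state index
  path[T - 1] = (int)s + 1;
  for (uword t = T - 1; t > 0; --t) {
    s = psi(t, s);
    path[t - 1] = (int)s + 1;
  }
  return path;
}
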