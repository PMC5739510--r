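// Core DAR estimation loop: weighted least squares for the AR coefficients
// alternated with Newton-Raphson for the log-variance polynomial. This is
// the hot path of comodulogram grids and surrogate testing (1e5+ calls), so
// it is compiled; an equivalent R implementation (dar_core_r) is kept in the
// package and tested for agreement.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double sigma_objective(const vec& e2, const mat& Xb, const vec& B) {
  vec u = Xb * B;
  return accu(e2 % exp(-2.0 * u)) + 2.0 * accu(u);
}

// Newton-Raphson on B: minimizes sum(eps^2 exp(-2 u) + 2 u), u = Xb * B,
// with step halving on objective increase.
static vec newton_sigma_cpp(const mat& Xb, const vec& eps, vec B,
                            int max_iter, double tol) {
  const int n = Xb.n_rows;
  vec e2 = eps % eps;
  double f = sigma_objective(e2, Xb, B);
  if (!std::isfinite(f)) {  // bad warm start
    B.zeros();
    B(0) = std::log(std::max(stddev(eps), 1e-12));
    f = sigma_objective(e2, Xb, B);
  }
  for (int it = 0; it < max_iter; ++it) {
    vec u = Xb * B;
    vec w = e2 % exp(-2.0 * u);
    vec g = 2.0 * (Xb.t() * (1.0 - w));
    if (norm(g, 2) < tol * n) break;
    mat Xw = Xb;
    Xw.each_col() %= w;
    mat H = 4.0 * (Xw.t() * Xb);
    vec step;
    if (!solve(step, H, g, solve_opts::no_approx))
      step = g / (4.0 * accu(w) / n);
    double lam = 1.0, fn = f;
    vec Bn = B;
    for (;;) {
      Bn = B - lam * step;
      fn = sigma_objective(e2, Xb, Bn);
      if (fn <= f + 1e-12 * std::abs(f)) break;
      lam *= 0.5;
      if (lam < 1e-8) { Bn = B; fn = f; break; }
    }
    if (fn >= f - 1e-12 * (std::abs(f) + 1.0)) { B = Bn; f = fn; break; }
    B = Bn;
    f = fn;
  }
  return B;
}

// [[Rcpp::export(name = ".dar_core_cpp")]]
Rcpp::List dar_core_cpp(const arma::vec& yt, const arma::mat& L,
                        const arma::mat& Xa, const arma::mat& Xb,
                        int n_outer, int newton_max, double newton_tol,
                        Rcpp::Nullable<Rcpp::NumericVector> B_init) {
  const int n = yt.n_elem;
  const int p = L.n_cols;
  const int na = Xa.n_cols;
  const int nb = Xb.n_cols;

  // regressors, lag-major: column (i * na + b) = y(t - i - 1) * basis_b(t)
  mat R(n, p * na);
  if (na == 1) {
    R = L;
  } else {
    for (int i = 0; i < p; ++i)
      for (int b = 0; b < na; ++b)
        R.col(i * na + b) = L.col(i) % Xa.col(b);
  }

  const double v0 = var(yt);
  vec sigma2(n, fill::value(v0));
  vec A, B, eps, logs;
  bool haveB = false;
  if (B_init.isNotNull()) {
    B = Rcpp::as<vec>(B_init.get());
    haveB = true;
  }

  for (int iter = 0; iter < std::max(n_outer, 1); ++iter) {
    mat G;
    vec rhs;
    if (iter == 0) {  // constant initial variance: weights cancel
      G = R.t() * R;
      rhs = -(R.t() * yt);
    } else {
      vec sw = sqrt(1.0 / sigma2);
      mat Rw = R;
      Rw.each_col() %= sw;
      G = Rw.t() * Rw;                       // syrk path
      rhs = -(Rw.t() * (yt % sw));
    }
    if (!solve(A, G, rhs, solve_opts::likely_sympd + solve_opts::no_approx)) {
      double rc = rcond(G);
      Rcpp::stop("singular normal equations (reciprocal condition number %g); reduce p or m", rc);
    }
    eps = yt + R * A;
    if (!haveB) {
      B = zeros<vec>(nb);
      B(0) = std::log(std::max(stddev(eps), 1e-12));
      haveB = true;
    }
    B = newton_sigma_cpp(Xb, eps, B, newton_max, newton_tol);
    logs = clamp(Xb * B, -50.0, 50.0);
    sigma2 = exp(2.0 * logs);
  }

  const double neg2ll = n * std::log(2.0 * M_PI) +
                        accu(square(eps) / sigma2) + 2.0 * accu(logs);
  return Rcpp::List::create(
      Rcpp::Named("A") = A, Rcpp::Named("B") = B,
      Rcpp::Named("resid") = eps, Rcpp::Named("log_sigma") = logs,
      Rcpp::Named("loglik") = -neg2ll / 2.0,
      Rcpp::Named("n_effective") = n);
}
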