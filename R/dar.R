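# Driven auto-regressive (DAR) models: an AR(p) model whose coefficients and
# log innovation standard deviation are degree-m polynomials in a slow
# exogenous driver x (real- or complex-valued).
#
# Model:   y(t) + sum_i a_i(x(t)) y(t-i) = eps(t),   eps(t) ~ N(0, sigma(t)^2)
#          a_i(x) = sum_{k+l<=m} a_ikl x1^k x2^l     (complex driver)
#          log sigma(x) = sum_{k+l<=m} b_kl x1^k x2^l
#
# Estimation alternates weighted least squares for A (normal equations) with
# Newton-Raphson maximization over B, starting from sigma^2 = var(y).

# Exponent table for the polynomial driver basis, graded-lexicographic:
# degree 0 first, then within each degree k descending (k, l) with k + l = d.
# Returns a 2-column integer matrix (k, l).
basis_exponents <- function(m, complex_driver) {
  if (!complex_driver) {
    return(cbind(k = 0:m, l = rep(0L, m + 1L)))
  }
  ks <- integer(0); ls <- integer(0)
  for (d in 0:m) {
    ks <- c(ks, d:0)
    ls <- c(ls, 0:d)
  }
  cbind(k = ks, l = ls)
}

# n x n_basis matrix of driver monomials x1^k x2^l at the given samples.
driver_basis <- function(x, m, complex_driver = is.complex(x)) {
  n <- length(x)
  x1 <- Re(x)
  if (!complex_driver) {
    out <- matrix(1, n, m + 1L)
    for (k in seq_len(m)) out[, k + 1L] <- out[, k] * x1
    return(out)
  }
  x2 <- Im(x)
  ex <- basis_exponents(m, TRUE)
  x1p <- matrix(1, n, m + 1L)
  x2p <- matrix(1, n, m + 1L)
  for (k in seq_len(m)) {
    x1p[, k + 1L] <- x1p[, k] * x1
    x2p[, k + 1L] <- x2p[, k] * x2
  }
  out <- matrix(1, n, nrow(ex))
  for (j in seq_len(nrow(ex))[-1L]) {
    k <- ex[j, 1L]; l <- ex[j, 2L]
    out[, j] <- if (l == 0L) x1p[, k + 1L]
                else if (k == 0L) x2p[, l + 1L]
                else x1p[, k + 1L] * x2p[, l + 1L]
  }
  out
}

variant_orders <- function(variant, m) {
  switch(variant,
         ar   = c(0L, 0L),
         har  = c(0L, m),
         pdar = c(m, m),
         dar  = c(m, m),
         stop("unknown variant: ", variant))
}

#' Build the DAR regressor structure
#'
#' Returns, for `t` in the likelihood support, the regressor vectors of
#' monomials `x1(t)^k x2(t)^l y(t-i)`. Column ordering is lag-major: for each
#' lag `i = 1..p`, the basis terms `(k, l)` in graded-lexicographic order
#' (degree ascending, then `k` descending).
#'
#' @param y Real vector.
#' @param x Driver (real or complex), same length as `y`.
#' @param p AR order.
#' @param m Driver polynomial degree.
#' @param variant One of `"dar"`, `"ar"`, `"har"`, `"pdar"`.
#' @param support_start,support_end Likelihood support `[support_start,
#'   support_end]`; defaults `p + 1` and `length(y)`.
#' @return List with `R` (regressor matrix), `yt` (response), `Xb` (variance
#'   basis), `support` (indices), `ordering` (data frame lag/k/l per column).
#' @export
build_regressors <- function(y, x, p, m, variant = "dar",
                             support_start = NULL, support_end = NULL) {
  T_ <- length(y)
  if (length(x) != T_) stop("x and y must have equal length")
  if (p >= T_) stop("p must be smaller than the signal length")
  if (p < 1L) stop("p must be >= 1")
  if (m < 0L) stop("m must be >= 0")
  t0 <- as.integer(support_start %||% (p + 1L))
  t1 <- as.integer(support_end %||% T_)
  if (t0 <= p || t1 > T_ || t1 - t0 < 10L)
    stop("invalid likelihood support")
  if (variant == "pdar") {
    mod <- Mod(x)
    x <- ifelse(mod > 0, x / mod, 0)
  }
  cplx <- is.complex(x)
  mm <- variant_orders(variant, as.integer(m))
  idx <- t0:t1
  emb <- stats::embed(y, p + 1L)           # row r <-> t = r + p
  rows <- (t0 - p):(t1 - p)
  yt <- emb[rows, 1L]
  L <- emb[rows, -1L, drop = FALSE]        # y(t-1) ... y(t-p)
  Xa <- driver_basis(x[idx], mm[1], cplx)
  Xb <- driver_basis(x[idx], mm[2], cplx)
  na <- ncol(Xa)
  R <- L[, rep(seq_len(p), each = na), drop = FALSE] *
       Xa[, rep(seq_len(na), times = p), drop = FALSE]
  ex <- basis_exponents(mm[1], cplx)
  ordering <- data.frame(lag = rep(seq_len(p), each = na),
                         k = rep(ex[, 1L], times = p),
                         l = rep(ex[, 2L], times = p))
  list(R = R, yt = yt, Xb = Xb, L = L, Xa = Xa, support = idx,
       ordering = ordering, ordering_b = basis_exponents(mm[2], cplx),
       complex_driver = cplx, m_a = mm[1], m_b = mm[2])
}

# Newton-Raphson for B: minimizes sum(eps^2 exp(-2u) + 2u), u = Xb %*% B.
newton_sigma <- function(Xb, eps, B0 = NULL, max_iter = 50L, tol = 1e-6) {
  nb <- ncol(Xb)
  n <- nrow(Xb)
  e2 <- eps^2
  B <- B0 %||% c(log(max(stats::sd(eps), 1e-12)), numeric(nb - 1L))
  obj <- function(B) {
    u <- as.numeric(Xb %*% B)
    sum(e2 * exp(-2 * u)) + 2 * sum(u)   # Inf on overflow triggers damping
  }
  f <- obj(B)
  if (!is.finite(f)) {   # a bad warm start: fall back to the default init
    B <- c(log(max(stats::sd(eps), 1e-12)), numeric(nb - 1L))
    f <- obj(B)
  }
  for (it in seq_len(max_iter)) {
    u <- as.numeric(Xb %*% B)
    w <- e2 * exp(-2 * u)
    g <- 2 * crossprod(Xb, 1 - w)            # gradient of the objective
    if (sqrt(sum(g^2)) < tol * n) break
    H <- 4 * crossprod(Xb * w, Xb)
    step <- tryCatch(solve(H, g), error = function(e) g / (4 * sum(w) / n))
    lam <- 1
    repeat {
      Bn <- B - lam * step
      fn <- obj(Bn)
      if (fn <= f + 1e-12 * abs(f)) break
      lam <- lam / 2
      if (lam < 1e-8) { Bn <- B; fn <- f; break }
    }
    if (fn >= f - 1e-12 * (abs(f) + 1)) { B <- Bn; f <- fn; break }
    B <- Bn; f <- fn
  }
  as.numeric(B)
}

# Core alternating estimation on precomputed structures. Dispatches to the
# compiled implementation; dar_core_r below is the reference R version, kept
# for cross-checking.
dar_core <- function(yt, L, Xa, Xb, n_outer = 2L, newton_max = 50L,
                     newton_tol = 1e-6, B_init = NULL) {
  out <- .dar_core_cpp(yt, L, Xa, Xb, as.integer(n_outer),
                       as.integer(newton_max), newton_tol, B_init)
  out$A <- as.numeric(out$A)
  out$B <- as.numeric(out$B)
  out$resid <- as.numeric(out$resid)
  out$log_sigma <- as.numeric(out$log_sigma)
  out
}

dar_core_r <- function(yt, L, Xa, Xb, n_outer = 2L, newton_max = 50L,
                       newton_tol = 1e-6, var_init = NULL, B_init = NULL) {
  n <- length(yt)
  p <- ncol(L); na <- ncol(Xa)
  R <- if (na == 1L) L else
    L[, rep(seq_len(p), each = na), drop = FALSE] *
    Xa[, rep(seq_len(na), times = p), drop = FALSE]
  v0 <- var_init %||% stats::var(yt)
  sigma2 <- rep(v0, n)
  A <- NULL; B <- B_init
  eps <- NULL; logs <- NULL
  for (iter in seq_len(max(n_outer, 1L))) {
    if (iter == 1L) {
      # constant initial variance: weights cancel in the normal equations
      G <- crossprod(R)
      rhs <- -crossprod(R, yt)
    } else {
      w <- 1 / sigma2
      G <- crossprod(R, R * w)
      rhs <- -crossprod(R, yt * w)
    }
    ch <- tryCatch(chol(G), error = function(e) NULL)
    if (is.null(ch)) {
      kap <- kappa(G)
      stop(sprintf(
        "singular normal equations (condition number %.3g); reduce p or m",
        kap))
    }
    A <- backsolve(ch, forwardsolve(t(ch), rhs))
    eps <- as.numeric(yt + R %*% A)
    B <- newton_sigma(Xb, eps, B0 = B, max_iter = newton_max,
                      tol = newton_tol)
    logs <- pmin(pmax(as.numeric(Xb %*% B), -50), 50)
    sigma2 <- exp(2 * logs)
  }
  neg2ll <- n * log(2 * pi) + sum(eps^2 / sigma2) + 2 * sum(logs)
  list(A = as.numeric(A), B = B, resid = eps, log_sigma = logs,
       loglik = -neg2ll / 2, n_effective = n)
}

#' Fit a driven auto-regressive model
#'
#' Fits a DAR model (or one of its restricted variants) by maximum
#' likelihood: the innovation variance is initialized to the empirical
#' variance of `y`, the AR coefficients `A` are solved from the weighted
#' normal equations, the variance polynomial `B` is found by Newton-Raphson,
#' and the two steps are alternated `n_outer` times (two are sufficient in
#' practice).
#'
#' Variants: `"ar"` — constant coefficients and variance; `"har"` —
#' heteroskedastic AR (constant coefficients, driven variance); `"pdar"` —
#' phase-only DAR (driver normalized to unit modulus); `"dar"` — fully driven.
#'
#' @param pair A `driver_pair` from [prepare_pair()], or a real vector `y`
#'   (then supply `x`).
#' @param p AR order (>= 1).
#' @param m Driver polynomial degree (>= 0).
#' @param variant Model variant (see Details).
#' @param x Driver vector when `pair` is a plain vector.
#' @param n_outer Number of A/B alternations (default 2).
#' @param support_start,support_end Likelihood support; defaults to
#'   `[p + 1, T]`. Fix `support_start` to `max(p_grid) + 1` when comparing
#'   models of different orders.
#' @param newton_max,newton_tol Newton-Raphson iteration cap and gradient
#'   tolerance.
#' @return A `dar_model` object: coefficients `A` (lag-major ordering, see
#'   [build_regressors()]), `B`, residuals, per-sample `sigma`, `loglik`,
#'   `loglik_per_sample`, `n_effective`, degrees of freedom `dof`, and the
#'   driver radius `rho` (median driver modulus).
#' @export
fit_dar <- function(pair, p = 10L, m = 1L, variant = c("dar", "ar", "har", "pdar"),
                    x = NULL, n_outer = 2L, support_start = NULL,
                    support_end = NULL, newton_max = 50L, newton_tol = 1e-6) {
  variant <- match.arg(variant)
  if (inherits(pair, "driver_pair")) {
    y <- pair$y; x <- pair$x; fs <- pair$fs
  } else {
    y <- as.numeric(pair); fs <- NA_real_
    if (is.null(x)) stop("supply `x` when `pair` is a plain vector")
  }
  reg <- build_regressors(y, x, p, m, variant, support_start, support_end)
  core <- dar_core(reg$yt, reg$L, reg$Xa, reg$Xb, n_outer = n_outer,
                   newton_max = newton_max, newton_tol = newton_tol)
  na <- ncol(reg$R) / p
  nb <- ncol(reg$Xb)
  structure(list(
    p = as.integer(p), m = as.integer(m), variant = variant,
    complex_driver = reg$complex_driver,
    A = core$A, B = core$B,
    ordering = reg$ordering, ordering_b = reg$ordering_b,
    resid = core$resid, sigma = exp(core$log_sigma),
    loglik = core$loglik, loglik_per_sample = core$loglik / core$n_effective,
    n_effective = core$n_effective,
    dof = as.integer(p * na + nb),
    rho = stats::median(Mod(x)),
    fs = fs, n_outer = n_outer,
    support = c(reg$support[1], reg$support[length(reg$support)])),
    class = "dar_model")
}

#' @export
print.dar_model <- function(x, ...) {
  cat(sprintf(
    "<dar_model> %s(p = %d, m = %d)%s | dof = %d | logL = %.2f (%.4f / sample, n = %d)\n",
    toupper(x$variant), x$p, x$m,
    if (x$complex_driver) " complex driver" else " real driver",
    x$dof, x$loglik, x$loglik_per_sample, x$n_effective))
  invisible(x)
}

#' Log-likelihood of a fitted DAR model
#'
#' `-2 log L = n log(2 pi) + sum(eps^2 / sigma^2) + 2 sum(log sigma)` over the
#' likelihood support (`n = T - p` samples by default).
#'
#' @param fit A `dar_model`.
#' @param per_sample Return the per-sample mean instead of the total.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(fit, per_sample = FALSE) {
  if (per_sample) fit$loglik_per_sample else fit$loglik
}

#' Information criteria for a fitted DAR model
#'
#' `AIC = -2 log L + 2 d` and `BIC = -2 log L + d log(T)` with `d` the number
#' of degrees of freedom: `(p + 1)(m + 1)` for a real driver and
#' `(p + 1)(m + 1)(m + 2)/2` for a complex driver (full DAR variant).
#'
#' @param fit A `dar_model`.
#' @param T_ Sample count used in the BIC penalty; defaults to the number of
#'   samples in the likelihood support.
#' @return Named vector `c(aic = , bic = )`.
#' @export
information_criteria <- function(fit, T_ = fit$n_effective) {
  n2ll <- -2 * fit$loglik
  c(aic = n2ll + 2 * fit$dof, bic = n2ll + fit$dof * log(T_))
}

#' Evaluate a fitted model on new data
#'
#' Computes residuals and per-sample variance on new data with frozen
#' coefficients and returns the log-likelihood (used for train/test
#' cross-validation).
#'
#' @param fit A `dar_model`.
#' @param pair A `driver_pair` or real vector `y` (then supply `x`).
#' @param x Driver when `pair` is a plain vector.
#' @param support_start,support_end Likelihood support on the new data.
#' @return List with `loglik`, `loglik_per_sample`, `n_effective`.
#' @export
evaluate_on <- function(fit, pair, x = NULL, support_start = NULL,
                        support_end = NULL) {
  if (inherits(pair, "driver_pair")) {
    y <- pair$y; x <- pair$x
  } else {
    y <- as.numeric(pair)
    if (is.null(x)) stop("supply `x` when `pair` is a plain vector")
  }
  if (length(x) != length(y)) stop("x and y must have equal length")
  reg <- build_regressors(y, x, fit$p, fit$m, fit$variant,
                          support_start, support_end)
  eps <- as.numeric(reg$yt + reg$R %*% fit$A)
  logs <- pmin(pmax(as.numeric(reg$Xb %*% fit$B), -50), 50)
  n <- length(eps)
  neg2ll <- n * log(2 * pi) + sum(eps^2 / exp(2 * logs)) + 2 * sum(logs)
  list(loglik = -neg2ll / 2, loglik_per_sample = -neg2ll / 2 / n,
       n_effective = n)
}
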