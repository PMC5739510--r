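test_that("regressor counts match the model dimensions", {
  set.seed(1)
  y <- rnorm(500)
  xc <- complex(real = rnorm(500), imaginary = rnorm(500))
  xr <- rnorm(500)
  # m = 0: ordinary AR regressors, the p lagged values
  reg <- build_regressors(y, xr, p = 3, m = 0)
  expect_equal(ncol(reg$R), 3)
  expect_equal(reg$R[, 1], y[3:499])
  expect_equal(reg$R[, 3], y[1:497])
  # complex driver, p = 10, m = 2: p (m+1)(m+2)/2 = 60 regressors
  expect_equal(ncol(build_regressors(y, xc, p = 10, m = 2)$R), 60)
  # real driver, p = 10, m = 1: p (m+1) = 20
  expect_equal(ncol(build_regressors(y, xr, p = 10, m = 1)$R), 20)
})

test_that("AR(1) coefficient is recovered with the model's sign convention", {
  set.seed(2)
  y <- as.numeric(arima.sim(list(ar = 0.5), 1e5))
  fit <- fit_dar(y, p = 1, m = 0, variant = "ar", x = rep(0, length(y)))
  # Yule-Walker oracle: a_1 = -acf(1)
  r1 <- acf(y, lag.max = 1, plot = FALSE, demean = TRUE)$acf[2]
  expect_equal(fit$A, -0.5, tolerance = 0.02)
  expect_equal(fit$A, -r1, tolerance = 0.005)
})

test_that("white noise yields near-zero coefficients and unit sigma", {
  set.seed(3)
  T_ <- 1e5
  y <- rnorm(T_)
  x <- complex(real = rnorm(T_), imaginary = rnorm(T_))
  fit <- fit_dar(y, p = 10, m = 1, x = x)
  expect_lt(max(abs(fit$A)), 0.05)
  expect_lt(abs(fit$B[1]), 0.05)            # log sigma ~ 0
  expect_equal(-2 * fit$loglik_per_sample, log(2 * pi) + 1,
               tolerance = 0.02)
})

test_that("known DAR(2,1) coefficients are recovered from simulation", {
  a0 <- c(-0.6, 0.2)
  a1 <- c(0.1, -0.05)
  x <- Re(simulate_driver(1e5, 240, 3, 1, seed = 21)) * 0.8
  y <- simulate_from_dar(a0, a1, b0 = 0, b1 = 0.15, x, seed = 22)
  fit <- fit_dar(y, p = 2, m = 1, x = x)
  truth <- c(a0[1], a1[1], a0[2], a1[2])    # lag-major ordering
  expect_equal(fit$A, truth, tolerance = 0.02)
  expect_equal(fit$B, c(0, 0.15), tolerance = 0.02)
})

test_that("normal-equations solution equals a QR least-squares oracle", {
  set.seed(5)
  y <- rnorm(200)
  x <- complex(real = rnorm(200), imaginary = rnorm(200))
  reg <- build_regressors(y, x, p = 3, m = 1)
  # sigma fixed (first iteration): plain least squares
  fit <- fit_dar(y, p = 3, m = 1, x = x, n_outer = 1)
  oracle <- -stats::lm.fit(reg$R, reg$yt)$coefficients
  expect_lt(max(abs(fit$A - as.numeric(oracle))), 1e-8)
})

test_that("compiled and reference cores agree", {
  set.seed(6)
  y <- rnorm(3000)
  x <- complex(real = rnorm(3000), imaginary = rnorm(3000))
  for (spec in list(c(5, 1), c(3, 2), c(10, 0))) {
    reg <- build_regressors(y, x, p = spec[1], m = spec[2])
    a <- darpac:::dar_core(reg$yt, reg$L, reg$Xa, reg$Xb, n_outer = 2)
    b <- darpac:::dar_core_r(reg$yt, reg$L, reg$Xa, reg$Xb, n_outer = 2)
    expect_equal(a$A, b$A, tolerance = 1e-10)
    expect_equal(a$B, b$B, tolerance = 1e-10)
    expect_equal(a$loglik, b$loglik, tolerance = 1e-8)
  }
})

test_that("log-likelihood identities hold", {
  sig <- default_pac_signal()
  pair <- prepare_pair(sig, 3, 1, rng_seed = 1)
  fit <- fit_dar(pair, 6, 1)
  # formula consistency on the fit's own fields
  n <- fit$n_effective
  n2ll <- n * log(2 * pi) + sum(fit$resid^2 / fit$sigma^2) +
          2 * sum(log(fit$sigma))
  expect_equal(-2 * fit$loglik, n2ll, tolerance = 1e-8)
  # doubling sigma uniformly: -2logL changes by 2n log 2 - (3/4) sum(eps^2/sigma^2)
  fit2 <- fit
  fit2$B[1] <- fit2$B[1] + log(2)
  ev <- evaluate_on(fit2, pair)
  delta <- -2 * ev$loglik - n2ll
  expect_equal(delta, 2 * n * log(2) - 0.75 * sum(fit$resid^2 / fit$sigma^2),
               tolerance = 1e-6)
})

test_that("evaluating on the training data reproduces the fit likelihood", {
  sig <- default_pac_signal()
  pair <- prepare_pair(sig, 3, 1, rng_seed = 1)
  fit <- fit_dar(pair, 10, 1)
  ev <- evaluate_on(fit, pair)
  expect_equal(ev$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("a null model on white noise gives the Gaussian entropy rate", {
  set.seed(7)
  y <- rnorm(2e4)
  x <- complex(real = rnorm(2e4), imaginary = rnorm(2e4))
  fit <- fit_dar(y[1:1000], p = 2, m = 1, x = x[1:1000])
  fit$A[] <- 0
  fit$B[] <- 0
  ev <- evaluate_on(fit, y, x = x)
  expect_equal(-2 * ev$loglik_per_sample, log(2 * pi) + 1, tolerance = 0.02)
})

test_that("degrees of freedom and information criteria", {
  set.seed(8)
  y <- rnorm(3000)
  xc <- complex(real = rnorm(3000), imaginary = rnorm(3000))
  f_real <- fit_dar(y, p = 10, m = 1, x = Re(xc))
  f_cplx <- fit_dar(y, p = 10, m = 1, x = xc)
  expect_equal(f_real$dof, 22)              # (p+1)(m+1)
  expect_equal(f_cplx$dof, 33)              # (p+1)(m+1)(m+2)/2
  ic1 <- information_criteria(f_real)
  expect_equal(as.numeric(ic1["aic"]), -2 * f_real$loglik + 2 * 22)
  expect_equal(as.numeric(ic1["bic"]),
               -2 * f_real$loglik + 22 * log(f_real$n_effective))
  # equal loglik, larger dof -> larger BIC
  f2 <- f_real
  f2$dof <- 30L
  expect_gt(information_criteria(f2)["bic"], ic1["bic"])
})

test_that("DAR with m = 0 nests the AR model exactly", {
  sig <- default_pac_signal()
  pair <- prepare_pair(sig, 3, 1, rng_seed = 1)
  f_ar <- fit_dar(pair, 8, 0, variant = "ar")
  f_dar0 <- fit_dar(pair, 8, 0, variant = "dar")
  expect_equal(f_ar$loglik, f_dar0$loglik, tolerance = 1e-10)
  expect_equal(f_ar$A, f_dar0$A, tolerance = 1e-12)
})

test_that("outer A/B iterations do not decrease the likelihood", {
  sig <- default_pac_signal()
  pair <- prepare_pair(sig, 3, 1, rng_seed = 1)
  lls <- vapply(1:4, function(k)
    fit_dar(pair, 10, 1, n_outer = k)$loglik, numeric(1))
  expect_true(all(diff(lls) >= -1e-6 * length(pair$y)))
})

test_that("PDAR equals DAR on the unit-modulus driver", {
  sig <- default_pac_signal()
  pair <- prepare_pair(sig, 3, 1, rng_seed = 1)
  f_pdar <- fit_dar(pair, 6, 1, variant = "pdar")
  pair_norm <- pair
  pair_norm$x <- pair$x / Mod(pair$x)
  f_dar <- fit_dar(pair_norm, 6, 1, variant = "dar")
  expect_equal(f_pdar$A, f_dar$A, tolerance = 1e-10)
  expect_equal(f_pdar$loglik, f_dar$loglik, tolerance = 1e-8)
})

test_that("invalid model specifications are rejected", {
  y <- rnorm(100)
  expect_error(build_regressors(y, rnorm(100), p = 100, m = 0),
               "smaller than the signal length")
  expect_error(build_regressors(y, rnorm(50), p = 2, m = 0), "equal length")
  expect_error(fit_dar(y, p = 2, m = 1), "supply `x`")
})
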