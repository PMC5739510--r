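test_that("flat spectrum when all AR coefficients vanish", {
  set.seed(1)
  y <- rnorm(2000)
  x <- complex(real = rnorm(2000), imaginary = rnorm(2000))
  fit <- fit_dar(y, p = 2, m = 1, x = x)
  fit$A[] <- 0
  cp <- conditional_psd(fit, 0.5 + 0.2i, n_fft = 128)
  s2 <- exp(2 * sum(darpac:::driver_basis(0.5 + 0.2i, 1, TRUE) * fit$B))
  expect_equal(cp$power, rep(s2, length(cp$power)), tolerance = 1e-10)
})

test_that("doubling sigma quadruples the conditional spectrum", {
  set.seed(2)
  y <- rnorm(2000)
  x <- complex(real = rnorm(2000), imaginary = rnorm(2000))
  fit <- fit_dar(y, p = 4, m = 1, x = x)
  p1 <- conditional_psd(fit, 0.3 + 0i, n_fft = 128)$power
  fit$B[1] <- fit$B[1] + log(2)
  p2 <- conditional_psd(fit, 0.3 + 0i, n_fft = 128)$power
  expect_equal(p2, 4 * p1, tolerance = 1e-10)
})

test_that("an AR(2) model spectrum matches the Welch periodogram within 3 dB", {
  set.seed(3)
  y <- as.numeric(arima.sim(list(ar = c(0.6, -0.3)), 1e5))
  fit <- fit_dar(y, p = 2, m = 0, variant = "ar", x = rep(0, length(y)))
  cp <- conditional_psd(fit, 0 + 0i, n_fft = 256, fs = 1)
  w <- darpac:::welch_psd(y, 1, n_seg = 256)
  band <- which(cp$freqs > 0 & cp$freqs <= 0.45)
  # model form is the two-sided density; Welch is one-sided (factor 2)
  db_diff <- 10 * log10(2 * cp$power[band] / w$psd[band])
  expect_lt(max(abs(db_diff)), 3)
})

test_that("phase circle requires a complex driver and honors n_phases = 1", {
  set.seed(4)
  y <- rnorm(3000)
  xr <- rnorm(3000)
  xc <- complex(real = xr, imaginary = rnorm(3000))
  expect_error(psd_on_phase_circle(fit_dar(y, 4, 1, x = xr)), "complex")
  fit <- fit_dar(y, 4, 1, x = xc)
  one <- psd_on_phase_circle(fit, n_phases = 1, n_fft = 64)
  ref <- conditional_psd(fit, fit$rho * exp(-1i * pi), n_fft = 64)
  expect_equal(as.numeric(one$power), ref$power, tolerance = 1e-12)
})

test_that("driver-independent noise gives a flat phase circle", {
  set.seed(5)
  y <- rnorm(5e4)
  x <- complex(real = rnorm(5e4), imaginary = rnorm(5e4))
  cp <- psd_on_phase_circle(fit_dar(y, 5, 1, x = x), n_phases = 20,
                            n_fft = 128)
  spread_db <- apply(cp$power, 2, function(col)
    10 * log10(max(col) / min(col)))
  expect_lt(max(spread_db), 1)
})

test_that("modulation metric attains its closed-form values", {
  # constant column: KL(u||u) = 0
  expect_equal(as.numeric(modulation_spectrum(matrix(2, 8, 3))),
               rep(0, 3))
  # all mass in one of n bins: KL = log n, normalized to 1
  onehot <- matrix(1e-300, 8, 1); onehot[3, 1] <- 1
  expect_equal(as.numeric(modulation_spectrum(onehot)), 1, tolerance = 1e-10)
  # two equal bins among n = 8: M = 1 - log(2)/log(8)
  two <- matrix(0, 8, 1); two[c(2, 6), 1] <- 1
  expect_equal(as.numeric(modulation_spectrum(two)), 1 - log(2) / log(8),
               tolerance = 1e-12)
  # zero-power column flagged, M = 0
  z <- modulation_spectrum(matrix(0, 8, 1))
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "undefined"))
})

test_that("modulation metric is scale- and rotation-invariant", {
  set.seed(6)
  pw <- matrix(rexp(40 * 5), 40, 5)
  m0 <- modulation_spectrum(pw)
  expect_equal(as.numeric(modulation_spectrum(7.3 * pw)), as.numeric(m0),
               tolerance = 1e-12)
  rot <- pw[c(15:40, 1:14), ]
  expect_equal(as.numeric(modulation_spectrum(rot)), as.numeric(m0),
               tolerance = 1e-12)
})

test_that("an m = 0 fit has zero modulation at every frequency", {
  sig <- default_pac_signal()
  pair <- prepare_pair(sig, 3, 1, rng_seed = 1)
  fit <- fit_dar(pair, 8, 0, variant = "dar")
  M <- modulation_spectrum(psd_on_phase_circle(fit, n_phases = 16,
                                               n_fft = 128))
  expect_lt(max(M), 1e-12)
})

test_that("simulated PAC produces phase-dependent power near f_y", {
  sig <- default_pac_signal()
  pair <- prepare_pair(sig, 3, 1, rng_seed = 1)
  fit <- fit_dar(pair, 10, 1)
  cp <- psd_on_phase_circle(fit)
  i50 <- which.min(abs(cp$freqs - 50))
  col <- cp$power[, i50]
  expect_gt(10 * log10(max(col) / min(col)), 1)
})

test_that("comodulogram on PAC peaks at the simulated frequency pair", {
  sig <- default_pac_signal()
  com <- comodulogram_dar(sig, seq(2, 5, by = 0.5), rng_seed = 3)
  expect_true(all(com$values >= 0 & com$values <= 1, na.rm = TRUE))
  am <- comodulogram_argmax(com)
  expect_equal(as.numeric(am["driver_freq"]), 3, tolerance = 0.51)
  expect_equal(as.numeric(am["signal_freq"]), 50, tolerance = 2)
})

test_that("comodulogram argmax ties break lexicographically", {
  com <- structure(list(driver_freqs = c(2, 3), signal_freqs = c(10, 20),
                        values = matrix(1, 2, 2), method = "dar"),
                   class = "comodulogram")
  am <- comodulogram_argmax(com)
  expect_equal(as.numeric(am), c(2, 10))
})
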