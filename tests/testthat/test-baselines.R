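test_that("phase and amplitude extraction on pure sinusoids", {
  fs <- 240
  tt <- (0:(fs * 30 - 1)) / fs
  # amplitude of a pure fast sinusoid is flat
  sigy <- raw_signal(2.5 * cos(2 * pi * 50 * tt), fs)
  pa <- phase_amplitude(sigy, 3, 1, 50, 14)
  expect_lt(diff(range(pa$amplitude)) / mean(pa$amplitude), 0.05)
  expect_equal(mean(pa$amplitude), 2.5, tolerance = 0.05)
  # phase of a pure slow sinusoid advances linearly
  sigx <- raw_signal(cos(2 * pi * 3 * tt), fs)
  pb <- phase_amplitude(sigx, 3, 1, 50, 14)
  dphi <- diff(pb$phase) %% (2 * pi)
  expect_equal(median(dphi), 2 * pi * 3 / fs, tolerance = 1e-3)
})

test_that("narrow fast bandwidth triggers the observability warning", {
  sig <- default_pac_signal()
  expect_warning(phase_amplitude(sig, 3, 1, 50, 5), "amplitude modulation")
})

test_that("Tort MI: uniformity, concentration and bin-relabeling invariance", {
  set.seed(1)
  T_ <- 1e5
  phi <- runif(T_, -pi, pi)
  amp <- rexp(T_)
  mkpair <- function(phi, amp)
    structure(list(phase = phi, amplitude = amp), class = "phase_amplitude")
  expect_lt(tort_mi(mkpair(phi, amp)), 0.01)
  # amplitude concentrated in exactly one of 18 bins
  onebin <- ifelse(phi >= -pi & phi < -pi + 2 * pi / 18, 1, 0)
  expect_equal(as.numeric(tort_mi(mkpair(phi, onebin))), 1, tolerance = 1e-6)
  # shifting phases by one exact bin width relabels the bins
  amp2 <- 1 + cos(phi)
  m0 <- tort_mi(mkpair(phi, amp2))
  shifted <- ((phi + 2 * pi / 18 + pi) %% (2 * pi)) - pi
  expect_equal(as.numeric(tort_mi(mkpair(shifted, amp2))), as.numeric(m0),
               tolerance = 1e-12)
})

test_that("Ozkurt MI matches a numerical-integration oracle", {
  # a_y = 1 + cos(phi), uniform phases:
  # numerator |E a e^{i phi}|, denominator sqrt(E a^2), both by quadrature
  re <- integrate(function(t) (1 + cos(t)) * cos(t) / (2 * pi), -pi, pi)$value
  im <- integrate(function(t) (1 + cos(t)) * sin(t) / (2 * pi), -pi, pi)$value
  ea2 <- integrate(function(t) (1 + cos(t))^2 / (2 * pi), -pi, pi)$value
  oracle <- sqrt(re^2 + im^2) / sqrt(ea2)
  phi <- seq(-pi, pi, length.out = 1e5 + 1)[-1]
  pair <- structure(list(phase = phi, amplitude = 1 + cos(phi)),
                    class = "phase_amplitude")
  expect_equal(ozkurt_mi(pair), oracle, tolerance = 1e-4)
  # scaling invariance and null behavior
  pair2 <- pair; pair2$amplitude <- 13 * pair$amplitude
  expect_equal(ozkurt_mi(pair2), ozkurt_mi(pair), tolerance = 1e-12)
  set.seed(2)
  pn <- structure(list(phase = runif(1e5, -pi, pi), amplitude = rexp(1e5)),
                  class = "phase_amplitude")
  expect_lt(ozkurt_mi(pn), 0.01)
})

test_that("Penny GLM: exact fit, null and preferred-phase invariance", {
  phi <- seq(-pi, pi, length.out = 5001)[-1]
  mk <- function(a) structure(list(phase = phi, amplitude = a,
                                   amplitude_x = rep(1, length(phi))),
                              class = "phase_amplitude")
  expect_equal(penny_glm(mk(2 + cos(phi))), 1, tolerance = 1e-10)
  set.seed(3)
  expect_lt(penny_glm(mk(rexp(length(phi)))), 0.01)
  r2 <- vapply(c(0, pi / 3, pi / 2, 2), function(ph0)
    penny_glm(mk(2 + cos(phi - ph0))), numeric(1))
  expect_lt(diff(range(r2)), 1e-8)
})

test_that("Tort MI and the DAR metric share the same KL kernel", {
  prof <- c(0.05, 0.3, 0.9, 1.4, 0.8, 0.2, 0.1, 0.25)
  expect_equal(darpac:::kl_uniform_norm(prof),
               as.numeric(modulation_spectrum(matrix(prof, ncol = 1))),
               tolerance = 1e-12)
})

test_that("simulated PAC shows stronger phase/amplitude association than a shuffle", {
  sig <- default_pac_signal()
  pa <- phase_amplitude(sig, 3, 1, 50, 14)
  obs <- ozkurt_mi(pa)
  set.seed(4)
  shuf <- pa
  shuf$amplitude <- sample(pa$amplitude)
  expect_gt(obs, 5 * ozkurt_mi(shuf))
})

test_that("baseline comodulograms locate the simulated coupling", {
  sig <- default_pac_signal()
  for (method in c("tort", "ozkurt", "penny")) {
    com <- comodulogram_baseline(sig, method, seq(2, 5, by = 0.5),
                                 delta_f_x = 1,
                                 f_y_grid = seq(30, 80, by = 5))
    am <- comodulogram_argmax(com)
    expect_equal(as.numeric(am["driver_freq"]), 3, tolerance = 0.51,
                 label = method)
    expect_equal(as.numeric(am["signal_freq"]), 50, tolerance = 5.1,
                 label = method)
  }
})

test_that("all metrics are invariant to the simulated preferred phase", {
  vals <- sapply(c(0, pi / 2, pi), function(ph0) {
    sig <- simulate_pac(sim_pac_config(n_seconds = 30, phi0 = ph0,
                                       seed = 11))
    pa <- phase_amplitude(sig, 3, 1, 50, 14)
    c(tort_mi(pa), ozkurt_mi(pa), penny_glm(pa))
  })
  for (i in 1:3) {
    expect_lt(diff(range(vals[i, ])) / mean(vals[i, ]), 0.35)
    expect_gt(min(vals[i, ]), 0)
  }
})
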