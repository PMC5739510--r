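test_that("powerline removal suppresses an exact 50 Hz line by >= 40 dB", {
  fs <- 333
  tt <- (0:(10 * fs - 1)) / fs
  z <- raw_signal(sin(2 * pi * 50 * tt + 0.7), fs)
  out <- remove_powerline(z, 50, search_halfwidth = 0.5)
  before <- peak_power_near(z$samples, fs, 50)
  after <- peak_power_near(out$samples, fs, 50)
  expect_gt(10 * log10(before / after), 40)
})

test_that("powerline removal finds an off-nominal line (50.1 Hz)", {
  fs <- 333
  tt <- (0:(10 * fs - 1)) / fs
  z <- raw_signal(sin(2 * pi * 50.1 * tt), fs)
  out <- remove_powerline(z, 50, search_halfwidth = 0.5)
  drop_db <- 10 * log10(peak_power_near(z$samples, fs, 50.1, 0.2) /
                        peak_power_near(out$samples, fs, 50.1, 0.2))
  expect_gt(drop_db, 20)
})

test_that("powerline removal barely touches white noise", {
  set.seed(4)
  z <- raw_signal(rnorm(3000), 333)
  out <- remove_powerline(z, 50)
  rel <- sqrt(mean((out$samples - z$samples)^2)) /
         sqrt(mean(z$samples^2))
  expect_lt(rel, 0.05)
})

test_that("powerline removal rejects frequencies at or above Nyquist", {
  expect_error(remove_powerline(raw_signal(rnorm(100), 100), 50), "Nyquist")
})

test_that("extract_driver returns the analytic-like signal of a sinusoid", {
  fs <- 240
  tt <- (0:4799) / fs
  x <- extract_driver(raw_signal(cos(2 * pi * 4 * tt), fs), 4, 1)
  mid <- 500:4300
  expect_lt(diff(range(Mod(x[mid]))) / mean(Mod(x[mid])), 0.05)
  dphi <- diff(Arg(x[mid])) %% (2 * pi)
  expect_equal(median(dphi), 2 * pi * 4 / fs, tolerance = 1e-3)
})

test_that("extracted driver power is concentrated in the band", {
  set.seed(5)
  fs <- 240
  x <- extract_driver(raw_signal(rnorm(fs * 60), fs), 4, 1)
  expect_gt(band_power_fraction(Re(x), fs, 3, 5), 0.95)
})

test_that("time reversal maps x1 -> rev(x1) and x2 -> -rev(x2)", {
  set.seed(6)
  z <- rnorm(2000)
  x_f <- extract_driver(raw_signal(z, 240), 4, 1.5)
  x_r <- extract_driver(raw_signal(rev(z), 240), 4, 1.5)
  expect_equal(Re(x_r), rev(Re(x_f)), tolerance = 1e-10)
  expect_equal(Im(x_r), -rev(Im(x_f)), tolerance = 1e-10)
})

test_that("gap filling restores a flat PSD across the notch within 3 dB", {
  set.seed(7)
  fs <- 240
  z <- rnorm(fs * 120)
  filt <- design_driver_filter(fs, 6, 2)
  y <- z - fir_apply(z, filt)       # exact notch at 6 Hz
  yf <- fill_gap(y, filt, rng_seed = 1)
  flat <- band_psd_level(z, fs, 12, 60)
  filled <- band_psd_level(yf, fs, 5.5, 6.5)
  expect_lt(abs(10 * log10(filled / flat)), 3)
  # and the notch was real before filling
  notch <- band_psd_level(y, fs, 5.7, 6.3)
  expect_gt(10 * log10(flat / notch), 6)
})

test_that("gap filling is deterministic and a zero-tap filter is identity", {
  set.seed(8)
  fs <- 240
  z <- rnorm(fs * 30)
  filt <- design_driver_filter(fs, 6, 2)
  y <- z - fir_apply(z, filt)
  expect_identical(fill_gap(y, filt, rng_seed = 3),
                   fill_gap(y, filt, rng_seed = 3))
  empty <- list(taps = numeric(0), f_x = 6, delta_f_x = 2, fs = fs)
  expect_identical(fill_gap(y, empty, 1), y)
})

test_that("whitening flattens an AR(1) process", {
  set.seed(9)
  y <- as.numeric(arima.sim(list(ar = 0.5), 1e5))
  w <- whiten(y, order = 1)
  r1 <- acf(w$y, lag.max = 1, plot = FALSE)$acf[2]
  expect_lt(abs(r1), 0.05)
  expect_equal(w$ar, 0.5, tolerance = 0.02)
})

test_that("whitening white noise is near-identity; order 0 is identity", {
  set.seed(10)
  y <- rnorm(2e4)
  w <- whiten(y, order = 10)
  expect_lt(max(abs(w$ar)), 0.05)
  expect_identical(whiten(y, 0)$y, y)
})

test_that("prepare_pair bookkeeping reconstructs the raw signal", {
  sig <- default_pac_signal()
  pair <- prepare_pair(sig, 3, 1, rng_seed = 1, keep_intermediate = TRUE)
  x1 <- Re(pair$x)
  expect_equal(x1 + pair$y_before_fill, sig$samples, tolerance = 1e-12)
  expect_equal(length(pair$x), length(pair$y))
})

test_that("prepare_pair is deterministic and keeps PAC structure", {
  sig <- default_pac_signal()
  p1 <- prepare_pair(sig, 3, 1, rng_seed = 5)
  p2 <- prepare_pair(sig, 3, 1, rng_seed = 5)
  expect_identical(p1$y, p2$y)
  # fast power in phase bins of the driver should follow the sigmoid of x1
  phase <- Arg(p1$x)
  fast2 <- p1$y^2
  bins <- cut(phase, seq(-pi, pi, length.out = 13), include.lowest = TRUE)
  prof <- tapply(fast2, bins, mean)
  centers <- seq(-pi, pi, length.out = 13)[-1] - pi / 12
  sigm <- sigmoid_modulation(cos(centers) * median(Mod(p1$x)), 3)
  expect_gt(cor(prof, sigm), 0)
})

test_that("pure driver-band input leaves only fill noise in y", {
  fs <- 240
  tt <- (0:(fs * 30 - 1)) / fs
  sig <- raw_signal(sin(2 * pi * 3 * tt), fs)
  pair <- prepare_pair(sig, 3, 1, whitening_order = 0L, rng_seed = 2,
                       keep_intermediate = TRUE)
  # residual y before gap fill is tiny compared with the input
  expect_lt(stats::var(pair$y_before_fill[500:6700]), 0.01 * stats::var(sig$samples))
})

test_that("grid-search preparation removes the low band and is deterministic", {
  set.seed(12)
  fs <- 240
  z <- raw_signal(rnorm(fs * 60), fs)
  hp <- darpac:::fir_highpass(fs, 10)
  y_hp <- fir_apply(z$samples, hp)
  expect_lt(band_power_fraction(y_hp, fs, 0.5, 9.5), 0.01)
  y1 <- prepare_for_gridsearch(z, 10, rng_seed = 4)
  y2 <- prepare_for_gridsearch(z, 10, rng_seed = 4)
  expect_identical(as.numeric(y1), as.numeric(y2))
})

test_that("polyphase resampling preserves a band-limited waveform", {
  fs <- 1000
  tt <- (0:(fs * 4 - 1)) / fs
  sig <- raw_signal(sin(2 * pi * 7 * tt), fs)
  down <- resample_signal(sig, 250)
  expect_equal(down$fs, 250)
  expect_equal(length(down$samples), 1000)
  tt2 <- (0:999) / 250
  mid <- 100:900
  expect_lt(max(abs(down$samples[mid] - sin(2 * pi * 7 * tt2)[mid])), 0.02)
  expect_identical(resample_signal(sig, fs)$samples, sig$samples)
})
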