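# Synthetic PAC signals: a band-limited stochastic driver whose value
# modulates, through a sigmoid, the amplitude of a fast sinusoid; plus
# noisy-driver and spike-train (spurious PAC) variants. The generator is
# deliberately NOT a DAR process, so model validation is not circular.

#' Simulation configuration
#'
#' Default parameters of the PAC simulation protocol: coupling between a
#' 3 Hz band-limited driver (1 Hz bandwidth, unit standard deviation) and a
#' 50 Hz carrier, sampled at 240 Hz; sigmoid sharpness `lambda = 3`;
#' modulated-carrier standard deviation `sigma_y = 0.4`; additive white
#' noise standard deviation `sigma_eps = 1`; preferred phase `phi0 = 0`;
#' coupling delay `tau = 0` s.
#'
#' @param n_seconds Signal duration in seconds.
#' @param fs Sampling rate (Hz).
#' @param f_x,delta_f_x Driver center frequency and bandwidth (Hz).
#' @param f_y Fast-oscillation frequency (Hz).
#' @param lambda Sigmoid sharpness (0 disables the coupling).
#' @param sigma_y Standard deviation of the modulated carrier component.
#' @param sigma_eps Standard deviation of the additive white noise.
#' @param phi0 Preferred phase of the coupling (radians): driver phase at
#'   which the fast amplitude peaks.
#' @param tau Coupling delay in seconds (positive: the driver precedes the
#'   amplitude modulation).
#' @param seed Integer RNG seed.
#' @return A `sim_pac_config` list.
#' @export
sim_pac_config <- function(n_seconds = 100, fs = 240, f_x = 3,
                           delta_f_x = 1, f_y = 50, lambda = 3,
                           sigma_y = 0.4, sigma_eps = 1, phi0 = 0,
                           tau = 0, seed = 0L) {
  stopifnot(fs > 0, n_seconds > 0, f_x > 0, f_x < fs / 2, f_y > 0,
            f_y < fs / 2, delta_f_x > 0, sigma_y >= 0, sigma_eps >= 0)
  structure(list(n_seconds = n_seconds, fs = fs, f_x = f_x,
                 delta_f_x = delta_f_x, f_y = f_y, lambda = lambda,
                 sigma_y = sigma_y, sigma_eps = sigma_eps, phi0 = phi0,
                 tau = tau, seed = as.integer(seed)),
            class = "sim_pac_config")
}

#' Simulate a band-limited stochastic driver
#'
#' Gaussian white noise band-pass filtered with the Blackman-cosine filter
#' (and its quadrature sine filter), giving a complex driver whose real part
#' is normalized to unit standard deviation. Smaller bandwidths approach a
#' perfect sinusoid.
#'
#' @param n Number of samples (alternatively pass a config as `cfg`).
#' @param fs,f_x,delta_f_x Sampling rate and driver band (Hz).
#' @param seed Integer seed.
#' @param cfg Optional `sim_pac_config`, overriding the scalar arguments.
#' @return Complex vector of length `n` with `sd(Re(x)) == 1`.
#' @export
simulate_driver <- function(n = NULL, fs = 240, f_x = 3, delta_f_x = 1,
                            seed = 0L, cfg = NULL) {
  if (!is.null(cfg)) {
    n <- n %||% floor(cfg$n_seconds * cfg$fs)
    fs <- cfg$fs; f_x <- cfg$f_x; delta_f_x <- cfg$delta_f_x
    seed <- cfg$seed
  }
  noise <- with_seed(seed, stats::rnorm(n))
  x <- extract_driver(raw_signal(noise, fs), f_x, delta_f_x)
  x / stats::sd(Re(x))
}

#' Sigmoid amplitude modulation
#'
#' `a_y(t) = 1 / (1 + exp(-lambda * x(t)))`: the fast amplitude as a
#' logistic function of the (real) driver value, in `(0, 1)`.
#'
#' @param x_real Real driver values.
#' @param lam Sharpness.
#' @return Amplitude sequence in `(0, 1)`.
#' @export
sigmoid_modulation <- function(x_real, lam) {
  1 / (1 + exp(-lam * x_real))
}

#' Simulate a PAC signal
#'
#' The amplitude of a fast sinusoid at `f_y` is modulated by a sigmoid of
#' the slow driver; the modulated carrier is normalized to `sigma_y`, and
#' the driver (real part) plus Gaussian white noise of standard deviation
#' `sigma_eps` are added. A nonzero `tau` delays the modulation relative to
#' the driver (realized on an extended driver, no wrap-around); a nonzero
#' `phi0` rotates the driver phase at which the amplitude peaks.
#'
#' @param cfg A [sim_pac_config()] (or arguments passed to it via `...`).
#' @param ... Overrides forwarded to [sim_pac_config()].
#' @param keep_components Attach the individual components (driver, carrier,
#'   noise) for diagnostics.
#' @return A [raw_signal]; `meta` carries the full configuration.
#' @export
simulate_pac <- function(cfg = NULL, ..., keep_components = FALSE) {
  cfg <- cfg %||% sim_pac_config(...)
  n <- floor(cfg$n_seconds * cfg$fs)
  k <- round(cfg$tau * cfg$fs)
  with_seed(cfg$seed, {
    noise_long <- stats::rnorm(n + abs(k))
    theta0 <- stats::runif(1, 0, 2 * pi)
    wn <- stats::rnorm(n, 0, cfg$sigma_eps)
    x_long <- extract_driver(raw_signal(noise_long, cfg$fs),
                             cfg$f_x, cfg$delta_f_x)
    x_long <- x_long / stats::sd(Re(x_long))
    a0 <- max(k, 0L)
    x <- x_long[(1L + a0):(n + a0)]                 # driver entering z
    x_mod <- x_long[(1L + a0 - k):(n + a0 - k)]     # x(t - tau)
    a_y <- sigmoid_modulation(Re(x_mod * exp(-1i * cfg$phi0)), cfg$lambda)
    tt <- (seq_len(n) - 1L) / cfg$fs
    carrier <- a_y * cos(2 * pi * cfg$f_y * tt + theta0)
    s <- stats::sd(carrier)
    if (s > 0 && cfg$sigma_y > 0) carrier <- carrier * (cfg$sigma_y / s)
    else carrier <- carrier * 0
    z <- carrier + Re(x) + wn
    out <- raw_signal(z, cfg$fs, meta = list(config = unclass(cfg)))
    if (keep_components) {
      out$components <- list(driver = x, carrier = carrier, noise = wn,
                             a_y = a_y)
    }
    out
  })
}

#' Simulate PAC with a noisy driver band
#'
#' Adds to the PAC signal a Gaussian white noise low-pass filtered at
#' `lowpass_noise_freq` and scaled so that the PSD of the driver exceeds the
#' PSD of the noise by `snr_db_at_fx` dB at the driver frequency.
#'
#' @inheritParams simulate_pac
#' @param lowpass_noise_freq Low-pass cutoff of the added noise (Hz).
#' @param snr_db_at_fx Driver-over-noise PSD gap at `f_x` (dB).
#' @return A [raw_signal].
#' @export
simulate_noisy_driver_pac <- function(cfg = NULL, lowpass_noise_freq = 20,
                                      snr_db_at_fx = 10, ...,
                                      keep_components = FALSE) {
  cfg <- cfg %||% sim_pac_config(...)
  stopifnot(lowpass_noise_freq < cfg$fs / 2)
  base <- simulate_pac(cfg, keep_components = TRUE)
  n <- length(base$samples)
  if (is.infinite(snr_db_at_fx)) {
    if (!keep_components) base$components <- NULL
    return(base)
  }
  lp <- fir_lowpass(cfg$fs, lowpass_noise_freq)
  noise <- with_seed(cfg$seed + 104729L, stats::rnorm(n))
  noise_f <- fir_apply(noise, lp)
  half_bw <- cfg$delta_f_x / 2
  lev_x <- band_psd_level(Re(base$components$driver), cfg$fs,
                          cfg$f_x - half_bw, cfg$f_x + half_bw)
  lev_n <- band_psd_level(noise_f, cfg$fs, cfg$f_x - half_bw,
                          cfg$f_x + half_bw)
  scale <- sqrt(lev_x / (lev_n * 10^(snr_db_at_fx / 10)))
  out <- raw_signal(base$samples + scale * noise_f, cfg$fs,
                    meta = c(base$meta,
                             list(lowpass_noise_freq = lowpass_noise_freq,
                                  snr_db_at_fx = snr_db_at_fx)))
  if (keep_components) {
    out$components <- c(base$components,
                        list(band_noise = scale * noise_f))
  }
  out
}

#' Simulate spurious PAC from a spike train
#'
#' Periodic sharp transients (one-sample rise, exponential decay with a
#' 10 ms time constant) at `spike_rate`, with Gaussian jitter on the spike
#' times, plus background white noise. The sharp edges create broadband
#' harmonics phase-locked to the repetition rate, so PAC metrics detect
#' coupling although the signal contains no nested oscillators.
#'
#' @param fs Sampling rate (Hz).
#' @param n_seconds Duration (s).
#' @param spike_rate Transient repetition rate (Hz), below Nyquist.
#' @param spike_amp Transient amplitude (0 gives pure noise).
#' @param jitter_sd Spike-time jitter standard deviation (s).
#' @param noise_sd Background noise standard deviation.
#' @param seed Integer seed.
#' @return A [raw_signal].
#' @export
simulate_spurious_pac <- function(fs = 240, n_seconds = 20, spike_rate = 10,
                                  spike_amp = 1, jitter_sd = NULL,
                                  noise_sd = 0.1, seed = 0L) {
  stopifnot(spike_rate < fs / 2)
  n <- floor(n_seconds * fs)
  jitter_sd <- jitter_sd %||% (0.05 / spike_rate)
  with_seed(seed, {
    times <- seq(0, n_seconds, by = 1 / spike_rate)
    times <- times + stats::rnorm(length(times), 0, jitter_sd)
    idx <- round(times * fs) + 1L
    idx <- idx[idx >= 1L & idx <= n]
    train <- numeric(n)
    train[idx] <- spike_amp
    decay <- exp(-(0:ceiling(5 * 0.01 * fs)) / (0.01 * fs))
    z <- conv_full(train, decay)[1:n] + stats::rnorm(n, 0, noise_sd)
    raw_signal(z, fs, meta = list(spike_rate = spike_rate,
                                  spike_amp = spike_amp,
                                  jitter_sd = jitter_sd, seed = seed))
  })
}
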