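# Shared fixtures and oracles, all generated in code.

# Memoized default PAC signal (40 s keeps unit tests fast; acceptance tests
# use the full 100 s protocol).
default_pac_signal <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_pac(sim_pac_config(n_seconds = 40, seed = 42))
    cache
  }
})

# Peak periodogram power near a frequency (raw periodogram, no smoothing).
peak_power_near <- function(x, fs, f0, halfwidth = 0.3) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x))[1:(n %/% 2)])^2
  fr <- (0:(n %/% 2 - 1)) * fs / n
  max(sp[fr >= f0 - halfwidth & fr <= f0 + halfwidth])
}

# Fraction of total spectral power inside a band.
band_power_fraction <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x - mean(x))[1:(n %/% 2)])^2
  fr <- (0:(n %/% 2 - 1)) * fs / n
  sum(sp[fr >= f_lo & fr <= f_hi]) / sum(sp)
}

# Independent simulator of a DAR process with affine coefficient and
# log-sigma dependence on a real driver (direct recursion, no shared code
# with the fitting path).
simulate_from_dar <- function(a0, a1, b0, b1, x, seed) {
  p <- length(a0)
  T_ <- length(x)
  y <- numeric(T_)
  set.seed(seed)
  eps <- stats::rnorm(T_)
  for (t in (p + 1):T_) {
    ai <- a0 + a1 * x[t]
    y[t] <- -sum(ai * y[(t - 1):(t - p)]) + exp(b0 + b1 * x[t]) * eps[t]
  }
  y
}

# Reference stable AR(10) polynomial (five damped resonances at 240 Hz);
# with coefficient modulation gamma the per-sample poles stay inside the
# unit circle for driver values |x| < 3.5.
dar_truth <- local({
  fs <- 240
  poles <- c(0.92 * exp(2i * pi * 50 / fs), 0.88 * exp(2i * pi * 30 / fs),
             0.84 * exp(2i * pi * 80 / fs), 0.78 * exp(2i * pi * 15 / fs),
             0.72 * exp(2i * pi * 100 / fs))
  poles <- c(poles, Conj(poles))
  co <- 1
  for (pp in poles) co <- c(co, 0) - c(0, pp * co)
  list(a0 = Re(co[-1]), gamma = 0.12, b0 = 0, b1 = 0.2, fs = fs)
})

# Wrap plain (y, x) vectors as a driver_pair for the selection functions.
as_pair <- function(y, x, fs = 240, f_x = 3, delta_f_x = 1) {
  structure(list(x = x, y = y, fs = fs, f_x = f_x, delta_f_x = delta_f_x,
                 whitening_order = 0L, whitening_ar = numeric(0),
                 rng_seed = 0L, meta = list()),
            class = "driver_pair")
}
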