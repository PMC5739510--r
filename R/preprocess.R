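# Preprocessing chain: raw signal z -> complex driver x and driver-free,
# gap-filled, whitened fast signal y.

#' Remove power-line interference by sinusoid projection
#'
#' The line frequency is estimated by projecting the signal onto cosine/sine
#' pairs over a fine frequency grid around the nominal frequency; the
#' maximum-power projection is subtracted. Harmonics are handled by repeating
#' the projection at multiples of the estimated line frequency.
#'
#' @param signal A [raw_signal] (or numeric vector with `fs` supplied).
#' @param nominal_freq Nominal line frequency in Hz (e.g. 50 or 60).
#' @param search_halfwidth Half-width of the search interval (Hz).
#' @param grid_resolution Search grid resolution (Hz).
#' @param n_harmonics Number of harmonics (including the fundamental) to
#'   remove; harmonics above Nyquist are skipped.
#' @param fs Sampling rate, only needed for plain vectors.
#' @return A [raw_signal] with the line components subtracted.
#' @export
remove_powerline <- function(signal, nominal_freq, search_halfwidth = 0.5,
                             grid_resolution = 0.01, n_harmonics = 1L,
                             fs = NULL) {
  sig <- as_raw_signal(signal, fs)
  z <- sig$samples
  fs <- sig$fs
  if (nominal_freq >= fs / 2)
    stop(sprintf("nominal_freq = %g Hz is at or above Nyquist (%g Hz)",
                 nominal_freq, fs / 2))
  if (nominal_freq <= 0) stop("nominal_freq must be positive")
  tt <- (seq_along(z) - 1L) / fs
  grid <- seq(nominal_freq - search_halfwidth, nominal_freq + search_halfwidth,
              by = grid_resolution)
  grid <- grid[grid > 0 & grid < fs / 2]
  proj_power <- vapply(grid, function(f) {
    c1 <- sum(z * cos(2 * pi * f * tt))
    s1 <- sum(z * sin(2 * pi * f * tt))
    c1^2 + s1^2
  }, numeric(1))
  f_line <- grid[which.max(proj_power)]
  removed <- numeric(0)
  for (k in seq_len(n_harmonics)) {
    fk <- k * f_line
    if (fk >= fs / 2) break
    X <- cbind(cos(2 * pi * fk * tt), sin(2 * pi * fk * tt))
    co <- stats::.lm.fit(X, z)$coefficients
    z <- z - X %*% co
    removed <- c(removed, fk)
  }
  raw_signal(as.numeric(z), fs,
             meta = c(sig$meta, list(powerline_removed = removed)))
}

#' Resample a signal to a new rate
#'
#' Anti-aliased resampling to an arbitrary target rate: when downsampling,
#' the signal is first low-pass filtered (zero-phase windowed-sinc FIR with
#' cutoff at 45% of the target rate), then interpolated at the new sample
#' times. Downsampling to a few hundred Hz is the usual first step before
#' PAC analysis, since only frequencies up to `fs/2` are modeled.
#'
#' @param signal A [raw_signal] (or numeric vector with `fs`).
#' @param fs_target Target sampling rate (Hz).
#' @param fs Sampling rate for plain vectors.
#' @return A [raw_signal] at the target rate.
#' @export
resample_signal <- function(signal, fs_target, fs = NULL) {
  sig <- as_raw_signal(signal, fs)
  if (fs_target <= 0) stop("fs_target must be positive")
  if (fs_target == sig$fs) return(sig)
  x <- sig$samples
  if (fs_target < sig$fs) {
    n_taps <- min(4001L, as.integer(55 * sig$fs / fs_target) %/% 2L * 2L + 1L)
    x <- fir_apply(x, fir_lowpass(sig$fs, 0.45 * fs_target, n_taps))
  }
  tt <- (seq_along(x) - 1L) / sig$fs
  t_new <- seq(0, tt[length(tt)], by = 1 / fs_target)
  out <- stats::spline(tt, x, xout = t_new)$y
  raw_signal(out, fs_target,
             meta = c(sig$meta, list(resampled_from = sig$fs)))
}

#' Extract the complex driver
#'
#' Filters the raw signal with the Blackman-cosine filter to obtain `x1` and
#' with the quadrature Blackman-sine filter to obtain `x2`, and returns the
#' complex driver `x = x1 + i x2`. Both filters are zero-phase
#' (reflect-padded application).
#'
#' @inheritParams remove_powerline
#' @param f_x Driver center frequency (Hz).
#' @param delta_f_x Driver bandwidth at -3 dB (Hz).
#' @return Complex vector, same length as the signal.
#' @export
extract_driver <- function(signal, f_x, delta_f_x, fs = NULL) {
  sig <- as_raw_signal(signal, fs)
  fc <- design_driver_filter(sig$fs, f_x, delta_f_x, "cosine")
  fsn <- design_driver_filter(sig$fs, f_x, delta_f_x, "sine")
  complex(real = fir_apply(sig$samples, fc),
          imaginary = fir_apply(sig$samples, fsn))
}

#' Fill the spectral gap left by driver subtraction
#'
#' After subtracting the driver band, `y = z - x1` has a notch around `f_x`
#' that would distort a compact AR spectral model. The notch is filled by
#' adding Gaussian white noise filtered with the same driver filter, scaled so
#' that the PSD across the gap is continuous: the target level is the
#' geometric mean of Welch PSD levels on the two flanks of the gap (each
#' flank `2 * delta_f_x` wide).
#'
#' @param y Numeric vector (signal with the spectral notch).
#' @param filt A `driver_filter` (the filter that carved the notch).
#' @param rng_seed Integer seed; the fill noise is deterministic given it.
#' @return Numeric vector `y` plus scaled filtered noise, with attributes
#'   `fill_scale` (noise standard-deviation multiplier before filtering) and
#'   `fill_seed`.
#' @export
fill_gap <- function(y, filt, rng_seed = 0L) {
  if (length(filt$taps) == 0L) return(y)
  fs <- filt$fs
  f_x <- filt$f_x
  d <- filt$delta_f_x
  gap_lo <- max(f_x - d, 0)
  gap_hi <- min(f_x + d, fs / 2)
  flank_lo <- band_psd_level(y, fs, max(gap_lo - 2 * d, 0), gap_lo)
  flank_hi <- band_psd_level(y, fs, gap_hi, min(gap_hi + 2 * d, fs / 2))
  target <- sqrt(flank_lo * flank_hi)
  level_y <- band_psd_level(y, fs, f_x - d / 2, f_x + d / 2)
  noise <- with_seed(rng_seed, stats::rnorm(length(y)))
  noise_f <- fir_apply(noise, filt)
  level_n <- band_psd_level(noise_f, fs, f_x - d / 2, f_x + d / 2)
  scale <- sqrt(max(target - level_y, 0) / level_n)
  out <- y + scale * noise_f
  attr(out, "fill_scale") <- scale
  attr(out, "fill_seed") <- rng_seed
  out
}

#' Temporal whitening with an inverse AR filter
#'
#' Fits an ordinary AR model of the given order (Burg method) and applies the
#' inverse FIR filter `1 - sum(phi_i z^-i)`, flattening the spectrum of `y` so
#' that subsequent driven-AR fits only need to model the modulation. The first
#' samples use a reflect-padded start so the output keeps full length.
#'
#' @param y Numeric vector.
#' @param order AR order (>= 0); `order = 0` returns `y` unchanged.
#' @return List with `y` (whitened signal) and `ar` (AR coefficients, in the
#'   `stats::ar` convention `y(t) = sum(ar_i y(t-i)) + e(t)`).
#' @export
whiten <- function(y, order = 10L) {
  y <- as.numeric(y)
  if (order == 0L) return(list(y = y, ar = numeric(0)))
  if (order < 0L) stop("order must be >= 0")
  if (order >= length(y) / 10)
    stop("whitening order too large for signal length")
  fit <- stats::ar(y, aic = FALSE, order.max = order, method = "burg",
                   demean = TRUE)
  a <- as.numeric(fit$ar)
  yc <- y - mean(y)
  yp <- c(rev(yc[2:(order + 1L)]), yc)
  w <- stats::filter(yp, c(1, -a), method = "convolution", sides = 1L)
  list(y = as.numeric(w[(order + 1L):length(w)]), ar = a)
}

#' Prepare a driver pair from a raw signal
#'
#' Runs the full preprocessing chain: extract the complex driver `x`, subtract
#' its real part to get `y = z - x1`, fill the spectral gap with filtered
#' noise, and whiten `y` with a linear AR model. This is the standard input
#' to [fit_dar()].
#'
#' @inheritParams extract_driver
#' @param whitening_order Order of the whitening AR model (0 disables).
#' @param rng_seed Integer seed for the gap-fill noise.
#' @param keep_intermediate Keep the pre-gap-fill and pre-whitening signals
#'   (for diagnostics); off by default.
#' @return A `driver_pair`: list with complex `x`, real `y` (same length),
#'   `fs`, `f_x`, `delta_f_x`, `whitening_order`, `whitening_ar`, `rng_seed`
#'   and a `meta` record of all preprocessing parameters.
#' @export
prepare_pair <- function(signal, f_x, delta_f_x, whitening_order = 10L,
                         rng_seed = 0L, fs = NULL, keep_intermediate = FALSE) {
  sig <- as_raw_signal(signal, fs)
  x <- extract_driver(sig, f_x, delta_f_x)
  filt <- design_driver_filter(sig$fs, f_x, delta_f_x, "cosine")
  y0 <- sig$samples - Re(x)
  yg <- fill_gap(y0, filt, rng_seed)
  wh <- whiten(as.numeric(yg), whitening_order)
  pair <- structure(list(
    x = x, y = wh$y, fs = sig$fs, f_x = f_x, delta_f_x = delta_f_x,
    whitening_order = whitening_order, whitening_ar = wh$ar,
    rng_seed = rng_seed,
    meta = list(fill_scale = attr(yg, "fill_scale"),
                n_taps = length(filt$taps), source_meta = sig$meta)),
    class = "driver_pair")
  if (keep_intermediate) {
    pair$y_before_fill <- y0
    pair$y_before_whiten <- as.numeric(yg)
  }
  pair
}

#' @export
print.driver_pair <- function(x, ...) {
  cat(sprintf(
    "<driver_pair> %d samples at %g Hz | driver f_x = %g Hz, bandwidth %g Hz | whitening order %d\n",
    length(x$y), x$fs, x$f_x, x$delta_f_x, x$whitening_order))
  invisible(x)
}

# Subset a driver_pair to an index range (used by cross-validation).
slice_pair <- function(pair, idx) {
  out <- pair
  out$x <- pair$x[idx]
  out$y <- pair$y[idx]
  out
}

#' Prepare the common fast signal for a driver grid search
#'
#' For a likelihood comparison across candidate drivers, every model must be
#' fitted on the exact same `y`. All candidate driver bands are removed at
#' once with a high-pass filter above the maximum candidate center frequency,
#' the emptied low band is refilled with complementary low-pass-filtered
#' noise (energy-matched to the flank just above the cutoff), and the result
#' is whitened once.
#'
#' @inheritParams prepare_pair
#' @param f_x_max Highest candidate driver center frequency (Hz); the
#'   high-pass cutoff.
#' @param n_taps High-pass filter length (odd).
#' @return Numeric vector `y` usable with every candidate driver, with
#'   attributes `whitening_ar` and `fill_scale`.
#' @export
prepare_for_gridsearch <- function(signal, f_x_max, whitening_order = 10L,
                                   rng_seed = 0L, n_taps = 513L, fs = NULL) {
  sig <- as_raw_signal(signal, fs)
  fs <- sig$fs
  if (f_x_max >= fs / 2) stop("f_x_max must be below Nyquist")
  hp <- fir_highpass(fs, f_x_max, n_taps)
  y <- fir_apply(sig$samples, hp)
  # complementary low-pass: delta - highpass
  lp <- -hp
  lp[(length(hp) + 1L) %/% 2L] <- lp[(length(hp) + 1L) %/% 2L] + 1
  flank_width <- max(2, 0.5 * f_x_max)
  target <- band_psd_level(y, fs, f_x_max, min(f_x_max + flank_width, fs / 2))
  noise <- with_seed(rng_seed, stats::rnorm(length(y)))
  noise_f <- fir_apply(noise, lp)
  low_band <- c(max(0.25 * f_x_max, 0.5), 0.75 * f_x_max)
  level_n <- band_psd_level(noise_f, fs, low_band[1], low_band[2])
  level_y <- band_psd_level(y, fs, low_band[1], low_band[2])
  scale <- sqrt(max(target - level_y, 0) / level_n)
  y <- y + scale * noise_f
  wh <- whiten(y, whitening_order)
  out <- wh$y
  attr(out, "whitening_ar") <- wh$ar
  attr(out, "fill_scale") <- scale
  out
}
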