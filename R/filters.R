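# FIR filtering primitives: the Blackman-cosine driver filter and zero-phase
# application with reflect padding.

#' Design the band-pass driver filter
#'
#' The driver-extraction filter is a Blackman window modulated by a cosine (or
#' sine, for the quadrature component): `w(t) = b(t) cos(2 pi f_x t)`. The
#' window length is `floor(1.65 * fs / delta_f_x)` rounded down to an odd tap
#' count, which gives a bandwidth of `delta_f_x` at -3 dB: the power
#' attenuation is 50% at `f_x +/- delta_f_x/2` (within 0.05 dB).
#' Taps are scaled so the magnitude response at `f_x` equals 1, making driver
#' amplitudes comparable across candidate `(f_x, delta_f_x)` pairs.
#'
#' @param fs Sampling rate (Hz).
#' @param f_x Center frequency (Hz), in `(0, fs/2)`.
#' @param delta_f_x Bandwidth at -3 dB (Hz), positive.
#' @param phase_variant `"cosine"` (symmetric taps) or `"sine"` (antisymmetric
#'   taps, the quadrature filter used to build the complex driver).
#' @return A `driver_filter` object with fields `taps`, `f_x`, `delta_f_x`,
#'   `fs`, `phase_variant`.
#' @export
design_driver_filter <- function(fs, f_x, delta_f_x,
                                 phase_variant = c("cosine", "sine")) {
  phase_variant <- match.arg(phase_variant)
  if (f_x <= 0 || f_x >= fs / 2)
    stop(sprintf("f_x = %g Hz must lie strictly inside (0, %g) Hz", f_x, fs / 2))
  if (delta_f_x <= 0) stop("delta_f_x must be positive")
  half <- floor(1.65 * fs / delta_f_x) %/% 2L
  if (half < 1L) stop("delta_f_x too large for this sampling rate")
  n <- 2L * half + 1L
  tt <- (-half:half) / fs
  b <- as.numeric(signal::blackman(n))
  taps <- if (phase_variant == "cosine") b * cos(2 * pi * f_x * tt)
          else                           b * sin(2 * pi * f_x * tt)
  # unit magnitude response at f_x
  h <- sum(taps * exp(-2i * pi * f_x * (0:(n - 1L)) / fs))
  taps <- taps / Mod(h)
  structure(list(taps = taps, f_x = f_x, delta_f_x = delta_f_x, fs = fs,
                 phase_variant = phase_variant),
            class = "driver_filter")
}

#' @export
print.driver_filter <- function(x, ...) {
  cat(sprintf("<driver_filter> %s, %d taps, f_x = %g Hz, bandwidth %g Hz at fs = %g Hz\n",
              x$phase_variant, length(x$taps), x$f_x, x$delta_f_x, x$fs))
  invisible(x)
}

#' Frequency response of an FIR filter
#'
#' @param taps Numeric vector of filter taps (or a `driver_filter`).
#' @param freqs Frequencies (Hz) at which to evaluate the response.
#' @param fs Sampling rate (Hz); taken from the filter if available.
#' @return Complex response (group delay of `(n-1)/2` samples included).
#' @export
fir_freq_response <- function(taps, freqs, fs = NULL) {
  if (inherits(taps, "driver_filter")) {
    fs <- taps$fs
    taps <- taps$taps
  }
  if (is.null(fs)) stop("`fs` required")
  vapply(freqs, function(f)
    sum(taps * exp(-2i * pi * f * (seq_along(taps) - 1L) / fs)),
    complex(1))
}

#' Zero-phase FIR filtering with reflect padding
#'
#' Applies an odd-length FIR filter, compensating the pure delay of the
#' symmetric/antisymmetric taps. The signal is reflect-padded by half the
#' filter length on each side and the central part of the convolution kept,
#' so the output is full-length and zero-phase.
#'
#' @param x Numeric vector.
#' @param taps FIR taps (odd length) or a `driver_filter`.
#' @return Filtered vector, same length as `x`.
#' @export
fir_apply <- function(x, taps) {
  if (inherits(taps, "driver_filter")) taps <- taps$taps
  n <- length(taps)
  if (n == 0L) return(x)
  if (n %% 2L == 0L) stop("filter length must be odd")
  half <- (n - 1L) %/% 2L
  if (half == 0L) return(x * taps)
  T_ <- length(x)
  if (n > T_)
    warning(sprintf("filter (%d taps) longer than signal (%d samples)", n, T_))
  lp <- pmin(half, T_ - 1L)
  xp <- c(rev(x[2:(lp + 1L)]), x, rev(x[(T_ - lp):(T_ - 1L)]))
  if (lp < half) {  # extremely short signal: extend by repetition
    extra <- half - lp
    xp <- c(rep(xp[1], extra), xp, rep(xp[length(xp)], extra))
  }
  out <- conv_full(xp, taps)
  out[(2L * half + 1L):(2L * half + T_)]
}

# Full linear convolution via FFT; returns length(a) + length(b) - 1 samples.
conv_full <- function(a, b) {
  la <- length(a); lb <- length(b)
  L <- la + lb - 1L
  nf <- stats::nextn(L, 2)
  fa <- stats::fft(c(a, numeric(nf - la)))
  fb <- stats::fft(c(b, numeric(nf - lb)))
  Re(stats::fft(fa * fb, inverse = TRUE))[1:L] / nf
}

# Windowed-sinc low/high-pass with Blackman window (signal::fir1), zero-phase
# application. Used for grid-search preparation and noisy-driver simulation.
fir_lowpass <- function(fs, cutoff, n_taps = 513L) {
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  as.numeric(signal::fir1(n_taps - 1L, cutoff / (fs / 2), type = "low",
                          window = signal::blackman(n_taps)))
}

fir_highpass <- function(fs, cutoff, n_taps = 513L) {
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  as.numeric(signal::fir1(n_taps - 1L, cutoff / (fs / 2), type = "high",
                          window = signal::blackman(n_taps)))
}

#' Analytic signal via the FFT
#'
#' Discrete Hilbert-transform construction of the analytic signal
#' `x + i H(x)`. The record is reflect-padded before the transform to limit
#' edge artifacts; callers discard edge samples where relevant.
#'
#' @param x Real vector.
#' @param pad Padding length on each side (samples).
#' @return Complex vector, same length as `x`.
#' @export
analytic_signal <- function(x, pad = NULL) {
  T_ <- length(x)
  pad <- pad %||% min(T_ - 1L, 1024L)
  xp <- if (pad > 0L) c(rev(x[2:(pad + 1L)]), x, rev(x[(T_ - pad):(T_ - 1L)])) else x
  n <- length(xp)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n %/% 2L + 1L)] <- 1
    h[2:(n %/% 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) %/% 2L)] <- 2
  }
  a <- stats::fft(h * stats::fft(xp), inverse = TRUE) / n
  a[(pad + 1L):(pad + T_)]
}
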