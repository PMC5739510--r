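#' @keywords internal
#' @useDynLib darpac, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft rnorm runif sd var median quantile
#' @importFrom utils head tail
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a raw signal object
#'
#' A `raw_signal` is a univariate, regularly sampled time series together with
#' its sampling rate. It is the input type of the preprocessing, comodulogram
#' and simulation functions.
#'
#' @param samples Numeric vector of samples (arbitrary units), length >= 2,
#'   no missing values.
#' @param fs Sampling rate in Hz, must be positive.
#' @param meta Free-form provenance information (string or list).
#' @return An object of class `raw_signal` with fields `samples`, `fs`, `meta`.
#' @export
raw_signal <- function(samples, fs, meta = list()) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number (Hz)")
  if (length(samples) < 2L)
    stop("`samples` must contain at least 2 values")
  if (anyNA(samples))
    stop("`samples` must not contain missing values")
  structure(list(samples = samples, fs = fs, meta = meta),
            class = "raw_signal")
}

#' @export
print.raw_signal <- function(x, ...) {
  cat(sprintf("<raw_signal> %d samples at %g Hz (%.2f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.raw_signal <- function(x) length(x$samples)

# Accept either a raw_signal or a bare numeric vector (then fs is required).
as_raw_signal <- function(signal, fs = NULL) {
  if (inherits(signal, "raw_signal")) return(signal)
  if (is.null(fs)) stop("`fs` is required when `signal` is a plain vector")
  raw_signal(signal, fs)
}

#' Band-averaged power spectral density level
#'
#' Averaged-periodogram estimate of the PSD level of `x` in the band
#' `[f_lo, f_hi]` (Hz), used for gap-fill energy matching and for tests.
#' The estimate is segment-averaged (Welch-style, 50% overlap, Hann taper),
#' returned in power per Hz up to a constant common to all calls.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param f_lo,f_hi Band edges in Hz.
#' @param n_seg Segment length (samples); default `min(length(x), 1024)`.
#' @return Scalar PSD level (linear units).
#' @export
band_psd_level <- function(x, fs, f_lo, f_hi, n_seg = NULL) {
  w <- welch_psd(x, fs, n_seg = n_seg)
  sel <- w$freq >= f_lo & w$freq <= f_hi
  if (!any(sel)) sel <- which.min(abs(w$freq - (f_lo + f_hi) / 2))
  mean(w$psd[sel])
}

# Segment-averaged (Welch) PSD: Hann taper, 50% overlap, one-sided, per Hz.
welch_psd <- function(x, fs, n_seg = NULL) {
  n <- length(x)
  n_seg <- n_seg %||% min(n, 1024L)
  n_seg <- min(n_seg, n)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(n_seg) / (n_seg + 1))
  step <- max(1L, n_seg %/% 2L)
  starts <- seq(1L, n - n_seg + 1L, by = step)
  nf <- n_seg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + n_seg - 1L)]
    seg <- (seg - mean(seg)) * taper
    sp <- Mod(stats::fft(seg)[1:nf])^2
    acc <- acc + sp
  }
  scale <- fs * sum(taper^2)
  psd <- 2 * acc / (length(starts) * scale)
  psd[1] <- psd[1] / 2
  if (n_seg %% 2L == 0L) psd[nf] <- psd[nf] / 2
  list(freq = seq(0, by = fs / n_seg, length.out = nf), psd = psd)
}

# Linear power ratio in decibels.
to_db <- function(p) 10 * log10(p)

# Deterministic RNG scope: all stochastic functions funnel through this.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  withr::with_seed(as.integer(seed), code)
}

# Lexicographically first argmax of a matrix; returns c(row, col).
argmax_lex <- function(mat) {
  best <- which(mat == max(mat, na.rm = TRUE), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  best[1, ]
}
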