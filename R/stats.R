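# Surrogate-based significance for comodulograms and block-bootstrap
# uncertainty for scalar estimators.

#' Surrogate threshold for a comodulogram
#'
#' Builds a null distribution of the comodulogram maximum by circularly
#' shifting the driver pathway relative to the fast signal by a random
#' offset (at least `min_shift`), recomputing the entire comodulogram, and
#' keeping only its maximum. The threshold is the requested percentile of
#' the surrogate maxima; using the max statistic avoids multiple-testing
#' corrections across grid cells. Shifting the extracted pathway preserves
#' both marginal spectra.
#'
#' @inheritParams comodulogram_dar
#' @param method `"dar"`, `"tort"`, `"ozkurt"`, or `"penny"`.
#' @param n_surrogates Number of surrogate shifts (>= 20).
#' @param percentile Threshold percentile of the surrogate maxima (e.g. 99
#'   for p = 0.01).
#' @param min_shift Minimum shift in seconds; default
#'   `max(1, 3 / min(driver_freqs))` (one second or three driver periods,
#'   whichever is larger).
#' @param comod_args List of extra arguments for the comodulogram engine
#'   (e.g. `p`, `m`, `n_phases`, `n_fft`, `whitening_order` for
#'   `method = "dar"`; `f_y_grid`, `delta_f_y`, `n_bins` for baselines).
#' @return A `surrogate_null`: `max_values`, `threshold`, `percentile`,
#'   `observed` (comodulogram with `sig_mask` filled), `n_surrogates`,
#'   `min_shift`.
#' @export
surrogate_threshold <- function(signal, method = "dar",
                                driver_freqs = seq(1, 7, by = 0.5),
                                delta_f_x = 1.0, n_surrogates = 1000L,
                                percentile = 99, rng_seed = 0L,
                                min_shift = NULL, comod_args = list(),
                                fs = NULL) {
  stopifnot(n_surrogates >= 20L)
  sig <- as_raw_signal(signal, fs)
  min_shift <- min_shift %||% max(1, 3 / min(driver_freqs))
  min_k <- round(min_shift * sig$fs)
  T_ <- length(sig$samples)
  if (2L * min_k >= T_)
    stop("signal too short for the minimum surrogate shift")
  if (method == "dar") {
    a <- comod_args
    eng <- dar_comod_engine(sig, driver_freqs, delta_f_x,
                            p = a$p %||% 10L, m = a$m %||% 1L,
                            whitening_order = a$whitening_order %||% 10L,
                            rng_seed = rng_seed,
                            variant = a$variant %||% "dar",
                            n_phases = a$n_phases %||% 40L,
                            n_fft = a$n_fft %||% 256L,
                            n_outer = a$n_outer %||% 2L,
                            signal_freq_range = a$signal_freq_range)
  } else {
    a <- comod_args
    f_y_grid <- a$f_y_grid %||%
      seq(2.5 * max(driver_freqs), 0.9 * sig$fs / 2, length.out = 25L)
    eng <- baseline_comod_engine(sig, method, driver_freqs, delta_f_x,
                                 f_y_grid,
                                 a$delta_f_y %||% (2 * max(driver_freqs)),
                                 n_bins = a$n_bins %||% 18L)
  }
  observed_vals <- eng$compute(0L)
  shifts <- with_seed(rng_seed,
                      sample.int(T_ - 2L * min_k, n_surrogates,
                                 replace = TRUE) + min_k)
  max_values <- vapply(shifts, function(s)
    max(eng$compute(s), na.rm = TRUE), numeric(1))
  threshold <- as.numeric(stats::quantile(max_values, percentile / 100,
                                          names = FALSE))
  observed <- structure(list(
    driver_freqs = driver_freqs, signal_freqs = eng$signal_freqs,
    values = observed_vals, method = method,
    params = c(list(delta_f_x = delta_f_x, fs = eng$fs), comod_args),
    sig_mask = observed_vals > threshold,
    failed = numeric(0)), class = "comodulogram")
  structure(list(max_values = max_values, threshold = threshold,
                 percentile = percentile, n_surrogates = n_surrogates,
                 min_shift = min_shift, observed = observed,
                 observed_max = max(observed_vals, na.rm = TRUE),
                 rng_seed = rng_seed),
            class = "surrogate_null")
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat(sprintf(
    "<surrogate_null> %d surrogates | threshold (p = %.3g): %.4g | observed max: %.4g (%s)\n",
    x$n_surrogates, 1 - x$percentile / 100, x$threshold, x$observed_max,
    if (x$observed_max > x$threshold) "significant" else "not significant"))
  invisible(x)
}

#' Block-bootstrap standard deviation of an estimator
#'
#' Splits the signal into `n_blocks` non-overlapping blocks of equal length,
#' draws `n_blocks` blocks at random with replacement, concatenates them,
#' re-runs the estimator, and repeats; returns the standard deviation of the
#' estimates. Suitable for empirical uncertainty of statistics of
#' (locally) stationary time series, such as the coupling delay.
#'
#' @param signal A [raw_signal] or numeric vector.
#' @param estimator Function mapping a [raw_signal] to a scalar.
#' @param n_blocks Number of blocks (paper protocol: 100).
#' @param n_repeats Number of bootstrap repetitions (paper protocol: 20).
#' @param rng_seed Integer seed.
#' @param fs Sampling rate for plain vectors.
#' @return Scalar standard deviation, with attributes `estimates` and
#'   `n_failed` (failed resamples are excluded and counted).
#' @export
block_bootstrap_std <- function(signal, estimator, n_blocks = 100L,
                                n_repeats = 20L, rng_seed = 0L, fs = NULL) {
  sig <- as_raw_signal(signal, fs)
  T_ <- length(sig$samples)
  if (2L * n_blocks > T_) stop("too many blocks for this signal length")
  blen <- T_ %/% n_blocks
  starts <- (seq_len(n_blocks) - 1L) * blen + 1L
  ests <- with_seed(rng_seed, {
    vapply(seq_len(n_repeats), function(r) {
      picks <- sample.int(n_blocks, n_blocks, replace = TRUE)
      idx <- unlist(lapply(starts[picks], function(s) s:(s + blen - 1L)))
      tryCatch(estimator(raw_signal(sig$samples[idx], sig$fs)),
               error = function(e) NA_real_)
    }, numeric(1))
  })
  out <- stats::sd(ests[!is.na(ests)])
  attr(out, "estimates") <- ests
  attr(out, "n_failed") <- sum(is.na(ests))
  out
}
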