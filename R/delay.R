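# Coupling delay estimation: likelihood profile over a grid of driver
# shifts, on forward and time-reversed signals (summing the two
# log-likelihoods cancels the filtering bias), plus a modified
# phase-slope-index comparator.

#' Shift the driver in time
#'
#' `x_tau(t) = x(t - tau)` realized as an integer-sample shift
#' (`round(tau * fs)`). Only the overlapping support is valid; the returned
#' vector keeps full length with the `valid` attribute marking the indices
#' where the shifted driver is defined (edges are repeated-edge padded).
#'
#' @param x Driver vector (complex or real).
#' @param tau Delay in seconds; positive means the past driver is used.
#' @param fs Sampling rate (Hz).
#' @return Shifted driver with attribute `valid` (index range).
#' @export
shift_driver <- function(x, tau, fs) {
  n <- length(x)
  k <- round(tau * fs)
  if (abs(k) >= n) stop("shift is at least as long as the signal")
  if (k == 0L) {
    attr(x, "valid") <- c(1L, n)
    return(x)
  }
  if (k > 0L) {
    out <- c(rep(x[1], k), x[1:(n - k)])
    attr(out, "valid") <- c(k + 1L, n)
  } else {
    out <- c(x[(1 - k):n], rep(x[n], -k))
    attr(out, "valid") <- c(1L, n + k)
  }
  out
}

#' Likelihood profile over coupling delays
#'
#' For each candidate delay `tau`, a DAR model is fitted with the shifted
#' driver `x(t - tau)` on the forward signal and, with the opposite shift,
#' on the time-reversed signal; the two negative log-likelihoods are summed.
#' Filtering biases affect both directions alike and cancel in the sum. All
#' grid cells are evaluated on the common valid support (equal sample
#' counts), so the profile is comparable across delays. A positive best
#' delay means the past driver fits best: the slow oscillation precedes the
#' amplitude modulation.
#'
#' @param pair A `driver_pair`.
#' @param tau_grid Candidate delays in seconds; default 25 points spanning
#'   +/- 1.5 driver periods.
#' @param p,m,variant,n_outer Model specification.
#' @return A `delay_profile`: `delays`, `neg_loglik` (summed, per sample),
#'   `neg_loglik_fwd`, `neg_loglik_rev`, `best_delay` (s).
#' @export
delay_profile <- function(pair, tau_grid = NULL, p = 10L, m = 1L,
                          variant = "dar", n_outer = 2L) {
  fs <- pair$fs
  tau_grid <- tau_grid %||%
    seq(-1.5 / pair$f_x, 1.5 / pair$f_x, length.out = 25L)
  ks <- round(tau_grid * fs)
  T_ <- length(pair$y)
  kmax <- max(abs(ks))
  if (p + 1L + 2L * kmax + 20L >= T_) stop("tau grid too wide for this signal")
  # common support (forward time): excludes every shifted edge
  t0 <- p + 1L + kmax
  t1 <- T_ - kmax
  y_rev <- rev(pair$y)
  x_rev <- Conj(rev(pair$x))
  nll_f <- nll_r <- numeric(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    xf <- shift_driver(pair$x, k / fs, fs)
    xr <- shift_driver(x_rev, -k / fs, fs)
    ff <- fit_dar(pair$y, p = p, m = m, variant = variant, x = xf,
                  n_outer = n_outer, support_start = t0, support_end = t1)
    fr <- fit_dar(y_rev, p = p, m = m, variant = variant, x = xr,
                  n_outer = n_outer, support_start = t0, support_end = t1)
    nll_f[i] <- -ff$loglik_per_sample
    nll_r[i] <- -fr$loglik_per_sample
  }
  nll <- nll_f + nll_r
  best <- which(nll == min(nll))[1]
  structure(list(delays = ks / fs, neg_loglik = nll,
                 neg_loglik_fwd = nll_f, neg_loglik_rev = nll_r,
                 best_delay = ks[best] / fs, fs = fs, f_x = pair$f_x,
                 p = p, m = m, variant = variant),
            class = "delay_profile")
}

#' @export
print.delay_profile <- function(x, ...) {
  cat(sprintf(
    "<delay_profile> %d delays in [%.3g, %.3g] s | best delay %.4g s (%.3g driver periods)\n",
    length(x$delays), min(x$delays), max(x$delays), x$best_delay,
    x$best_delay * x$f_x))
  invisible(x)
}

#' Delay estimate from a modified phase slope index
#'
#' Computes the complex coherence between the (real part of the) driver and
#' the fast-amplitude envelope on a smoothed periodogram, forms the phase
#' slope index over the given band, `PSI(F) = Im(sum conj(C(f)) C(f + df))`,
#' and converts it to seconds, `tau = PSI / (2 pi df n_F)`. The estimator
#' assumes near-perfect coherence and a small phase slope; it is biased
#' toward zero for large delays and is intended only for qualitative
#' comparison with [delay_profile()].
#'
#' @param x Driver (complex or real vector).
#' @param y_envelope Amplitude envelope of the band-passed fast signal.
#' @param freq_band Numeric length-2, band `F` in Hz.
#' @param fs Sampling rate (Hz).
#' @param spans Smoothing spans for the periodogram (passed to
#'   [stats::spec.pgram()]).
#' @return Delay estimate in seconds.
#' @export
psi_delay <- function(x, y_envelope, freq_band, fs, spans = c(25, 25)) {
  stopifnot(length(freq_band) == 2, freq_band[1] < freq_band[2],
            freq_band[2] < fs / 2, freq_band[1] >= 0)
  x1 <- Re(x)
  n <- min(length(x1), length(y_envelope))
  dat <- stats::ts(cbind(x1[1:n], y_envelope[1:n]), frequency = fs)
  sp <- stats::spec.pgram(dat, spans = spans, taper = 0.1, detrend = TRUE,
                          plot = FALSE)
  C <- sqrt(pmin(sp$coh[, 1], 1)) * exp(1i * sp$phase[, 1])
  sel <- which(sp$freq >= freq_band[1] & sp$freq <= freq_band[2])
  if (length(sel) < 2) stop("frequency band too narrow for the resolution")
  df <- sp$freq[2] - sp$freq[1]
  i1 <- sel[-length(sel)]
  psi <- Im(sum(Conj(C[i1]) * C[i1 + 1L]))
  psi / (2 * pi * df * length(i1))
}
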