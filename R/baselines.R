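# Classical PAC metrics for comparison: Tort's KL-based modulation index,
# Ozkurt's normalized mean vector length, and Penny's GLM-based measure.
# All operate on the instantaneous phase of the slow band and amplitude of
# the fast band, obtained by band-pass filtering plus the analytic signal.

#' Extract instantaneous phase and amplitude
#'
#' Band-pass filters the signal around `f_x` (bandwidth `delta_f_x`) and
#' around `f_y` (bandwidth `delta_f_y`), using the Blackman-cosine design,
#' then takes the analytic-signal phase of the slow band and magnitude of
#' the fast band. Edge samples (half the longer filter) are excluded.
#' Amplitude modulation at `f_y` is only observable when
#' `delta_f_y > 2 f_x`; a warning is emitted otherwise.
#'
#' @inheritParams extract_driver
#' @param f_y,delta_f_y Fast band center and bandwidth (Hz).
#' @return A `phase_amplitude` object: `phase` (radians in `[-pi, pi)`),
#'   `amplitude` (fast envelope), `amplitude_x` (slow envelope, used by the
#'   GLM metric with amplitude terms), band parameters, `fs`.
#' @export
phase_amplitude <- function(signal, f_x, delta_f_x, f_y, delta_f_y,
                            fs = NULL) {
  sig <- as_raw_signal(signal, fs)
  if (delta_f_y <= 2 * f_x)
    warning(sprintf(
      "delta_f_y = %g Hz <= 2 f_x = %g Hz: amplitude modulation at f_y is attenuated",
      delta_f_y, 2 * f_x))
  if (f_y - delta_f_y / 2 <= f_x + delta_f_x / 2)
    warning("slow and fast bands overlap")
  filt_x <- design_driver_filter(sig$fs, f_x, delta_f_x, "cosine")
  filt_y <- design_driver_filter(sig$fs, f_y, delta_f_y, "cosine")
  xb <- fir_apply(sig$samples, filt_x)
  yb <- fir_apply(sig$samples, filt_y)
  ax <- analytic_signal(xb)
  ay <- analytic_signal(yb)
  edge <- (max(length(filt_x$taps), length(filt_y$taps)) - 1L) %/% 2L
  keep <- (edge + 1L):(length(xb) - edge)
  if (length(keep) < 10L) stop("signal too short for these bands")
  structure(list(phase = Arg(ax[keep]), amplitude = Mod(ay[keep]),
                 amplitude_x = Mod(ax[keep]),
                 f_x = f_x, delta_f_x = delta_f_x, f_y = f_y,
                 delta_f_y = delta_f_y, fs = sig$fs, edge = edge),
            class = "phase_amplitude")
}

#' @export
print.phase_amplitude <- function(x, ...) {
  cat(sprintf(
    "<phase_amplitude> %d samples | slow %g Hz (bw %g), fast %g Hz (bw %g)\n",
    length(x$phase), x$f_x, x$delta_f_x, x$f_y, x$delta_f_y))
  invisible(x)
}

# Metric kernels on plain (phase, amplitude) vectors -----------------------

# Normalized KL divergence of a nonnegative profile to uniformity; shared
# kernel of tort_mi and the DAR modulation metric.
kl_uniform_norm <- function(profile) {
  n <- length(profile)
  tot <- sum(profile)
  if (!(tot > 0) || !is.finite(tot)) return(0)
  pr <- profile / tot
  lg <- pr * log(pr * n)
  lg[pr == 0] <- 0
  min(max(sum(lg) / log(n), 0), 1)
}

tort_mi_kernel <- function(phi, amp, n_bins = 18L) {
  bins <- floor((phi + pi) / (2 * pi) * n_bins) + 1L
  bins[bins > n_bins] <- n_bins
  means <- rep(NA_real_, n_bins)
  agg <- tapply(amp, factor(bins, levels = seq_len(n_bins)), mean)
  means[as.integer(names(agg))] <- agg
  empty <- is.na(means)
  if (any(empty)) {
    # merge empty bins with their nearest filled neighbor's mean
    filled <- which(!empty)
    if (length(filled) == 0L) return(structure(0, empty_bins = n_bins))
    for (b in which(empty)) {
      d <- pmin(abs(filled - b), n_bins - abs(filled - b))
      means[b] <- means[filled[which.min(d)]]
    }
  }
  structure(kl_uniform_norm(means), empty_bins = sum(empty))
}

ozkurt_mi_kernel <- function(phi, amp) {
  s2 <- sum(amp^2)
  if (!(s2 > 0)) return(0)
  Mod(sum(amp * exp(1i * phi))) / sqrt(length(amp) * s2)
}

penny_glm_kernel <- function(phi, amp, amp_x = NULL,
                             include_amplitude = FALSE) {
  X <- cbind(1, cos(phi), sin(phi))
  if (include_amplitude) {
    if (is.null(amp_x)) stop("driver amplitude needed when include_amplitude")
    X <- cbind(X, amp_x, amp_x * cos(phi), amp_x * sin(phi))
  }
  if (nrow(X) <= ncol(X)) stop("too few samples for the GLM regressors")
  fit <- stats::.lm.fit(X, amp)
  if (fit$rank < ncol(X)) stop("rank-deficient GLM design")
  ss_tot <- sum((amp - mean(amp))^2)
  if (!(ss_tot > 0)) return(0)
  1 - sum(fit$residuals^2) / ss_tot
}

#' Tort modulation index
#'
#' Mean fast amplitude per phase bin, normalized to a distribution; the
#' Kullback-Leibler divergence to uniformity divided by `log(n_bins)`, in
#' `[0, 1]`. Empty bins inherit the nearest filled bin's mean and are
#' counted in the `empty_bins` attribute.
#'
#' @param pair A `phase_amplitude` object.
#' @param n_bins Number of phase bins (>= 2).
#' @return Scalar in `[0, 1]`.
#' @export
tort_mi <- function(pair, n_bins = 18L) {
  stopifnot(n_bins >= 2L)
  tort_mi_kernel(pair$phase, pair$amplitude, n_bins)
}

#' Ozkurt normalized mean vector length
#'
#' `|sum(a_y exp(i phi_x))| / sqrt(T sum(a_y^2))`: the modulus of the mean
#' composite vector with the normalization of Ozkurt & Schnitzler, invariant
#' to amplitude scaling.
#'
#' @param pair A `phase_amplitude` object.
#' @return Nonnegative scalar (0 for phase-independent amplitude).
#' @export
ozkurt_mi <- function(pair) {
  ozkurt_mi_kernel(pair$phase, pair$amplitude)
}

#' Penny GLM coupling measure
#'
#' Least-squares regression of the fast amplitude on
#' `[1, cos(phi_x), sin(phi_x)]` (optionally augmented with
#' driver-amplitude-scaled regressors); the statistic is the proportion of
#' amplitude variance explained, invariant to the preferred phase.
#'
#' @param pair A `phase_amplitude` object.
#' @param include_amplitude Also include the slow-oscillation amplitude and
#'   its interactions with the phase regressors.
#' @return R-squared in `[0, 1]`.
#' @export
penny_glm <- function(pair, include_amplitude = FALSE) {
  penny_glm_kernel(pair$phase, pair$amplitude, pair$amplitude_x,
                   include_amplitude)
}

# Engine: precompute per-band phases and amplitudes once, apply the metric
# per (f_x, f_y) cell; `shift` circularly shifts the phase pathway (used by
# surrogate testing).
baseline_comod_engine <- function(signal, method, driver_freqs, delta_f_x,
                                  f_y_grid, delta_f_y, n_bins = 18L,
                                  fs = NULL) {
  sig <- as_raw_signal(signal, fs)
  kern <- switch(method,
                 tort = function(phi, amp) tort_mi_kernel(phi, amp, n_bins),
                 ozkurt = ozkurt_mi_kernel,
                 penny = function(phi, amp) penny_glm_kernel(phi, amp),
                 stop("unknown baseline method: ", method))
  edges <- integer(0)
  phases <- vector("list", length(driver_freqs))
  for (j in seq_along(driver_freqs)) {
    filt <- design_driver_filter(sig$fs, driver_freqs[j], delta_f_x, "cosine")
    phases[[j]] <- Arg(analytic_signal(fir_apply(sig$samples, filt)))
    edges <- c(edges, (length(filt$taps) - 1L) %/% 2L)
  }
  amps <- vector("list", length(f_y_grid))
  for (q in seq_along(f_y_grid)) {
    dfy <- if (length(delta_f_y) > 1L) delta_f_y[q] else delta_f_y
    filt <- design_driver_filter(sig$fs, f_y_grid[q], dfy, "cosine")
    amps[[q]] <- Mod(analytic_signal(fir_apply(sig$samples, filt)))
    edges <- c(edges, (length(filt$taps) - 1L) %/% 2L)
  }
  edge <- max(edges)
  T_ <- length(sig$samples)
  keep <- (edge + 1L):(T_ - edge)
  if (length(keep) < 50L) stop("signal too short for these bands")
  compute <- function(shift = 0L) {
    vals <- matrix(NA_real_, length(driver_freqs), length(f_y_grid))
    for (j in seq_along(driver_freqs)) {
      phi <- if (shift != 0L) circ_shift(phases[[j]], shift) else phases[[j]]
      phi <- phi[keep]
      for (q in seq_along(f_y_grid)) {
        vals[j, q] <- tryCatch(as.numeric(kern(phi, amps[[q]][keep])),
                               error = function(e) NA_real_)
      }
    }
    vals
  }
  list(compute = compute, signal_freqs = f_y_grid, T_ = T_, fs = sig$fs)
}

#' Comodulogram with a classical PAC metric
#'
#' Computes Tort, Ozkurt or Penny coupling values on a grid of
#' (driver frequency, fast frequency). The fast bandwidth follows the
#' selected rule: `"wide"` (default) uses a constant
#' `delta_f_y = 2 * max(driver_freqs)` so amplitude modulation is observable
#' at every driver frequency on the grid; `"proportional"` uses
#' `delta_f_y = alpha * f_y` (a common but biased convention, hides coupling
#' below `f_y = 2 f_x / alpha`); `"fixed"` uses the supplied constant.
#' `method = "dar"` delegates to [comodulogram_dar()].
#'
#' @inheritParams comodulogram_dar
#' @param method `"tort"`, `"ozkurt"`, `"penny"`, or `"dar"`.
#' @param f_y_grid Fast-frequency grid (Hz); default spans
#'   `[2.5 * max(driver_freqs), 0.9 * fs / 2]` in 25 steps.
#' @param delta_f_y_rule `"wide"`, `"proportional"`, or `"fixed"`.
#' @param delta_f_y Constant bandwidth for `"fixed"`.
#' @param alpha Proportionality factor for `"proportional"`.
#' @param n_bins Phase bins for the Tort metric.
#' @param ... Extra arguments forwarded to [comodulogram_dar()] when
#'   `method = "dar"`.
#' @return A `comodulogram` object.
#' @export
comodulogram_baseline <- function(signal, method = c("tort", "ozkurt",
                                                     "penny", "dar"),
                                  driver_freqs = seq(1, 7, by = 0.5),
                                  delta_f_x = 1.0, f_y_grid = NULL,
                                  delta_f_y_rule = c("wide", "proportional",
                                                     "fixed"),
                                  delta_f_y = NULL, alpha = 0.4,
                                  n_bins = 18L, fs = NULL, ...) {
  method <- match.arg(method)
  if (method == "dar")
    return(comodulogram_dar(signal, driver_freqs, delta_f_x = delta_f_x,
                            fs = fs, ...))
  delta_f_y_rule <- match.arg(delta_f_y_rule)
  sig <- as_raw_signal(signal, fs)
  f_y_grid <- f_y_grid %||%
    seq(2.5 * max(driver_freqs), 0.9 * sig$fs / 2, length.out = 25L)
  dfy <- switch(delta_f_y_rule,
                wide = 2 * max(driver_freqs),
                proportional = alpha * f_y_grid,
                fixed = delta_f_y %||% stop("supply delta_f_y for rule 'fixed'"))
  eng <- baseline_comod_engine(sig, method, driver_freqs, delta_f_x,
                               f_y_grid, dfy, n_bins)
  vals <- eng$compute(0L)
  structure(list(driver_freqs = driver_freqs, signal_freqs = f_y_grid,
                 values = vals, method = method,
                 params = list(delta_f_x = delta_f_x,
                               delta_f_y_rule = delta_f_y_rule,
                               delta_f_y = dfy, n_bins = n_bins,
                               fs = sig$fs),
                 sig_mask = NULL,
                 failed = driver_freqs[apply(vals, 1, function(r) all(is.na(r)))]),
            class = "comodulogram")
}
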