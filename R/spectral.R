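# Driver-conditional power spectra and the normalized-KL modulation metric.
#
# From a fitted DAR model, the PSD at a driver value x0 is
#   PSD_y(x0)(f) = sigma(x0)^2 |sum_{i=0}^p a_i(x0) e^{-j 2 pi f i}|^{-2}
# with a_0 = 1. Evaluating it on a circle of driver values of radius rho and
# normalizing each frequency across phases gives a distribution whose
# divergence from uniformity quantifies the amplitude modulation.

# AR coefficients a_i(x0) (p x n_points) and sigma(x0) from coefficient
# vectors; `points` is a complex vector of driver values.
eval_coeffs_at <- function(A, B, p, m_a, m_b, complex_driver, points) {
  Ba <- t(driver_basis(points, m_a, complex_driver))   # na x n
  Bb <- t(driver_basis(points, m_b, complex_driver))   # nb x n
  na <- nrow(Ba)
  a <- t(matrix(A, na, p)) %*% Ba                      # p x n
  sigma <- exp(pmin(pmax(as.numeric(B %*% Bb), -50), 50))
  list(a = a, sigma = sigma)
}

# PSD matrix (n_points x n_freqs, linear power) from coefficients.
psd_from_coeffs <- function(a, sigma, n_fft) {
  p <- nrow(a)
  if (n_fft < 2 * (p + 1)) stop("n_fft too small for the model order")
  nf <- n_fft %/% 2L + 1L
  C <- matrix(0, n_fft, ncol(a))
  C[1, ] <- 1
  C[2:(p + 1), ] <- a
  H <- stats::mvfft(C)[1:nf, , drop = FALSE]
  # result: n_points x n_freqs
  sigma^2 / t(Mod(H)^2 + .Machine$double.xmin)
}

#' Conditional power spectral density at one driver value
#'
#' Evaluates the model PSD at a fixed driver value `x0`: the AR coefficients
#' and innovation standard deviation are computed from the fitted polynomial
#' bases at `x0`, and the spectrum from the inverse squared magnitude of the
#' AR polynomial on an FFT grid.
#'
#' @param fit A `dar_model`.
#' @param x0 A single driver value (complex for complex-driver fits).
#' @param n_fft FFT length (>= `2 * p`).
#' @param fs Sampling rate; defaults to the one recorded in the fit.
#' @return List with `freqs` (Hz, `[0, fs/2]`) and `power` (linear units).
#' @export
conditional_psd <- function(fit, x0, n_fft = 256L, fs = NULL) {
  fs <- fs %||% fit$fs
  if (is.na(fs)) fs <- 1
  mm <- variant_orders(fit$variant, fit$m)
  if (fit$variant == "pdar") x0 <- if (Mod(x0) > 0) x0 / Mod(x0) else x0
  co <- eval_coeffs_at(fit$A, fit$B, fit$p, mm[1], mm[2],
                       fit$complex_driver, x0)
  pw <- psd_from_coeffs(co$a, co$sigma, n_fft)
  nf <- n_fft %/% 2L + 1L
  list(freqs = seq(0, by = fs / n_fft, length.out = nf),
       power = as.numeric(pw))
}

#' Conditional PSD on the driver phase circle
#'
#' Evaluates the conditional PSD at artificial driver values
#' `x0 = rho * exp(i phi_k)` for `n_phases` phases spanning `[-pi, pi)`, with
#' `rho` the median modulus of the empirical driver. Requires a
#' complex-driver fit (the circle needs two driver dimensions).
#'
#' @param fit A `dar_model` fitted with a complex driver.
#' @param n_phases Number of phase points.
#' @param n_fft FFT length.
#' @param rho Driver radius; default median driver modulus from the fit.
#' @param fs Sampling rate; defaults to the one recorded in the fit.
#' @param check_stability Warn if the per-phase AR polynomial has poles on or
#'   outside the unit circle.
#' @return A `conditional_psd` object: `phases`, `freqs` (Hz), `power`
#'   (`n_phases x n_freqs`, linear), `rho`, `scale = "linear"`.
#' @export
psd_on_phase_circle <- function(fit, n_phases = 40L, n_fft = 256L,
                                rho = NULL, fs = NULL,
                                check_stability = FALSE) {
  if (!fit$complex_driver)
    stop("conditional PSD on the phase circle needs a complex-driver fit")
  fs <- fs %||% fit$fs
  if (is.na(fs)) fs <- 1
  rho <- rho %||% fit$rho
  phases <- -pi + 2 * pi * (seq_len(n_phases) - 1L) / n_phases
  pts <- rho * exp(1i * phases)
  mm <- variant_orders(fit$variant, fit$m)
  if (fit$variant == "pdar") pts <- exp(1i * phases)
  co <- eval_coeffs_at(fit$A, fit$B, fit$p, mm[1], mm[2], TRUE, pts)
  if (check_stability) {
    unstable <- any(apply(co$a, 2, function(ai)
      any(Mod(polyroot(rev(c(1, ai)))) >= 1)))
    if (unstable)
      warning("AR polynomial unstable at some driver phases; conditional PSD is extrapolated")
  }
  pw <- psd_from_coeffs(co$a, co$sigma, n_fft)
  nf <- n_fft %/% 2L + 1L
  structure(list(phases = phases,
                 freqs = seq(0, by = fs / n_fft, length.out = nf),
                 power = pw, rho = rho, scale = "linear", fs = fs),
            class = "conditional_psd")
}

#' @export
print.conditional_psd <- function(x, ...) {
  cat(sprintf("<conditional_psd> %d phases x %d frequencies (0-%g Hz), rho = %.3g\n",
              length(x$phases), length(x$freqs), max(x$freqs), x$rho))
  invisible(x)
}

#' Modulation metric M(f): normalized KL divergence to uniformity
#'
#' Each frequency column of the conditional PSD (linear power) is normalized
#' to a distribution over phases; `M(f)` is its Kullback-Leibler divergence
#' from the uniform distribution, divided by `log(n_phases)`, so
#' `0 <= M <= 1`. A frequency with zero total power gets `M = 0` and is
#' flagged in the `undefined` attribute.
#'
#' @param cpsd A `conditional_psd` (linear scale), or a plain matrix
#'   (`n_phases x n_freqs`).
#' @return Numeric vector `M(f)`, one value per frequency, with attribute
#'   `undefined` marking zero-power columns.
#' @export
modulation_spectrum <- function(cpsd) {
  pw <- if (inherits(cpsd, "conditional_psd")) cpsd$power else as.matrix(cpsd)
  n <- nrow(pw)
  tot <- colSums(pw)
  bad <- !(tot > 0) | !is.finite(tot)
  tot[bad] <- 1
  pf <- sweep(pw, 2, tot, "/")
  lg <- pf * log(pf * n)
  lg[pf == 0] <- 0
  M <- colSums(lg) / log(n)
  M[bad] <- 0
  M <- pmin(pmax(M, 0), 1)
  attr(M, "undefined") <- bad
  M
}

# ---- fast comodulogram engine ------------------------------------------

# Precompute everything reusable across driver shifts for one prepared pair.
precompute_fit_ctx <- function(pair, p, m, variant = "dar") {
  T_ <- length(pair$y)
  emb <- stats::embed(pair$y, p + 1L)
  x <- pair$x
  if (variant == "pdar") {
    mod <- Mod(x)
    x <- ifelse(mod > 0, x / mod, 0)
  }
  mm <- variant_orders(variant, m)
  list(yt = emb[, 1L], L = emb[, -1L, drop = FALSE], x = x, T_ = T_,
       p = p, m = m, m_a = mm[1], m_b = mm[2], variant = variant,
       cplx = is.complex(x), rho = stats::median(Mod(x)),
       na = nrow(basis_exponents(mm[1], is.complex(x))),
       support = (p + 1L):T_)
}

circ_shift <- function(v, s) {
  n <- length(v)
  s <- s %% n
  if (s == 0L) return(v)
  c(v[(s + 1L):n], v[1:s])
}

# Fit on the precomputed context with the driver circularly shifted, and
# return the modulation spectrum M(f). Speed-critical path; Newton on B can
# be warm-started from a previous, similar fit via `B_init`.
fast_dar_modulation <- function(ctx, shift = 0L, n_phases = 40L,
                                n_fft = 256L, n_outer = 2L, B_init = NULL) {
  x <- if (shift != 0L) circ_shift(ctx$x, shift) else ctx$x
  xs <- x[ctx$support]
  Xa <- driver_basis(xs, ctx$m_a, ctx$cplx)
  Xb <- if (ctx$m_b == ctx$m_a) Xa else driver_basis(xs, ctx$m_b, ctx$cplx)
  p <- ctx$p
  core <- dar_core(ctx$yt, ctx$L, Xa, Xb, n_outer = n_outer, B_init = B_init)
  phases <- -pi + 2 * pi * (seq_len(n_phases) - 1L) / n_phases
  pts <- if (ctx$variant == "pdar") exp(1i * phases) else ctx$rho * exp(1i * phases)
  co <- eval_coeffs_at(core$A, core$B, p, ctx$m_a, ctx$m_b, ctx$cplx, pts)
  list(M = modulation_spectrum(psd_from_coeffs(co$a, co$sigma, n_fft)),
       B = core$B)
}

# Build prepared pairs + contexts for a driver-frequency grid. The fast
# (signal) frequency axis is restricted to `signal_freq_range`: power below
# the driver band reflects the slow components and the gap fill rather than
# fast-amplitude modulation, and the DC/Nyquist bins of the AR spectrum are
# edge-dominated, so the default range starts at 2.5x the highest driver
# frequency and stops short of Nyquist.
dar_comod_engine <- function(signal, driver_freqs, delta_f_x, p, m,
                             whitening_order, rng_seed, variant = "dar",
                             n_phases = 40L, n_fft = 256L, n_outer = 2L,
                             signal_freq_range = NULL, fs = NULL) {
  sig <- as_raw_signal(signal, fs)
  signal_freq_range <- signal_freq_range %||%
    c(2.5 * max(driver_freqs), 0.95 * sig$fs / 2)
  ctxs <- vector("list", length(driver_freqs))
  for (j in seq_along(driver_freqs)) {
    pair <- prepare_pair(sig, driver_freqs[j], delta_f_x,
                         whitening_order = whitening_order,
                         rng_seed = rng_seed + j)
    ctxs[[j]] <- precompute_fit_ctx(pair, p, m, variant)
  }
  freqs_all <- seq(0, by = sig$fs / n_fft, length.out = n_fft %/% 2L + 1L)
  sel <- which(freqs_all >= signal_freq_range[1] &
               freqs_all <= signal_freq_range[2])
  if (length(sel) < 2L) stop("signal_freq_range too narrow for this n_fft")
  nf <- length(sel)
  warmB <- vector("list", length(ctxs))
  compute <- function(shift = 0L) {
    vals <- matrix(NA_real_, length(driver_freqs), nf)
    for (j in seq_along(ctxs)) {
      res <- tryCatch(
        fast_dar_modulation(ctxs[[j]], shift, n_phases, n_fft, n_outer,
                            B_init = warmB[[j]]),
        error = function(e) NULL)
      if (!is.null(res)) {
        vals[j, ] <- res$M[sel]
        warmB[[j]] <<- res$B
      }
    }
    vals
  }
  list(compute = compute, signal_freqs = freqs_all[sel],
       T_ = length(sig$samples), fs = sig$fs)
}

#' DAR comodulogram
#'
#' For each driver frequency on the grid, prepares the driver pair, fits a
#' DAR model, and computes the modulation spectrum `M(f)`; the result is a
#' matrix of coupling strength over (driver frequency, signal frequency).
#' Columns whose fit fails are masked (`NA`) rather than aborting the grid.
#'
#' @inheritParams prepare_pair
#' @param driver_freqs Grid of driver center frequencies (Hz).
#' @param delta_f_x Driver bandwidth (Hz).
#' @param p,m DAR orders.
#' @param n_phases Phase-circle resolution for `M(f)`.
#' @param n_fft FFT length (signal-frequency resolution `fs / n_fft`).
#' @param n_outer A/B alternations per fit.
#' @param variant Model variant (see [fit_dar()]).
#' @param signal_freq_range Length-2 numeric: the fast-frequency axis of the
#'   comodulogram, Hz. Defaults to `c(2.5 * max(driver_freqs), 0.95 * fs/2)`:
#'   spectral power below or inside the driver band reflects the slow
#'   components themselves, and the DC/Nyquist edge bins of the AR spectrum
#'   are excluded.
#' @return A `comodulogram` object: `driver_freqs`, `signal_freqs`, `values`
#'   (`n_driver x n_freq`, in `[0, 1]`), `params`, optional `sig_mask` slot
#'   (filled by [surrogate_threshold()]).
#' @export
comodulogram_dar <- function(signal, driver_freqs = seq(1, 7, by = 0.5),
                             delta_f_x = 1.0, p = 10L, m = 1L,
                             n_phases = 40L, n_fft = 256L,
                             whitening_order = 10L, rng_seed = 0L,
                             n_outer = 2L, variant = "dar",
                             signal_freq_range = NULL, fs = NULL) {
  if (any(driver_freqs <= 0) || any(driver_freqs >= (as_raw_signal(signal, fs)$fs) / 2))
    stop("driver grid must lie within (0, fs/2)")
  eng <- dar_comod_engine(signal, driver_freqs, delta_f_x, p, m,
                          whitening_order, rng_seed, variant,
                          n_phases, n_fft, n_outer, signal_freq_range, fs)
  vals <- eng$compute(0L)
  structure(list(
    driver_freqs = driver_freqs, signal_freqs = eng$signal_freqs,
    values = vals, method = "dar",
    params = list(delta_f_x = delta_f_x, p = p, m = m, variant = variant,
                  n_phases = n_phases, n_fft = n_fft,
                  whitening_order = whitening_order, rng_seed = rng_seed,
                  n_outer = n_outer, fs = eng$fs),
    sig_mask = NULL,
    failed = driver_freqs[apply(vals, 1, function(r) all(is.na(r)))]),
    class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  am <- comodulogram_argmax(x)
  cat(sprintf(
    "<comodulogram> method %s | %d driver freqs (%g-%g Hz) x %d signal freqs | max %.4g at (%g, %g) Hz\n",
    x$method, length(x$driver_freqs), min(x$driver_freqs),
    max(x$driver_freqs), length(x$signal_freqs),
    max(x$values, na.rm = TRUE), am[1], am[2]))
  invisible(x)
}

#' Location of the comodulogram maximum
#'
#' @param com A `comodulogram`.
#' @return Named vector `c(driver_freq = , signal_freq = )` (Hz); ties are
#'   broken toward the lowest pair in lexicographic order.
#' @export
comodulogram_argmax <- function(com) {
  ij <- argmax_lex(com$values)
  c(driver_freq = com$driver_freqs[ij[1]],
    signal_freq = com$signal_freqs[ij[2]])
}

#' @export
plot.comodulogram <- function(x, ...) {
  graphics::image(x$driver_freqs, x$signal_freqs, x$values,
                  xlab = "driver frequency (Hz)",
                  ylab = "signal frequency (Hz)",
                  main = sprintf("comodulogram (%s)", x$method), ...)
  invisible(x)
}
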