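# Likelihood-driven hyper-parameter selection: grid search over the driver
# filtering parameters, order selection by BIC, and train/test
# cross-validation across model variants.

#' Grid search over driver filtering parameters
#'
#' Selects the driver band `(f_x, delta_f_x)` that maximizes the DAR model
#' likelihood. For a fair comparison all candidates are fitted on the exact
#' same fast signal `y`, built once by [prepare_for_gridsearch()] (high-pass
#' above the maximum candidate frequency, low band refilled with noise,
#' whitened); each candidate driver is extracted from the original signal.
#'
#' @inheritParams prepare_pair
#' @param f_x_grid Candidate center frequencies (Hz).
#' @param delta_f_x_grid Candidate bandwidths (Hz).
#' @param p,m,variant,n_outer Model specification passed to the fits.
#' @return A `grid_search_result`: `f_x_grid`, `delta_f_x_grid`,
#'   `neg_loglik` (per-sample, `n_fx x n_bw`), `best` (named vector
#'   `f_x`, `delta_f_x`), `rng_seed`.
#' @export
grid_search_driver <- function(signal, f_x_grid, delta_f_x_grid,
                               p = 10L, m = 1L, variant = "dar",
                               whitening_order = 10L, rng_seed = 0L,
                               n_outer = 2L, fs = NULL) {
  sig <- as_raw_signal(signal, fs)
  if (max(f_x_grid) + max(delta_f_x_grid) / 2 >= sig$fs / 2)
    stop("driver grid reaches beyond Nyquist")
  y <- prepare_for_gridsearch(sig, max(f_x_grid),
                              whitening_order = whitening_order,
                              rng_seed = rng_seed)
  nll <- matrix(NA_real_, length(f_x_grid), length(delta_f_x_grid),
                dimnames = list(f_x_grid, delta_f_x_grid))
  for (a in seq_along(f_x_grid)) {
    for (b in seq_along(delta_f_x_grid)) {
      x <- extract_driver(sig, f_x_grid[a], delta_f_x_grid[b])
      fit <- tryCatch(
        fit_dar(as.numeric(y), p = p, m = m, variant = variant, x = x,
                n_outer = n_outer),
        error = function(e) NULL)
      if (!is.null(fit)) nll[a, b] <- -fit$loglik_per_sample
    }
  }
  ij <- argmax_lex(-nll)
  structure(list(f_x_grid = f_x_grid, delta_f_x_grid = delta_f_x_grid,
                 neg_loglik = nll,
                 best = c(f_x = f_x_grid[ij[1]],
                          delta_f_x = delta_f_x_grid[ij[2]]),
                 p = p, m = m, variant = variant, rng_seed = rng_seed),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf(
    "<grid_search_result> %d x %d candidates | best: f_x = %g Hz, delta_f_x = %g Hz\n",
    length(x$f_x_grid), length(x$delta_f_x_grid),
    x$best["f_x"], x$best["delta_f_x"]))
  invisible(x)
}

#' Select model orders by BIC
#'
#' Fits every `(p, m)` combination on the same likelihood support
#' (`t > max(p_grid)`, so BIC values are comparable) and returns the pair
#' minimizing the BIC.
#'
#' @param pair A `driver_pair`.
#' @param p_grid,m_grid Candidate orders.
#' @param variant Model variant.
#' @param n_outer A/B alternations per fit.
#' @return List with `p`, `m` (selected), and `table` (data frame of `p`,
#'   `m`, `loglik`, `aic`, `bic`).
#' @export
select_orders_bic <- function(pair, p_grid = 1:20, m_grid = 0:2,
                              variant = "dar", n_outer = 2L) {
  stopifnot(length(p_grid) > 0, length(m_grid) > 0)
  support_start <- max(p_grid) + 1L
  rows <- list()
  for (p in p_grid) {
    for (m in m_grid) {
      fit <- tryCatch(
        fit_dar(pair, p = p, m = m, variant = variant,
                support_start = support_start, n_outer = n_outer),
        error = function(e) NULL)
      if (is.null(fit)) next
      ic <- information_criteria(fit)
      rows[[length(rows) + 1L]] <-
        data.frame(p = p, m = m, loglik = fit$loglik,
                   aic = ic["aic"], bic = ic["bic"])
    }
  }
  if (length(rows) == 0L)
    stop("no (p, m) candidate could be fitted on this pair")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- tab[order(tab$bic, tab$p, tab$m), ][1, ]
  list(p = best$p, m = best$m, table = tab)
}

#' Cross-validate model variants on a train/test split
#'
#' Fits each candidate specification on a contiguous training segment and
#' evaluates the per-sample log-likelihood on a held-out test segment,
#' separated by a guard interval to limit dependence between the two.
#'
#' @param pair A `driver_pair`.
#' @param specs List of model specifications, each a list with elements
#'   `p`, `m`, `variant` (and optionally a `label`).
#' @param split Fraction of the signal used for training (contiguous start).
#' @param guard_s Guard interval between train and test segments (seconds).
#' @param n_outer A/B alternations per fit.
#' @return Data frame with one row per spec: `label`, `variant`, `p`, `m`,
#'   `train_nll`, `test_nll` (per-sample negative log-likelihoods), sorted
#'   by test performance (best first).
#' @export
cross_validate <- function(pair, specs, split = 0.5, guard_s = 1,
                           n_outer = 2L) {
  T_ <- length(pair$y)
  n_train <- floor(T_ * split)
  guard <- round(guard_s * pair$fs)
  t_test0 <- n_train + guard + 1L
  if (t_test0 >= T_ - 20L) stop("degenerate split: no test data left")
  max_d <- max(vapply(specs, function(s)
    (s$p + 1) * (s$m + 1) * (s$m + 2) / 2, numeric(1)))
  if (n_train < 10 * max_d)
    stop("training segment shorter than 10 degrees of freedom per parameter")
  train <- slice_pair(pair, seq_len(n_train))
  test <- slice_pair(pair, t_test0:T_)
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    fit <- fit_dar(train, p = s$p, m = s$m, variant = s$variant,
                   n_outer = n_outer)
    ev <- evaluate_on(fit, test)
    data.frame(label = s$label %||% sprintf("%s(%d,%d)", s$variant, s$p, s$m),
               variant = s$variant, p = s$p, m = s$m,
               train_nll = -fit$loglik_per_sample,
               test_nll = -ev$loglik_per_sample)
  })
  out <- do.call(rbind, rows)
  out[order(out$test_nll), ]
}
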