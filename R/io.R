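# Plain-text input/output: one-column signals, driver pairs, comodulograms
# and grid tables, each with a JSON metadata sidecar.

#' Read a one-column signal file
#'
#' Reads a plain-text one-column CSV/TSV file (header optional, detected
#' automatically) into a [raw_signal].
#'
#' @param path File path.
#' @param fs Sampling rate (Hz).
#' @return A [raw_signal].
#' @export
read_signal <- function(path, fs) {
  first <- readLines(path, n = 1L)
  header <- is.na(suppressWarnings(as.numeric(strsplit(
    trimws(first), "[,;\t ]+")[[1]][1])))
  v <- utils::read.table(path, header = header, sep = "",
                         comment.char = "#")[[1]]
  raw_signal(as.numeric(v), fs, meta = list(path = path))
}

#' Write a one-column signal file
#'
#' @param signal A [raw_signal].
#' @param path Output path; a `.json` sidecar with `fs` and `meta` is
#'   written next to it.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "raw_signal"))
  utils::write.table(signal$samples, path, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(list(fs = signal$fs, meta = signal$meta),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Write a driver pair
#'
#' Three-column TSV (`x1`, `x2`, `y`) plus a JSON sidecar with the
#' preprocessing parameters.
#'
#' @param pair A `driver_pair`.
#' @param path Output path.
#' @export
write_driver_pair <- function(pair, path) {
  stopifnot(inherits(pair, "driver_pair"))
  utils::write.table(
    data.frame(x1 = Re(pair$x), x2 = Im(pair$x), y = pair$y),
    path, row.names = FALSE, sep = "\t", quote = FALSE)
  side <- list(fs = pair$fs, f_x = pair$f_x, delta_f_x = pair$delta_f_x,
               whitening_order = pair$whitening_order,
               whitening_ar = pair$whitening_ar, rng_seed = pair$rng_seed,
               meta = pair$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Read a driver pair written by [write_driver_pair()]
#'
#' @param path Path of the TSV file (expects the `.json` sidecar).
#' @return A `driver_pair`.
#' @export
read_driver_pair <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(x = complex(real = tab$x1, imaginary = tab$x2), y = tab$y,
                 fs = side$fs, f_x = side$f_x, delta_f_x = side$delta_f_x,
                 whitening_order = side$whitening_order,
                 whitening_ar = side$whitening_ar,
                 rng_seed = side$rng_seed, meta = side$meta),
            class = "driver_pair")
}

#' Write a comodulogram
#'
#' TSV matrix (driver frequencies in rows, signal frequencies in columns)
#' plus a JSON sidecar with the grids and parameters.
#'
#' @param com A `comodulogram`.
#' @param path Output path.
#' @export
write_comodulogram <- function(com, path) {
  stopifnot(inherits(com, "comodulogram"))
  m <- com$values
  dimnames(m) <- list(com$driver_freqs, com$signal_freqs)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  side <- list(method = com$method, driver_freqs = com$driver_freqs,
               signal_freqs = com$signal_freqs, params = com$params)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Serialize a fitted DAR model to JSON
#'
#' Orders, variant, coefficient vectors in the documented lag-major
#' ordering, log-likelihood and degrees of freedom.
#'
#' @param fit A `dar_model`.
#' @param path Output path.
#' @export
write_dar_model <- function(fit, path) {
  stopifnot(inherits(fit, "dar_model"))
  out <- list(p = fit$p, m = fit$m, variant = fit$variant,
              complex_driver = fit$complex_driver,
              A = fit$A, B = fit$B,
              ordering = as.list(fit$ordering),
              loglik = fit$loglik, dof = fit$dof,
              n_effective = fit$n_effective, rho = fit$rho, fs = fit$fs)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
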