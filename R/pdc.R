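#' Default PDC frequency grid
#'
#' Evenly spaced frequency bins at the given resolution up to `f_max`,
#' starting at one resolution step (so 0.1 Hz resolution up to 80 Hz yields
#' 800 bins, and 1 Hz resolution yields 80).
#'
#' @param resolution bin spacing in Hz.
#' @param f_max top of the grid in Hz (inclusive).
#' @return Strictly increasing numeric vector.
#' @export
default_frequency_grid <- function(resolution = 0.1, f_max = 80) {
  stopifnot(resolution > 0, f_max >= resolution)
  seq(resolution, f_max, by = resolution)
}

#' Partial directed coherence of an MVAR model
#'
#' Original (column-normalized) partial directed coherence.  With
#' `Abar(f) = I - sum_r A_r exp(-i 2 pi f r / fs)`, the PDC from channel `j`
#' to channel `i` at frequency `f` is
#' `|Abar[i, j](f)| / sqrt(sum_k |Abar[k, j](f)|^2)`.
#' Every value lies in `[0, 1]` and each source column has unit sum of
#' squares at every frequency.
#'
#' @param model an `mvar_model`.
#' @param frequencies frequencies in Hz; must stay below the Nyquist rate.
#' @param sampling_rate sampling rate in Hz (defaults to the model's).
#' @return An object of class `pdc_spectrum`: `frequencies` and `values`, a
#'   `d` x `d` x `n_freq` array with `values[i, j, f]` the PDC `j -> i` at
#'   `frequencies[f]`.
#' @export
pdc <- function(model, frequencies = default_frequency_grid(),
                sampling_rate = model$sampling_rate) {
  stopifnot(inherits(model, "mvar_model"),
            all(diff(frequencies) > 0),
            max(frequencies) < sampling_rate / 2)
  d <- model$dimension
  p <- model$order
  nf <- length(frequencies)
  values <- array(NA_real_, dim = c(d, d, nf))
  eye <- diag(d)
  for (f in seq_len(nf)) {
    phase <- exp(-1i * 2 * pi * frequencies[f] * seq_len(p) / sampling_rate)
    abar <- matrix(0i, d, d) + eye
    for (r in seq_len(p)) {
      abar <- abar - model$A[, , r] * phase[r]
    }
    mag <- Mod(abar)
    denom <- sqrt(colSums(mag^2))
    if (any(denom == 0)) stop("zero column norm in Abar(f): numerical failure")
    values[, , f] <- sweep(mag, 2, denom, "/")
  }
  structure(list(frequencies = frequencies, values = values),
            class = "pdc_spectrum")
}

#' Binarize a PDC spectrum by proportional threshold
#'
#' Per frequency bin, the `floor(fraction * d * (d - 1))` largest
#' off-diagonal PDC values are kept as directed edges (the pipeline default
#' keeps the top 15%, i.e. an 85% threshold).  Ties at the cut are broken by
#' descending value, then ascending (row, column) index, so the result is
#' fully deterministic and invariant to strictly monotone transforms of the
#' values.
#'
#' @param pdc_spectrum a `pdc_spectrum`.
#' @param fraction fraction of possible directed edges kept, in (0, 1).
#' @return An object of class `adjacency_series`: `frequencies`,
#'   `adjacency` (`d` x `d` x `n_freq` binary, zero diagonal),
#'   `edge_count`, `threshold_fraction`.
#' @export
binarize_top_fraction <- function(pdc_spectrum, fraction = 0.15) {
  stopifnot(inherits(pdc_spectrum, "pdc_spectrum"),
            fraction > 0, fraction < 1)
  v <- pdc_spectrum$values
  d <- dim(v)[1]
  nf <- dim(v)[3]
  k <- floor(fraction * d * (d - 1))
  off <- which(diag(d) == 0)                 # off-diagonal linear indices
  rows <- ((off - 1L) %% d) + 1L
  cols <- ((off - 1L) %/% d) + 1L
  adjacency <- array(0L, dim = c(d, d, nf))
  if (k > 0) {
    for (f in seq_len(nf)) {
      vals <- v[, , f][off]
      keep <- off[order(-vals, rows, cols)[seq_len(k)]]
      slice <- matrix(0L, d, d)
      slice[keep] <- 1L
      adjacency[, , f] <- slice
    }
  }
  structure(list(frequencies = pdc_spectrum$frequencies,
                 adjacency = adjacency,
                 edge_count = k,
                 threshold_fraction = fraction),
            class = "adjacency_series")
}
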