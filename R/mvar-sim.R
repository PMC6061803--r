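#' Build a stable MVAR model realizing a directed network
#'
#' Constructs lag matrices whose off-diagonal entries are nonzero exactly
#' where the network has an edge (entry `(i, j)` of a lag matrix couples node
#' `j` into node `i`).  Diagonal (self-lag) terms are always present so that
#' each source has a realistic autospectrum: with `order >= 2` every node is
#' given a damped resonance at a random frequency inside `osc_band`.  After
#' the couplings are placed, all lag matrices are rescaled until the
#' companion-matrix spectral radius is at most `max_radius`, which preserves
#' the network topology.
#'
#' @param network a `directed_network`.
#' @param order model order `p >= 1`.
#' @param coupling_strength magnitude scale of the cross couplings; must be
#'   positive and finite.
#' @param seed integer seed.
#' @param sampling_rate sampling rate in Hz (sets the resonance placement).
#' @param osc_band frequency band (Hz) from which node resonances are drawn.
#' @param damping range of the per-node resonance damping (pole radius of
#'   the self-lag AR(2) pair); smaller values give broader spectral peaks
#'   and weaker self terms relative to the couplings.
#' @param coupling_lag lag (or vector of candidate lags, sampled per edge)
#'   at which cross couplings act; the default places them at the first
#'   lag, i.e. the fastest interaction the sampling rate can express.
#' @param max_radius stability target for the companion spectral radius.
#' @return An `mvar_model` with identity innovation covariance and negative
#'   stability index.
#' @export
build_mvar_from_network <- function(network, order, coupling_strength = 0.4,
                                    seed, sampling_rate = 1000,
                                    osc_band = c(2, 45),
                                    damping = c(0.75, 0.9),
                                    coupling_lag = 1L,
                                    max_radius = 0.95) {
  stopifnot(inherits(network, "directed_network"), order >= 1)
  if (!is.finite(coupling_strength) || coupling_strength <= 0) {
    stop("coupling_strength must be positive and finite")
  }
  d <- network$n_nodes
  withr::with_seed(seed, {
    A <- array(0, dim = c(d, d, order))
    if (order >= 2) {
      f0 <- runif(d, osc_band[1], min(osc_band[2], 0.45 * sampling_rate))
      damp <- runif(d, damping[1], damping[2])
      theta <- 2 * pi * f0 / sampling_rate
      for (i in seq_len(d)) {
        A[i, i, 1] <- 2 * damp[i] * cos(theta[i])
        A[i, i, 2] <- -damp[i]^2
      }
    } else {
      diag(A[, , 1]) <- runif(d, 0.4, 0.7)
    }
    stopifnot(all(coupling_lag >= 1), all(coupling_lag <= order))
    if (nrow(network$edges) > 0) {
      for (e in seq_len(nrow(network$edges))) {
        s <- network$edges[e, "source"]
        t <- network$edges[e, "target"]
        lag <- if (length(coupling_lag) > 1) sample(coupling_lag, 1L) else coupling_lag
        A[t, s, lag] <- coupling_strength * runif(1, 0.75, 1.25) *
          sample(c(-1, 1), 1L)
      }
    }
    # rescale lag r by gamma^r: companion eigenvalues scale linearly in
    # gamma, so every model is normalized to the same spectral radius
    # (equal distance from instability), which keeps the effective
    # dynamics comparable across topologies
    for (iter in 1:50) {
      sr <- exp(stability_index(mvar_model(A, diag(d), sampling_rate)))
      if (!is.finite(sr) || sr == 0) stop("coupling_strength cannot be stabilized")
      if (abs(sr - max_radius) < 1e-10) break
      gamma <- max_radius / sr
      for (r in seq_len(order)) A[, , r] <- A[, , r] * gamma^r
    }
    mvar_model(A, diag(d), sampling_rate)
  })
}

#' Simulate an MVAR process
#'
#' Draws Gaussian innovations from the model's innovation covariance and
#' iterates the autoregression, discarding `burn_in` initial samples to
#' remove the transient from the zero initial condition.
#'
#' @param model an `mvar_model`.
#' @param n_samples number of samples returned; must exceed the model order.
#' @param burn_in samples discarded at the start (default 1000).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return `d` x `n_samples` matrix.
#' @export
simulate_mvar <- function(model, n_samples, burn_in = 1000L, seed) {
  stopifnot(inherits(model, "mvar_model"), n_samples > model$order,
            burn_in >= 0)
  d <- model$dimension
  p <- model$order
  n_tot <- n_samples + burn_in + p
  big_a <- matrix(model$A, nrow = d)  # d x (d*p), lag-1 block first
  ch <- chol(model$sigma + diag(1e-12, d))
  withr::with_seed(seed, {
    eps <- t(ch) %*% matrix(rnorm(d * n_tot), d, n_tot)
    x <- matrix(0, d, n_tot)
    for (tt in (p + 1):n_tot) {
      past <- as.vector(x[, tt - seq_len(p), drop = FALSE])
      x[, tt] <- big_a %*% past + eps[, tt]
    }
    if (!all(is.finite(x))) stop("simulated series diverged: model unstable")
    x[, (n_tot - n_samples + 1):n_tot, drop = FALSE]
  })
}
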