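#' Sensor recording container
#'
#' Multichannel sensor data with geometry: `data` is `n_channels` x
#' `n_samples`, `positions` gives 3D channel positions in metres, and
#' `pair_map` assigns every channel to exactly one planar-gradiometer pair
#' with a unique location index.
#'
#' @param data numeric matrix, channels x samples.
#' @param sampling_rate sampling rate in Hz.
#' @param positions `n_channels` x 3 matrix.
#' @param pair_map data frame with columns `channel_a`, `channel_b`,
#'   `location_index`.
#' @return An object of class `sensor_recording`.
#' @export
sensor_recording <- function(data, sampling_rate, positions, pair_map) {
  data <- as.matrix(data)
  stopifnot(ncol(data) > 0, sampling_rate > 0,
            nrow(positions) == nrow(data), ncol(positions) == 3)
  req <- c("channel_a", "channel_b", "location_index")
  if (!all(req %in% names(pair_map))) {
    stop("pair_map must have columns ", paste(req, collapse = ", "))
  }
  chans <- c(pair_map$channel_a, pair_map$channel_b)
  if (anyDuplicated(chans) || !setequal(chans, seq_len(nrow(data)))) {
    stop("every channel must appear in exactly one pair")
  }
  if (anyDuplicated(pair_map$location_index)) {
    stop("location_index must be unique per pair")
  }
  structure(list(data = data, sampling_rate = sampling_rate,
                 positions = positions, pair_map = pair_map),
            class = "sensor_recording")
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat(sprintf("<sensor_recording> %d channels (%d locations) x %d samples @ %g Hz\n",
              nrow(x$data), nrow(x$pair_map), ncol(x$data), x$sampling_rate))
  invisible(x)
}

#' Smooth distance-decay gain matrix
#'
#' Builds a simplified forward operator: each source, placed at a random
#' position under the helmet surface, projects onto the sensors with a
#' spatially smooth Gaussian distance-decay profile.  Columns are normalized
#' to unit norm, so every source is visible and the matrix has full column
#' rank for generic source positions.  With `spread = 0` the limiting
#' behaviour is used: each source maps only to its nearest sensor.
#'
#' @param n_sensors number of sensor channels; must be `>= n_sources`.
#' @param n_sources number of sources.
#' @param sensor_positions `n_sensors` x 3 channel positions (metres), e.g.
#'   from [helmet_layout()].
#' @param spread decay length scale in metres (default 0.04).
#' @param seed integer seed for source placement (ignored when
#'   `source_positions` is supplied).
#' @param source_positions optional `n_sources` x 3 matrix of source
#'   positions; when `NULL`, sources are placed at `depth` times the mean
#'   sensor radius, in random directions under the cap.
#' @param depth relative source depth in (0, 1).
#' @return An object of class `gain_matrix` with elements `weights`
#'   (`n_sensors` x `n_sources`), `sensor_positions`, `source_positions`.
#' @export
make_gain_matrix <- function(n_sensors, n_sources, sensor_positions,
                             spread = 0.04, seed = 1L,
                             source_positions = NULL, depth = 0.7) {
  stopifnot(n_sensors >= n_sources, nrow(sensor_positions) == n_sensors,
            spread >= 0, depth > 0, depth < 1)
  radius <- mean(sqrt(rowSums(sensor_positions^2)))
  if (is.null(source_positions)) {
    source_positions <- withr::with_seed(seed, {
      # random directions restricted to the upper cap so sources sit under
      # the helmet rather than at its rim
      z <- runif(n_sources, 0.2, 0.95)
      phi <- runif(n_sources, 0, 2 * pi)
      r_xy <- sqrt(1 - z^2)
      depth * radius * cbind(r_xy * cos(phi), r_xy * sin(phi), z)
    })
  }
  stopifnot(nrow(source_positions) == n_sources)
  d2 <- outer(rowSums(sensor_positions^2), rep(1, n_sources)) +
    outer(rep(1, n_sensors), rowSums(source_positions^2)) -
    2 * sensor_positions %*% t(source_positions)
  d2 <- pmax(d2, 0)
  if (spread == 0) {
    weights <- matrix(0, n_sensors, n_sources)
    weights[cbind(apply(d2, 2, which.min), seq_len(n_sources))] <- 1
  } else {
    weights <- exp(-d2 / (2 * spread^2))
    weights <- sweep(weights, 2, sqrt(colSums(weights^2)), "/")
  }
  if (any(colSums(abs(weights)) == 0) || !all(is.finite(weights))) {
    stop("degenerate gain matrix: a source is invisible to all sensors")
  }
  structure(list(weights = weights, sensor_positions = sensor_positions,
                 source_positions = source_positions),
            class = "gain_matrix")
}

#' Project sources to sensors and add noise at a given SNR
#'
#' The sensor signal is `weights %*% sources` plus independent Gaussian
#' noise whose per-channel standard deviation equals the per-channel signal
#' standard deviation divided by `snr` (so `snr` is the SD ratio of signal
#' to noise).  `snr = Inf` adds no noise.
#'
#' @param source_timeseries `n_sources` x `n_samples` matrix.
#' @param gain a `gain_matrix`.
#' @param snr positive signal-to-noise ratio, or `Inf`.
#' @param seed integer seed for the noise draw.
#' @param layout helmet layout providing `pair_map` (and positions matching
#'   the gain matrix), e.g. from [helmet_layout()].
#' @param sampling_rate sampling rate in Hz recorded on the output.
#' @return A `sensor_recording`.
#' @export
project_and_add_noise <- function(source_timeseries, gain, snr, seed,
                                  layout, sampling_rate = 1000) {
  stopifnot(inherits(gain, "gain_matrix"), snr > 0)
  signal <- gain$weights %*% source_timeseries
  if (is.finite(snr)) {
    sds <- apply(signal, 1, sd)
    if (any(sds == 0)) {
      stop("zero-variance projected channel: degenerate gain matrix")
    }
    noise <- withr::with_seed(seed, {
      matrix(rnorm(length(signal)), nrow(signal)) * (sds / snr)
    })
    signal <- signal + noise
  }
  sensor_recording(signal, sampling_rate, gain$sensor_positions,
                   layout$pair_map)
}
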