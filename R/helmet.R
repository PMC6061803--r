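#' Canonical helmet sensor layout
#'
#' Places `n_locations` measurement locations on a spherical cap (a
#' helmet-like surface over the upper head) using a Fibonacci spiral, and
#' assigns two planar-gradiometer channels to each location, mirroring the
#' 204-channel / 102-location geometry of whole-head gradiometer systems.
#'
#' @param n_locations number of sensor locations (two channels each).
#' @param radius helmet radius in metres.
#' @param cap_angle maximum polar angle of the cap in radians, measured from
#'   the vertex; the default extends the coverage down to roughly ear level.
#' @return A list with `positions` (`2 * n_locations` x 3 channel positions in
#'   metres; the two channels of a pair are co-located), `pair_map` (data
#'   frame with columns `channel_a`, `channel_b`, `location_index`) and
#'   `location_positions` (`n_locations` x 3).
#' @export
helmet_layout <- function(n_locations = 102L, radius = 0.09,
                          cap_angle = 1.9) {
  stopifnot(n_locations >= 1, radius > 0, cap_angle > 0, cap_angle < pi)
  i <- seq_len(n_locations)
  # uniform-area spiral on the cap: z runs from cos(cap_angle) up to ~1
  z <- 1 - (1 - cos(cap_angle)) * (i - 0.5) / n_locations
  golden <- pi * (3 - sqrt(5))
  phi <- (i - 1) * golden
  r_xy <- sqrt(pmax(0, 1 - z^2))
  loc <- radius * cbind(x = r_xy * cos(phi), y = r_xy * sin(phi), z = z)
  positions <- loc[rep(i, each = 2L), , drop = FALSE]
  rownames(positions) <- NULL
  pair_map <- data.frame(
    channel_a = 2L * i - 1L,
    channel_b = 2L * i,
    location_index = i
  )
  list(positions = positions, pair_map = pair_map, location_positions = loc)
}
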