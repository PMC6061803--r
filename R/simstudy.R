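#' Source-to-sensor validation study
#'
#' Replicates the simulation design used to validate sensor-space recovery
#' of source-network segregation: directed source networks with low vs high
#' mean local efficiency drive MVAR dynamics, are projected to 204 planar
#' gradiometers through a smooth gain matrix, sensor noise is added at a
#' sweep of SNRs, and each sensor recording is run through the full analysis
#' chain (RMS pairing, PCA, MVAR fit at the generating order,
#' back-projection, PDC, proportional-threshold binarization, local
#' efficiency).  The question is whether the sensor-level mean local
#' efficiency still separates the two source classes at each SNR and
#' binarization threshold.
#'
#' @param n_per_class networks per efficiency class (default 20 + 20).
#' @param n_nodes,n_edges source network size (default 6 nodes, 6 of the 30
#'   possible directed connections).
#' @param order source MVAR order (also used for the sensor fit).
#' @param coupling_strength coupling scale of the source models.
#' @param n_samples samples per recording (default 30 s at 1 kHz).
#' @param sampling_rate sampling rate in Hz.
#' @param snr_levels SNR sweep; `Inf` means no sensor noise.
#' @param thresholds binarization thresholds expressed as the retained top
#'   fraction (0.15 = an 85% threshold).
#' @param fit_order MVAR order used for the sensor fit; defaults to the
#'   generating order (the patient pipeline instead selects it by BIC).
#' @param freq_resolution,f_max PDC grid (Hz).
#' @param n_components retained principal components for the sensor fit,
#'   capped at the numerical rank of the RMS data (noiseless projections of
#'   few sources are rank deficient).
#' @param spread,depth forward-model focality (metres) and relative source
#'   depth; the default spread approximates the focal sensitivity of planar
#'   gradiometers.
#' @param layout helmet layout.
#' @param seed master seed.
#' @return Data frame with one row per network x SNR x threshold:
#'   `network`, `class`, `source_mean_leff`, `snr`, `threshold`,
#'   `sensor_mean_leff`.
#' @seealso [summarize_simulation_study()]
#' @export
simulation_study <- function(n_per_class = 20L, n_nodes = 6L, n_edges = 6L,
                             order = 3L, coupling_strength = 0.5,
                             n_samples = 30000L, sampling_rate = 1000,
                             snr_levels = c(0.1, 1, 3, 10, Inf),
                             thresholds = c(0.15, 0.05, 0.01),
                             fit_order = order,
                             freq_resolution = 1, f_max = 80,
                             n_components = 60L,
                             spread = 0.015, depth = 0.8,
                             layout = helmet_layout(), seed = 1L) {
  freqs <- default_frequency_grid(freq_resolution, f_max)
  gain <- make_gain_matrix(nrow(layout$positions), n_nodes,
                           layout$positions, spread = spread,
                           seed = seed + 1L, depth = depth)
  rows <- list()
  for (cls in c("low", "high")) {
    for (i in seq_len(n_per_class)) {
      net_seed <- seed + 1000L * i + 500L * (cls == "high")
      net <- generate_source_network(n_nodes, n_edges, cls, seed = net_seed)
      model <- build_mvar_from_network(net, order, coupling_strength,
                                       seed = net_seed + 1L,
                                       sampling_rate = sampling_rate)
      src <- simulate_mvar(model, n_samples, seed = net_seed + 2L)
      src_eff <- mean(local_efficiency(network_adjacency(net)))
      for (si in seq_along(snr_levels)) {
        rec <- project_and_add_noise(src, gain, snr_levels[si],
                                     seed = net_seed + 10L + si,
                                     layout = layout,
                                     sampling_rate = sampling_rate)
        rms <- combine_gradiometer_pairs(rec)
        xc <- rms - rowMeans(rms)
        ev <- eigen(tcrossprod(xc), symmetric = TRUE, only.values = TRUE)$values
        k <- min(n_components, nrow(rms), sum(ev > ev[1] * 1e-12))
        red <- reduce_dimensionality(rms, "fixed_k", k)
        fit <- fit_mvar(red$scores, fit_order, sampling_rate = sampling_rate)
        spec <- pdc(backproject_mvar(fit, red), freqs,
                    sampling_rate = sampling_rate)
        for (th in thresholds) {
          eff <- local_efficiency_series(binarize_top_fraction(spec, th))
          rows[[length(rows) + 1L]] <- data.frame(
            network = paste0(cls, i), class = cls,
            source_mean_leff = src_eff, snr = snr_levels[si],
            threshold = 1 - th,
            sensor_mean_leff = mean(eff$values))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Class separation per SNR and threshold
#'
#' Two-sided Wilcoxon rank-sum test of sensor-level mean local efficiency
#' between the low- and high-efficiency source classes, for every SNR x
#' threshold cell of a [simulation_study()] result.
#'
#' @param study data frame from [simulation_study()].
#' @return Data frame with `snr`, `threshold`, group medians, and the
#'   rank-sum `p_value`.
#' @export
summarize_simulation_study <- function(study) {
  cells <- unique(study[c("snr", "threshold")])
  out <- lapply(seq_len(nrow(cells)), function(r) {
    sub <- study[study$snr == cells$snr[r] &
                   study$threshold == cells$threshold[r], ]
    lo <- sub$sensor_mean_leff[sub$class == "low"]
    hi <- sub$sensor_mean_leff[sub$class == "high"]
    data.frame(snr = cells$snr[r], threshold = cells$threshold[r],
               median_low = stats::median(lo), median_high = stats::median(hi),
               p_value = stats::wilcox.test(lo, hi, exact = FALSE)$p.value)
  })
  out <- do.call(rbind, out)
  out[order(out$threshold, out$snr), ]
}
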