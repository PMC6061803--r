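#' Specify a group for cohort simulation
#'
#' A group is defined relative to a shared reference source dynamic by where
#' and at which frequencies its coupling is attenuated.  `band` restricts
#' the attenuation to couplings transmitted by sources whose resonance
#' frequency falls in the band; `region` restricts it to sources lying
#' within an angular distance of a scalp direction.  A control group uses
#' `attenuation = 0`.
#'
#' @param name group label.
#' @param attenuation fraction in `[0, 1]` by which qualifying couplings are
#'   reduced.
#' @param band `c(lo, hi)` in Hz, or `NULL` for all frequencies.
#' @param region unit direction vector (length 3) of the affected scalp
#'   region, or `NULL` for all sources.
#' @param region_angle angular radius of the region in radians.
#' @return A `group_spec` list.
#' @export
group_spec <- function(name, attenuation = 0, band = NULL, region = NULL,
                       region_angle = 0.7) {
  stopifnot(is.character(name), length(name) == 1,
            attenuation >= 0, attenuation <= 1)
  if (!is.null(band)) stopifnot(length(band) == 2, band[1] < band[2])
  if (!is.null(region)) {
    stopifnot(length(region) == 3)
    region <- region / sqrt(sum(region^2))
  }
  structure(list(name = name, attenuation = attenuation, band = band,
                 region = region, region_angle = region_angle),
            class = "group_spec")
}

#' Simulate a multi-group sensor cohort
#'
#' All groups share one reference source configuration (source positions
#' under the helmet, per-source resonance frequencies spanning the analysis
#' band, and a random coupling network); each group's spec attenuates the
#' couplings transmitted by sources matching its band/region, which lowers
#' directed connectivity - and therefore downstream local efficiency - at
#' the matching sensors and frequencies.  Subjects are independent draws:
#' coupling magnitudes are jittered per subject before stabilization, and
#' source noise, projection noise and the MVAR innovations all derive from
#' per-subject seeds under the single cohort seed.
#'
#' @param group_specs list of [group_spec()] objects with distinct names.
#' @param n_subjects_per_group subjects per group (0 gives an empty cohort).
#' @param seed cohort seed fixing all randomness.
#' @param layout helmet layout (defaults to the canonical 102-location one).
#' @param n_sources number of cortical sources.
#' @param n_edges number of directed couplings among sources.
#' @param n_samples samples per subject.
#' @param sampling_rate sampling rate in Hz.
#' @param snr sensor signal-to-noise ratio (SD ratio), `Inf` for noiseless.
#' @param order source MVAR order.
#' @param coupling_strength coupling scale of the reference network.
#' @param freq_range range (Hz) over which source resonances are spread.
#' @return A list with `recordings` (list of `sensor_recording`), `labels`
#'   (data frame `subject_id`, `group`) and `truth` (ground-truth metadata:
#'   specs, source positions, resonance frequencies, edge list).
#' @export
generate_group_cohort <- function(group_specs, n_subjects_per_group, seed,
                                  layout = helmet_layout(),
                                  n_sources = 10L, n_edges = 30L,
                                  n_samples = 20000L, sampling_rate = 1000,
                                  snr = 5, order = 4L,
                                  coupling_strength = 0.35,
                                  freq_range = c(3, 60)) {
  if (inherits(group_specs, "group_spec")) group_specs <- list(group_specs)
  nm <- vapply(group_specs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("group specs must have distinct names")
  stopifnot(n_subjects_per_group >= 0)

  base <- withr::with_seed(seed, {
    net <- random_digraph(n_sources, n_edges)
    gain <- make_gain_matrix(nrow(layout$positions), n_sources,
                             layout$positions, seed = seed + 7L)
    # resonances spread evenly over the analysis band, with jitter
    f0 <- seq(freq_range[1], freq_range[2], length.out = n_sources) +
      runif(n_sources, -1, 1)
    list(net = net, gain = gain, f0 = f0)
  })

  recordings <- list()
  labels <- data.frame(subject_id = character(), group = character())
  subj <- 0L
  if (n_subjects_per_group > 0) {
    for (g in seq_along(group_specs)) {
      gs <- group_specs[[g]]
      affected <- affected_sources(base, gs)
      for (s in seq_len(n_subjects_per_group)) {
        subj <- subj + 1L
        sseed <- (seed + 1000L * g + s) %% .Machine$integer.max
        model <- subject_source_model(base, affected, gs$attenuation,
                                      order, coupling_strength,
                                      sampling_rate, sseed)
        src <- simulate_mvar(model, n_samples, seed = sseed + 1L)
        rec <- project_and_add_noise(src, base$gain, snr, seed = sseed + 2L,
                                     layout = layout,
                                     sampling_rate = sampling_rate)
        id <- sprintf("S%03d", subj)
        recordings[[id]] <- rec
        labels <- rbind(labels,
                        data.frame(subject_id = id, group = gs$name))
      }
    }
  }
  list(recordings = recordings, labels = labels,
       truth = list(specs = group_specs,
                    source_positions = base$gain$source_positions,
                    resonance_hz = base$f0,
                    edges = base$net$edges))
}

affected_sources <- function(base, spec) {
  n <- length(base$f0)
  in_band <- if (is.null(spec$band)) rep(TRUE, n) else {
    base$f0 >= spec$band[1] & base$f0 <= spec$band[2]
  }
  in_region <- if (is.null(spec$region)) rep(TRUE, n) else {
    dirs <- base$gain$source_positions /
      sqrt(rowSums(base$gain$source_positions^2))
    acos(pmin(1, pmax(-1, dirs %*% spec$region))) <= spec$region_angle
  }
  which(in_band & as.vector(in_region))
}

# Build one subject's source model: the reference resonances and network
# with per-subject coupling jitter, then group-level attenuation of edges
# transmitted by affected sources.
subject_source_model <- function(base, affected, attenuation, order,
                                 coupling_strength, sampling_rate, sseed) {
  d <- base$net$n_nodes
  withr::with_seed(sseed + 3L, {
    A <- array(0, dim = c(d, d, order))
    damp <- runif(d, 0.8, 0.9)
    theta <- 2 * pi * base$f0 / sampling_rate
    for (i in seq_len(d)) {
      A[i, i, 1] <- 2 * damp[i] * cos(theta[i])
      A[i, i, 2] <- -damp[i]^2
    }
    for (e in seq_len(nrow(base$net$edges))) {
      s <- base$net$edges[e, "source"]
      t <- base$net$edges[e, "target"]
      w <- coupling_strength * runif(1, 0.7, 1.3) * sample(c(-1, 1), 1L)
      if (s %in% affected) w <- w * (1 - attenuation)
      A[t, s, sample.int(order, 1L)] <- w
    }
    for (iter in 1:50) {
      sr <- exp(stability_index(A))
      if (sr <= 0.95 || sr == 0) break
      gamma <- 0.95 / sr
      for (r in seq_len(order)) A[, , r] <- A[, , r] * gamma^r
    }
    mvar_model(A, diag(d), sampling_rate)
  })
}

#' Simulate subject scalp-by-frequency images directly
#'
#' Image-level generator for calibration studies of the group statistics
#' and classifier: each subject's volume is a constant baseline plus
#' spatially and spectrally smoothed Gaussian noise, optionally plus a
#' localized effect bump (a Gaussian blob in space crossed with a frequency
#' band).  Much cheaper than simulating sensor recordings, with matched
#' smoothness structure.
#'
#' @param n_subjects number of subjects.
#' @param dims volume dimensions `c(gs, gs, n_freq)`.
#' @param mask optional 2D logical mask; defaults to the inscribed disc.
#' @param baseline constant level.
#' @param noise_sd SD of the (pre-smoothing) voxel noise.
#' @param smooth_sigma smoothing sigma in voxels per axis.
#' @param effect optional list with `center` (pixel coords), `radius`
#'   (pixels), `band` (frequency-bin range `c(lo, hi)`) and `amplitude`;
#'   added to every subject.
#' @param seed integer seed.
#' @return A list with `images` (list of 3D arrays) and `mask`.
#' @export
simulate_scalp_images <- function(n_subjects, dims = c(16L, 16L, 40L),
                                  mask = NULL, baseline = 0.3,
                                  noise_sd = 0.05,
                                  smooth_sigma = c(1.2, 1.2, 1.5),
                                  effect = NULL, seed = 1L) {
  gs <- dims[1]
  if (is.null(mask)) {
    cx <- (gs + 1) / 2
    gx <- matrix(seq_len(gs), gs, dims[2])
    gy <- matrix(seq_len(dims[2]), gs, dims[2], byrow = TRUE)
    mask <- sqrt((gx - cx)^2 + (gy - cx)^2) <= gs / 2 - 0.5
  }
  bump <- array(0, dim = dims)
  if (!is.null(effect)) {
    gx <- matrix(seq_len(gs), gs, dims[2])
    gy <- matrix(seq_len(dims[2]), gs, dims[2], byrow = TRUE)
    blob <- exp(-((gx - effect$center[1])^2 + (gy - effect$center[2])^2) /
                  (2 * effect$radius^2))
    bins <- seq(max(1, effect$band[1]), min(dims[3], effect$band[2]))
    for (f in bins) bump[, , f] <- blob * effect$amplitude
  }
  images <- withr::with_seed(seed, {
    lapply(seq_len(n_subjects), function(i) {
      noise <- array(rnorm(prod(dims), 0, noise_sd), dim = dims)
      sm <- cpp_smooth3d(as.numeric(noise), dims,
                         as.logical(mask), smooth_sigma)
      vol <- baseline + array(sm, dim = dims) + bump
      vol[rep(!mask, times = dims[3])] <- NaN
      vol
    })
  })
  list(images = images, mask = mask)
}
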