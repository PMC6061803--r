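#' Two-sample nonparametric permutation test on scalp-by-frequency images
#'
#' Voxelwise pseudo-T statistics (two-sample T with the pooled variance
#' image smoothed by `variance_fwhm`, which stabilizes low-df variance
#' estimates), assessed by permutation of the group labels with cluster-level
#' family-wise correction: the cluster-forming threshold is the
#' `cluster_percentile` of the pooled permutation voxel statistics, clusters
#' are 26-connected suprathreshold components of `|pseudo-T|` in the 3D
#' scalp-by-frequency volume, and each observed cluster's corrected p-value
#' is the proportion of permutations (the identity included) whose maximum
#' cluster size reaches its size.  When the number of distinct label
#' arrangements is below `n_permutations` the permutation distribution is
#' enumerated exhaustively.
#'
#' @param images_group_a,images_group_b lists of `scalp_frequency_image`
#'   objects, or of 3D arrays sharing the mask.
#' @param mask `gs` x `gs` logical mask (taken from the images when they are
#'   `scalp_frequency_image` objects).
#' @param n_permutations permutation count (default 5000).
#' @param cluster_percentile percentile (0-100) of the pooled permutation
#'   statistics used as the cluster-forming threshold.
#' @param alpha family-wise significance level for reporting.
#' @param variance_fwhm FWHM `(mm, mm, Hz)` for variance smoothing; defaults
#'   to the images' own smoothing kernel, or `c(8, 8, 8)`.
#' @param pixel_mm,freq_step_hz physical scales, taken from the images when
#'   available.
#' @param seed integer seed for the random permutations.
#' @return An object of class `group_stats_result`: `pseudo_t` (masked 3D
#'   array, group A minus group B), `cluster_table` (`cluster_id`, `size`,
#'   `peak_x`, `peak_y`, `peak_freq_bin`, `corrected_p`),
#'   `cluster_forming_threshold`, `n_permutations`, `max_cluster_null`.
#' @export
snpm_two_sample <- function(images_group_a, images_group_b, mask = NULL,
                            n_permutations = 5000L, cluster_percentile = 95,
                            alpha = 0.05, variance_fwhm = NULL,
                            pixel_mm = NULL, freq_step_hz = NULL, seed = 1L) {
  ga <- normalize_images(images_group_a)
  gb <- normalize_images(images_group_b)
  if (is.null(mask)) mask <- ga$mask
  if (is.null(pixel_mm)) pixel_mm <- ga$pixel_mm %||% 1
  if (is.null(freq_step_hz)) freq_step_hz <- ga$freq_step %||% 1
  if (is.null(variance_fwhm)) variance_fwhm <- ga$fwhm %||% c(8, 8, 8)
  na <- length(ga$arrays)
  nb <- length(gb$arrays)
  stopifnot(na >= 2, nb >= 2)
  dims <- dim(ga$arrays[[1]])
  all_arr <- c(ga$arrays, gb$arrays)
  stopifnot(all(vapply(all_arr, function(a) identical(dim(a), dims), logical(1))))
  n <- na + nb
  V <- prod(dims)
  X <- vapply(all_arr, as.numeric, numeric(V))    # V x n
  X[!is.finite(X)] <- 0
  vox_mask <- rep(as.logical(mask), times = dims[3])

  perms <- make_permutations(n, na, n_permutations, seed)
  P <- ncol(perms)

  total_ss <- rowSums(X^2) - rowSums(X)^2 / n
  if (all(total_ss[vox_mask] < 1e-24)) {
    stop("degenerate variance: all images identical inside the mask")
  }

  sigma_vox <- variance_fwhm / (2 * sqrt(2 * log(2))) /
    c(pixel_mm, pixel_mm, freq_step_hz)
  mlog <- as.logical(mask)

  # one matmul gives the group-A sums for every permutation at once; the
  # pseudo-T volumes for all permutations are then computed in one pass
  Wa <- matrix(0, n, P)
  Wa[cbind(as.vector(perms), rep(seq_len(P), each = na))] <- 1
  stat <- cpp_pseudo_t_perm(X %*% Wa, rowSums(X), rowSums(X^2),
                            na, nb, dims, mlog, sigma_vox)
  observed <- stat[, 1]
  athresh <- cpp_quantile_abs_masked(stat, dims, mlog,
                                     cluster_percentile / 100)
  maxes <- cpp_max_cluster_sizes(stat, dims, mlog, athresh, absolute = TRUE)
  lab <- cpp_label_clusters(observed, dims, mlog, athresh, absolute = TRUE)
  sizes <- lab$sizes
  cluster_table <- data.frame(cluster_id = integer(), size = integer(),
                              peak_x = integer(), peak_y = integer(),
                              peak_freq_bin = integer(),
                              corrected_p = numeric())
  if (length(sizes) > 0) {
    ord <- order(sizes, decreasing = TRUE)
    for (ci in ord) {
      vox <- which(lab$labels == ci)
      peak <- vox[which.max(abs(observed)[vox])]
      coords <- arrayInd(peak, dims)
      cluster_table <- rbind(cluster_table, data.frame(
        cluster_id = ci, size = sizes[ci],
        peak_x = coords[1], peak_y = coords[2], peak_freq_bin = coords[3],
        corrected_p = mean(maxes >= sizes[ci])))
    }
  }
  structure(list(pseudo_t = array(replace(observed, !vox_mask, NA_real_),
                                  dim = dims),
                 cluster_table = cluster_table,
                 cluster_forming_threshold = athresh,
                 n_permutations = P,
                 max_cluster_null = maxes,
                 alpha = alpha,
                 labels = array(lab$labels, dim = dims)),
            class = "group_stats_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

normalize_images <- function(images) {
  if (inherits(images, "scalp_frequency_image")) images <- list(images)
  if (is.array(images) && length(dim(images)) == 4) {
    images <- lapply(seq_len(dim(images)[4]), function(i) images[, , , i])
  }
  stopifnot(is.list(images), length(images) >= 1)
  if (inherits(images[[1]], "scalp_frequency_image")) {
    first <- images[[1]]
    freqs <- first$freq_axis
    list(arrays = lapply(images, function(im) im$grid),
         mask = first$mask,
         pixel_mm = first$projection_meta$pixel_mm,
         freq_step = if (length(freqs) > 1) freqs[2] - freqs[1] else 1,
         fwhm = first$projection_meta$fwhm)
  } else {
    list(arrays = images, mask = NULL, pixel_mm = NULL, freq_step = NULL,
         fwhm = NULL)
  }
}

# Group-A index sets, identity arrangement first.  Exhaustive when feasible,
# otherwise seeded random draws.
make_permutations <- function(n, na, n_permutations, seed) {
  total <- choose(n, na)
  if (total <= n_permutations) {
    all_sets <- combn(n, na)
    identity_col <- which(apply(all_sets, 2, function(s) {
      identical(as.integer(s), seq_len(na))
    }))
    cbind(all_sets[, identity_col], all_sets[, -identity_col, drop = FALSE])
  } else {
    withr::with_seed(seed, {
      draws <- replicate(n_permutations - 1L, sort(sample.int(n, na)))
      cbind(seq_len(na), matrix(draws, nrow = na))
    })
  }
}

#' @export
print.group_stats_result <- function(x, ...) {
  sig <- sum(x$cluster_table$corrected_p < x$alpha)
  cat(sprintf(paste0("<group_stats_result> %d permutations, cluster-forming ",
                     "|T| > %.3f\n  %d cluster(s), %d significant at ",
                     "corrected p < %.2f\n"),
              x$n_permutations, x$cluster_forming_threshold,
              nrow(x$cluster_table), sig, x$alpha))
  invisible(x)
}
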