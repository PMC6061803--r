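#' Combine planar-gradiometer pairs by root mean square
#'
#' Collapses the two orthogonal planar gradiometers at each helmet location
#' into a single orientation-free series:
#' `out[loc, t] = sqrt((x_a(t)^2 + x_b(t)^2) / 2)`.
#' The result is invariant to swapping the channels within a pair; rows
#' follow `location_index` order.
#'
#' @param recording a `sensor_recording`.
#' @return `n_locations` x `n_samples` matrix with attributes
#'   `location_positions` and `sampling_rate`.
#' @export
combine_gradiometer_pairs <- function(recording) {
  stopifnot(inherits(recording, "sensor_recording"))
  pm <- recording$pair_map[order(recording$pair_map$location_index), ]
  bad <- pm$channel_a > nrow(recording$data) | pm$channel_b > nrow(recording$data)
  if (any(bad)) stop("pair_map refers to missing channels")
  a <- recording$data[pm$channel_a, , drop = FALSE]
  b <- recording$data[pm$channel_b, , drop = FALSE]
  out <- sqrt((a^2 + b^2) / 2)
  rownames(out) <- NULL
  attr(out, "location_positions") <-
    recording$positions[pm$channel_a, , drop = FALSE]
  attr(out, "sampling_rate") <- recording$sampling_rate
  out
}

#' Reduce location series by principal components analysis
#'
#' PCA on the time-domain covariance of the location series.  Rows
#' (locations) are mean-centred but not variance-normalized, since paired
#' gradiometer channels share units.  Either a fixed number of components is
#' retained (`mode = "fixed_k"`, the pipeline default is 60) or the smallest
#' K whose cumulative variance reaches a target
#' (`mode = "variance_target"`).
#'
#' @param location_timeseries `n_locations` x `n_samples` matrix.
#' @param mode `"fixed_k"` or `"variance_target"`.
#' @param k_or_target the fixed K, or the variance fraction target in (0, 1].
#' @return An object of class `pc_reduction`: `scores` (K x `n_samples`),
#'   `loadings` (`n_locations` x K, orthonormal columns), `mean_vector`,
#'   `explained_variance_fraction`.
#' @export
reduce_dimensionality <- function(location_timeseries,
                                  mode = c("fixed_k", "variance_target"),
                                  k_or_target = 60) {
  mode <- match.arg(mode)
  x <- as.matrix(location_timeseries)
  d <- nrow(x)
  n <- ncol(x)
  if (n <= d) {
    warning("n_samples <= n_locations; covariance estimate may be unstable")
  }
  mu <- rowMeans(x)
  xc <- x - mu
  cv <- tcrossprod(xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  total <- sum(vals)
  if (mode == "fixed_k") {
    k <- as.integer(k_or_target)
    rank_x <- sum(vals > max(vals) * 1e-12)
    if (k > rank_x) {
      stop("fixed_k = ", k, " exceeds the input rank (", rank_x, ")")
    }
  } else {
    stopifnot(k_or_target > 0, k_or_target <= 1)
    k <- which(cumsum(vals) / total >= k_or_target)[1]
  }
  loadings <- eg$vectors[, seq_len(k), drop = FALSE]
  structure(list(scores = crossprod(loadings, xc),
                 loadings = loadings,
                 mean_vector = mu,
                 explained_variance_fraction = sum(vals[seq_len(k)]) / total,
                 eigenvalues = vals),
            class = "pc_reduction")
}

#' Reconstruct location series from a reduction
#'
#' `loadings %*% scores + mean`; the total-sum-of-squares relative error is
#' at most `1 - explained_variance_fraction`.
#'
#' @param reduction a `pc_reduction`.
#' @return `n_locations` x `n_samples` matrix.
#' @export
reconstruct_reduction <- function(reduction) {
  reduction$loadings %*% reduction$scores + reduction$mean_vector
}
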