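test_that("gradiometer pairs combine by RMS", {
  lay <- helmet_layout(2)
  data <- rbind(c(3, 0), c(4, 0), c(1, 2), c(1, 2))
  rec <- sensor_recording(data, 1000, lay$positions, lay$pair_map)
  out <- combine_gradiometer_pairs(rec)
  expect_equal(out[1, 1], sqrt((9 + 16) / 2))
  expect_equal(out[1, 2], 0)
  expect_equal(out[2, ], c(1, 2), ignore_attr = TRUE)

  # swapping channels within a pair changes nothing
  swapped <- rec
  swapped$data <- data[c(2, 1, 4, 3), ]
  expect_equal(combine_gradiometer_pairs(swapped), out, ignore_attr = TRUE)
})

test_that("a 204-channel recording collapses to 102 locations", {
  fx <- make_test_recording(n_samples = 500, n_locations = 102)
  out <- combine_gradiometer_pairs(fx$recording)
  expect_equal(dim(out), c(102, 500))
  expect_equal(nrow(attr(out, "location_positions")), 102)
})

test_that("PCA reduction honours both modes and reconstructs", {
  set.seed(31)
  # near-isotropic noise: 99% variance needs ~99% of the components
  x <- matrix(rnorm(40 * 5000), 40)
  red <- reduce_dimensionality(x, "variance_target", 0.99)
  k <- ncol(red$loadings)
  expect_gt(k, 30)
  expect_gte(red$explained_variance_fraction, 0.99)

  # rank-1 data: one component suffices
  r1 <- outer(rnorm(40), rnorm(5000))
  red1 <- reduce_dimensionality(r1, "variance_target", 0.99)
  expect_equal(ncol(red1$loadings), 1)

  fx <- make_test_recording(n_samples = 2500, n_locations = 102)
  rms <- combine_gradiometer_pairs(fx$recording)
  red60 <- reduce_dimensionality(rms, "fixed_k", 60)
  expect_equal(dim(red60$scores), c(60, 2500))
  expect_equal(crossprod(red60$loadings), diag(60), tolerance = 1e-10,
               ignore_attr = TRUE)

  # reconstruction error bounded by the unexplained variance
  recon <- reconstruct_reduction(red60)
  rel_err <- sum((rms - recon)^2) / sum((rms - rowMeans(rms))^2)
  expect_lte(rel_err, 1 - red60$explained_variance_fraction + 1e-10)

  expect_error(reduce_dimensionality(r1, "fixed_k", 5), "rank")
})
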