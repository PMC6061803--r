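test_that("Vieira-Morf recovers known coefficients and matches least squares", {
  A <- array(0, c(2, 2, 1))
  A[, , 1] <- matrix(c(0.5, 0.3, 0, 0.4), 2, 2)
  x <- simulate_mvar(mvar_model(A, diag(2), 1), 1e5, seed = 51)

  vm <- fit_mvar(x, 1, method = "vm")
  expect_lt(max(abs(vm$A - A)), 0.03)
  ls <- fit_mvar(x, 1, method = "ls")
  expect_lt(max(abs(vm$A - ls$A)), 0.01)
  expect_lt(max(abs(vm$sigma - diag(2))), 0.05)

  # white noise: coefficients shrink like 1/sqrt(n)
  set.seed(52)
  w <- matrix(rnorm(3 * 2e4), 3)
  fw <- fit_mvar(w, 1)
  expect_lt(max(abs(fw$A)), 3 / sqrt(2e4) * 3)
})

test_that("fitted models of stable processes are stable", {
  for (s in 1:3) {
    net <- generate_source_network(4, 5, "low", seed = 400 + s)
    m <- build_mvar_from_network(net, 2, 0.5, seed = s)
    x <- simulate_mvar(m, 8000, seed = 60 + s)
    expect_lt(fit_mvar(x, 2)$stability_index, 0)
  }
})

test_that("BIC selects the generating order", {
  A <- array(0, c(3, 3, 2))
  A[, , 1] <- diag(0.4, 3); A[1, 2, 1] <- 0.3
  A[, , 2] <- diag(-0.35, 3)
  x <- simulate_mvar(mvar_model(A, diag(3), 1), 5e4, seed = 53)
  sel <- select_order_bic(x, 6)
  expect_equal(sel$p_opt, 2)
  expect_length(sel$bic_curve, 6)
  expect_equal(sel$model$order, 2)

  sel1 <- select_order_bic(x, 1)
  expect_equal(sel1$p_opt, 1)
})

test_that("stability index matches companion-polynomial roots", {
  expect_equal(stability_index(mvar_model(matrix(0.5), matrix(1))), log(0.5))
  expect_equal(stability_index(mvar_model(matrix(1.0), matrix(1))), 0)

  a1 <- 0.5; a2 <- 0.3
  A <- array(c(a1, a2), c(1, 1, 2))
  roots <- polyroot(c(-a2, -a1, 1))          # z^2 - a1 z - a2
  expect_equal(stability_index(mvar_model(A, matrix(1))),
               log(max(Mod(roots))), tolerance = 1e-12)
})

test_that("back-projection is consistent with the loadings", {
  fx <- make_test_recording(n_samples = 3000, n_locations = 20)
  rms <- combine_gradiometer_pairs(fx$recording)
  red <- reduce_dimensionality(rms, "fixed_k", 8)
  fit <- fit_mvar(red$scores, 2)
  bp <- backproject_mvar(fit, red)
  expect_equal(bp$dimension, 20)

  # orthonormality: re-projection recovers the PC-space coefficients
  L <- red$loadings
  for (r in 1:2) {
    expect_equal(t(L) %*% bp$A[, , r] %*% L, fit$A[, , r], tolerance = 1e-10)
  }
  # nonzero companion eigenvalues, and hence the index, are preserved
  expect_equal(bp$stability_index, fit$stability_index)
  direct <- stability_index(bp$A)
  expect_equal(direct, fit$stability_index, tolerance = 1e-8)

  # identity loadings: back-projection is a no-op
  red_id <- red
  red_id$loadings <- diag(8)
  bp_id <- backproject_mvar(fit, red_id)
  expect_equal(bp_id$A, fit$A)

  expect_error(backproject_mvar(fit_mvar(red$scores[1:3, ], 1), red),
               "dimension")
})
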