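test_that("the default frequency grid matches the stated bin counts", {
  g <- default_frequency_grid(0.1, 80)
  expect_length(g, 800)
  expect_equal(g[1], 0.1)
  expect_equal(g[800], 80)
  expect_length(default_frequency_grid(1, 80), 80)
  expect_true(all(diff(g) > 0))
  expect_equal(diff(range(diff(g))), 0, tolerance = 1e-12)
})

test_that("PDC satisfies its defining identities", {
  # independent channels: no off-diagonal flow
  A <- array(0, c(3, 3, 2))
  A[, , 1] <- diag(c(0.5, 0.3, -0.2))
  A[, , 2] <- diag(c(-0.2, 0.1, 0.05))
  sp <- pdc(mvar_model(A, diag(3), 1000), seq(1, 80, 1), 1000)
  off <- sp$values
  for (f in seq_len(dim(off)[3])) diag(off[, , f]) <- 0
  expect_equal(max(off), 0)

  # column normalization at every frequency, and the hand-evaluated
  # bivariate formula
  fx <- make_test_recording(n_samples = 2000, n_locations = 10)
  fit <- fit_mvar(combine_gradiometer_pairs(fx$recording), 2)
  spf <- pdc(fit, seq(0.5, 100, 0.5), 1000)
  norms <- apply(spf$values^2, c(2, 3), sum)
  expect_lt(max(abs(norms - 1)), 1e-12)

  Ab <- array(0, c(2, 2, 1))
  Ab[, , 1] <- matrix(c(0.5, 0.3, 0, 0.5), 2, 2)
  mb <- mvar_model(Ab, diag(2), 1000)
  spb <- pdc(mb, 10, 1000)
  theta <- 2 * pi * 10 / 1000
  hand <- Mod(0.3 * exp(-1i * theta)) /
    sqrt(Mod(0.3 * exp(-1i * theta))^2 + Mod(1 - 0.5 * exp(-1i * theta))^2)
  expect_equal(spb$values[2, 1, 1], hand, tolerance = 1e-10)
  expect_equal(spb$values[, , 1], oracle_pdc(Ab, 10, 1000), tolerance = 1e-12)
})

test_that("binarization keeps exactly the top fraction with deterministic ties", {
  d <- 102
  vals <- array(runif(d * d * 2), c(d, d, 2))
  sp <- structure(list(frequencies = c(1, 2), values = vals),
                  class = "pdc_spectrum")
  adj <- binarize_top_fraction(sp, 0.15)
  k <- floor(0.15 * d * (d - 1))
  expect_equal(k, 1545)
  expect_equal(sum(adj$adjacency[, , 1]), k)
  expect_equal(sum(adj$adjacency[, , 2]), k)
  expect_true(all(apply(adj$adjacency, 3, function(a) all(diag(a) == 0))))

  # brute-force oracle: the kept entries are exactly the k largest
  off <- which(diag(d) == 0)
  v1 <- vals[, , 1][off]
  keep_oracle <- off[order(v1, decreasing = TRUE)[seq_len(k)]]
  expect_setequal(which(adj$adjacency[, , 1] == 1), keep_oracle)

  # all-equal values: ties resolved in ascending (row, column) order
  tie <- array(0.5, c(4, 4, 1))
  spt <- structure(list(frequencies = 1, values = tie), class = "pdc_spectrum")
  at <- binarize_top_fraction(spt, 0.3)   # floor(0.3 * 12) = 3 edges
  picked <- which(at$adjacency[, , 1] == 1, arr.ind = TRUE)
  picked <- picked[order(picked[, 1], picked[, 2]), ]
  expect_equal(unname(picked), rbind(c(1, 2), c(1, 3), c(1, 4)))

  # invariance under strictly monotone transforms
  spm <- sp
  spm$values <- exp(3 * sp$values)
  expect_equal(binarize_top_fraction(spm, 0.15)$adjacency, adj$adjacency)
})
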