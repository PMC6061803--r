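test_that("source networks have the requested size and class ordering", {
  net <- generate_source_network(6, 6, "high", seed = 7)
  expect_s3_class(net, "directed_network")
  expect_equal(nrow(net$edges), 6)
  expect_true(all(net$edges >= 1 & net$edges <= 6))
  expect_true(all(net$edges[, 1] != net$edges[, 2]))

  # 2 nodes / 2 edges: combinatorics force the reciprocal pair
  forced <- generate_source_network(2, 2, "high", seed = 1)
  expect_setequal(paste(forced$edges[, 1], forced$edges[, 2]), c("1 2", "2 1"))

  # 20 + 20 draws: high class strictly exceeds low on the brute-force oracle
  lo <- vapply(1:20, function(i) {
    mean(oracle_local_efficiency(network_adjacency(
      generate_source_network(6, 6, "low", seed = 100 + i))))
  }, numeric(1))
  hi <- vapply(1:20, function(i) {
    mean(oracle_local_efficiency(network_adjacency(
      generate_source_network(6, 6, "high", seed = 200 + i))))
  }, numeric(1))
  expect_true(max(lo) < min(hi))
  # recorded metadata matches the oracle
  net2 <- generate_source_network(6, 6, "low", seed = 5)
  expect_equal(attr(net2, "mean_local_efficiency"),
               mean(oracle_local_efficiency(network_adjacency(net2))))
  expect_length(attr(net2, "class_band"), 2)
})

test_that("network-driven MVAR models respect topology and stability", {
  empty <- directed_network(3, matrix(integer(0), ncol = 2))
  m0 <- build_mvar_from_network(empty, 1, 0.5, seed = 3)
  expect_equal(m0$A[, , 1][row(m0$A[, , 1]) != col(m0$A[, , 1])],
               rep(0, 6))

  for (s in 1:5) {
    net <- generate_source_network(5, 7, "high", seed = 300 + s)
    m <- build_mvar_from_network(net, 3, 0.6, seed = s)
    expect_lt(m$stability_index, 0)
    # off-diagonal support only at true edges
    adj <- network_adjacency(net)
    for (r in 1:3) {
      nz <- abs(m$A[, , r]) > 0
      diag(nz) <- FALSE
      expect_true(all(adj[nz] == 1))
    }
  }

  # single edge 1 -> 2: PDC flows one way only
  net1 <- directed_network(2, cbind(1, 2))
  m1 <- build_mvar_from_network(net1, 2, 0.5, seed = 11)
  sp <- pdc(m1, frequencies = seq(1, 100, by = 1), sampling_rate = 1000)
  expect_gt(max(sp$values[2, 1, ]), 0)
  expect_equal(max(sp$values[1, 2, ]), 0)

  expect_error(build_mvar_from_network(net1, 2, -1, seed = 1), "positive")
})

test_that("simulate_mvar matches the AR(1) closed form and is deterministic", {
  m <- mvar_model(matrix(0.5), matrix(1), 1000)
  x <- simulate_mvar(m, 1e5, seed = 9)
  expect_equal(dim(x), c(1, 1e5))
  expect_lt(abs(var(as.vector(x)) - 1 / (1 - 0.25)) / (1 / (1 - 0.25)), 0.05)
  expect_identical(x, simulate_mvar(m, 1e5, seed = 9))
  expect_false(identical(x, simulate_mvar(m, 1e5, seed = 10)))
})

test_that("simulated series allow parameter recovery", {
  A <- array(0, c(2, 2, 1))
  A[, , 1] <- matrix(c(0.5, 0.3, 0, 0.4), 2, 2)
  m <- mvar_model(A, diag(2), 1000)
  x <- simulate_mvar(m, 1e5, seed = 21)
  fit <- fit_mvar(x, 1)
  expect_lt(max(abs(fit$A - A)), 0.05)
})

test_that("gain matrices are well formed", {
  lay <- helmet_layout()
  g <- make_gain_matrix(204, 6, lay$positions, seed = 4)
  expect_equal(dim(g$weights), c(204, 6))
  expect_equal(qr(g$weights)$rank, 6)
  expect_true(all(colSums(abs(g$weights)) > 0))
  # noiseless sensor covariance has rank equal to the source count
  expect_equal(qr(g$weights %*% t(g$weights))$rank, 6)

  g0 <- make_gain_matrix(204, 6, lay$positions, spread = 0, seed = 4)
  expect_equal(colSums(g0$weights != 0), rep(1, 6), ignore_attr = TRUE)
})

test_that("sensor projection respects the requested SNR", {
  lay <- helmet_layout(20)
  net <- generate_source_network(3, 4, "high", seed = 2)
  m <- build_mvar_from_network(net, 2, 0.5, seed = 3)
  src <- simulate_mvar(m, 2e4, seed = 4)
  gain <- make_gain_matrix(40, 3, lay$positions, spread = 0.03, seed = 5)

  clean <- project_and_add_noise(src, gain, Inf, seed = 6, layout = lay)
  expect_equal(clean$data, gain$weights %*% src, ignore_attr = TRUE)

  noisy <- project_and_add_noise(src, gain, 1, seed = 6, layout = lay)
  ratio <- apply(gain$weights %*% src, 1, sd) /
    apply(noisy$data - gain$weights %*% src, 1, sd)
  expect_true(all(abs(ratio - 1) < 0.05))

  # higher SNR preserves the clean signal better
  lo <- project_and_add_noise(src, gain, 0.1, seed = 7, layout = lay)
  hi <- project_and_add_noise(src, gain, 10, seed = 7, layout = lay)
  expect_gt(cor(hi$data[1, ], clean$data[1, ]),
            cor(lo$data[1, ], clean$data[1, ]))
})

test_that("group cohorts validate specs and record ground truth", {
  specs <- list(group_spec("control"),
                group_spec("patient", attenuation = 0.8,
                           band = c(30, 50), region = c(0, -1, 0.5)))
  empty <- generate_group_cohort(specs, 0, seed = 1)
  expect_length(empty$recordings, 0)
  expect_equal(nrow(empty$labels), 0)
  expect_length(empty$truth$specs, 2)

  small <- generate_group_cohort(specs, 2, seed = 1, n_samples = 1200,
                                 n_sources = 5, n_edges = 8)
  expect_length(small$recordings, 4)
  expect_equal(as.vector(table(small$labels$group)), c(2, 2))
  expect_s3_class(small$recordings[[1]], "sensor_recording")
  # determinism
  again <- generate_group_cohort(specs, 2, seed = 1, n_samples = 1200,
                                 n_sources = 5, n_edges = 8)
  expect_identical(small$recordings[[1]]$data, again$recordings[[1]]$data)

  dup <- list(group_spec("a"), group_spec("a"))
  expect_error(generate_group_cohort(dup, 1, seed = 1), "distinct")
  expect_error(group_spec("x", attenuation = 1.5))
})
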