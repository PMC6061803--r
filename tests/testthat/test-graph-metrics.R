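test_that("shortest paths and efficiencies match hand-countable cases", {
  # chain 1 -> 2 -> 3 (adj[target, source] = 1)
  chain <- matrix(0, 3, 3)
  chain[2, 1] <- 1; chain[3, 2] <- 1
  D <- shortest_path_lengths(chain)
  expect_equal(D[1, 3], 2)
  expect_equal(D[3, 1], Inf)
  expect_equal(diag(D), rep(0, 3))
  expect_equal(global_efficiency(chain), (1 + 0.5 + 1) / 6)

  K4 <- 1 - diag(4)
  expect_equal(shortest_path_lengths(K4), 1 - diag(4) + 0)
  expect_equal(global_efficiency(K4), 1)
  expect_equal(local_efficiency(K4), rep(1, 4))
  expect_equal(global_efficiency(matrix(0, 3, 3)), 0)

  # star: centre <-> leaves, no leaf-leaf edges
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- 1; star[2:4, 1] <- 1
  expect_equal(local_efficiency(star), rep(0, 4))

  expect_error(shortest_path_lengths(diag(3)), "diagonal")
})

test_that("distances and local efficiency agree with independent oracles", {
  set.seed(71)
  for (i in 1:60) {
    d <- sample(2:10, 1)
    adj <- random_adjacency(d, runif(1, 0.1, 0.6))
    expect_equal(shortest_path_lengths(adj), fw_distances(adj))
    expect_equal(local_efficiency(adj), oracle_local_efficiency(adj))
    expect_equal(global_efficiency(adj), oracle_global_efficiency(adj))
  }
})

test_that("local efficiency is bounded and monotone under neighbourhood edges", {
  set.seed(72)
  for (i in 1:25) {
    d <- sample(4:9, 1)
    adj <- random_adjacency(d, 0.35)
    eff <- local_efficiency(adj)
    expect_true(all(eff >= 0 & eff <= 1))

    # add an edge inside some node's neighbourhood subgraph
    node <- sample(d, 1)
    nb <- which((adj[node, ] | adj[, node]) & seq_len(d) != node)
    if (length(nb) >= 2) {
      pair <- sample(nb, 2)
      if (adj[pair[2], pair[1]] == 0) {
        adj2 <- adj
        adj2[pair[2], pair[1]] <- 1
        expect_gte(local_efficiency(adj2)[node], eff[node])
      }
    }
  }
})

test_that("efficiency series maps bins independently", {
  set.seed(73)
  a <- random_adjacency(12, 0.3)
  arr <- array(a, c(12, 12, 5))
  ser <- structure(list(frequencies = 1:5, adjacency = arr,
                        edge_count = sum(a), threshold_fraction = NA),
                   class = "adjacency_series")
  eff <- local_efficiency_series(ser)
  expect_equal(dim(eff$values), c(12, 5))
  for (f in 2:5) expect_equal(eff$values[, f], eff$values[, 1])
  expect_equal(eff$values[, 1], local_efficiency(a))

  # planted ordering: dense graphs beat sparse graphs columnwise
  dense <- 1 - diag(8)
  sparse <- matrix(0, 8, 8); sparse[2, 1] <- 1
  arr2 <- array(c(dense, sparse), c(8, 8, 2))
  ser2 <- structure(list(frequencies = 1:2, adjacency = arr2,
                         edge_count = NA, threshold_fraction = NA),
                    class = "adjacency_series")
  eff2 <- local_efficiency_series(ser2)
  expect_gt(mean(eff2$values[, 1]), mean(eff2$values[, 2]))

  # long format
  lg <- efficiency_long(eff)
  expect_equal(nrow(lg), 60)
  expect_equal(lg$efficiency[1:12], eff$values[, 1])
})
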