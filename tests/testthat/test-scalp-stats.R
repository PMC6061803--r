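test_that("the 2D projection preserves the helmet geometry", {
  vertex <- matrix(c(0, 0, 0.09), 1)
  expect_equal(project_sensors_2d(vertex), cbind(x = 0, y = 0))

  # mirror pair about the midline (y -> -y)
  p <- rbind(c(0.03, 0.05, 0.06), c(0.03, -0.05, 0.06))
  xy <- project_sensors_2d(p)
  expect_equal(xy[1, "x"], xy[2, "x"])
  expect_equal(xy[1, "y"], -xy[2, "y"])

  lay <- helmet_layout()
  co <- project_sensors_2d(lay$location_positions)
  grid <- make_scalp_grid(co, 64)
  expect_true(all(sqrt(rowSums(co^2)) <= max(abs(grid$x))))
  idx <- cbind(
    findInterval(co[, 1], grid$x + grid$pixel_mm / 2) + 1L,
    findInterval(co[, 2], grid$y + grid$pixel_mm / 2) + 1L)
  expect_true(all(grid$mask[idx]))   # every sensor falls inside the mask
})

test_that("grid interpolation is exact on constants, peaks and planes", {
  lay <- helmet_layout()
  co <- project_sensors_2d(lay$location_positions)
  grid <- make_scalp_grid(co, 32)
  ip <- build_grid_interpolator(co, grid)

  cimg <- interpolate_to_grid(rep(2.5, 102), interpolator = ip)
  expect_equal(range(cimg, na.rm = TRUE), c(2.5, 2.5))
  expect_true(all(is.nan(cimg[!grid$mask])))

  peak <- interpolate_to_grid(replace(rep(0, 102), 7, 1), interpolator = ip)
  pix <- arrayInd(which.max(replace(peak, is.nan(peak), -1)), dim(peak))
  expect_lt(sqrt((grid$x[pix[1]] - co[7, 1])^2 + (grid$y[pix[2]] - co[7, 2])^2),
            3 * grid$pixel_mm)

  v <- 0.02 * co[, 1] - 0.013 * co[, 2] + 1
  img <- interpolate_to_grid(v, interpolator = ip)
  truth <- outer(grid$x, grid$y, function(x, y) 0.02 * x - 0.013 * y + 1)
  inside <- ip$pixel_index[ip$inside_hull]
  expect_lt(max(abs(img[inside] - truth[inside])), 1e-10)
})

test_that("Gaussian smoothing preserves constants and impulses behave", {
  dims <- c(20, 20, 15)
  mask <- matrix(TRUE, 20, 20)
  const <- array(3, dims)
  sm <- smooth_image(const, mask, c(8, 8, 8), pixel_mm = 4, freq_step_hz = 2)
  expect_equal(range(sm), c(3, 3))

  delta <- array(0, dims); delta[10, 10, 8] <- 1
  smd <- smooth_image(delta, mask, c(8, 8, 8), 4, 2)
  # mask normalization inflates boundary voxels slightly, so the impulse
  # mass is conserved only approximately
  expect_equal(sum(smd), 1, tolerance = 5e-3)
  expect_equal(which.max(smd), which(delta == 1))
  # impulse response matches the analytic separable Gaussian at the centre
  sig <- 8 / (2 * sqrt(2 * log(2))) / c(4, 4, 2)
  expect_equal(smd[10, 10, 8], prod(1 / sqrt(2 * pi) / sig), tolerance = 0.02)

  expect_equal(smooth_image(delta, mask, c(0, 0, 0), 4, 2), delta)
})

test_that("the permutation test behaves under null, planted and relabelled data", {
  si <- simulate_scalp_images(16, dims = c(16, 16, 20), seed = 81)
  null_res <- snpm_two_sample(si$images[1:8], si$images[9:16], mask = si$mask,
                              n_permutations = 300, pixel_mm = 20,
                              freq_step_hz = 4, seed = 5)
  expect_s3_class(null_res, "group_stats_result")
  expect_true(all(null_res$cluster_table$corrected_p >= 0 &
                    null_res$cluster_table$corrected_p <= 1))

  # identical image sets in both groups: observed pseudo-T is zero
  same <- snpm_two_sample(si$images[1:4], si$images[1:4], mask = si$mask,
                          n_permutations = 100, pixel_mm = 20,
                          freq_step_hz = 4, seed = 5)
  expect_equal(sum(same$cluster_table$corrected_p < 0.05), 0)

  # planted band/region difference is recovered at the right place
  eff <- list(center = c(11, 11), radius = 2.5, band = c(6, 12),
              amplitude = 0.2)
  se <- simulate_scalp_images(8, dims = c(16, 16, 20), effect = eff, seed = 82)
  hit <- snpm_two_sample(se$images, si$images[9:16], mask = si$mask,
                         n_permutations = 300, pixel_mm = 20,
                         freq_step_hz = 4, seed = 6)
  top <- hit$cluster_table[1, ]
  expect_lt(top$corrected_p, 0.05)
  expect_lt(sqrt((top$peak_x - 11)^2 + (top$peak_y - 11)^2), 6)
  expect_true(top$peak_freq_bin >= 3 && top$peak_freq_bin <= 15)

  # swapping the groups flips the sign but not the inference (exhaustive
  # permutations, so the invariance is exact)
  a4 <- se$images[1:4]; b4 <- si$images[9:12]
  fwd <- snpm_two_sample(a4, b4, mask = si$mask, n_permutations = 200,
                         pixel_mm = 20, freq_step_hz = 4, seed = 6)
  swap <- snpm_two_sample(b4, a4, mask = si$mask, n_permutations = 200,
                          pixel_mm = 20, freq_step_hz = 4, seed = 6)
  expect_equal(fwd$n_permutations, choose(8, 4))
  expect_equal(swap$cluster_table$size, fwd$cluster_table$size)
  expect_equal(swap$cluster_table$corrected_p, fwd$cluster_table$corrected_p)
  expect_equal(swap$pseudo_t, -fwd$pseudo_t)

  # determinism under a fixed seed
  again <- snpm_two_sample(se$images, si$images[9:16], mask = si$mask,
                           n_permutations = 300, pixel_mm = 20,
                           freq_step_hz = 4, seed = 6)
  expect_identical(hit$pseudo_t, again$pseudo_t)
  expect_identical(hit$max_cluster_null, again$max_cluster_null)

  # degenerate variance is flagged
  flat <- lapply(1:4, function(i) array(1, c(16, 16, 20)))
  expect_error(snpm_two_sample(flat[1:2], flat[3:4], mask = si$mask,
                               n_permutations = 50, pixel_mm = 20,
                               freq_step_hz = 4, seed = 1), "degenerate")
})

test_that("exhaustive permutations are used when feasible", {
  si <- simulate_scalp_images(8, dims = c(8, 8, 6), seed = 83)
  res <- snpm_two_sample(si$images[1:4], si$images[5:8], mask = si$mask,
                         n_permutations = 500, pixel_mm = 20,
                         freq_step_hz = 4, seed = 1)
  expect_equal(res$n_permutations, choose(8, 4))
})
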