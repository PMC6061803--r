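test_that("feature extractors behave on degenerate and rank-1 inputs", {
  set.seed(91)
  imgs <- lapply(1:8, function(i) array(rnorm(8 * 8 * 5), c(8, 8, 5)))
  same <- c(imgs[1:4], imgs[1:4])
  ext <- extract_features(same, rep(c("a", "b"), each = 4), mode = "z", k = 50)
  expect_equal(max(abs(ext$z)), 0)

  base <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  rank1 <- lapply(seq(0.5, 2, length.out = 6), function(s) s * base)
  extp <- extract_features(rank1, rep(c("a", "b"), 3), mode = "pca", k = 1)
  expect_equal(extp$explained, 1, tolerance = 1e-10)
  expect_error(extract_features(rank1, rep(c("a", "b"), 3), "pca", k = 3),
               "rank")

  f <- extract(extp, rank1)
  expect_equal(dim(f), c(6, 1))
})

test_that("feature extraction is leakage-free", {
  set.seed(92)
  imgs <- lapply(1:10, function(i) array(rnorm(6 * 6 * 4), c(6, 6, 4)))
  labels <- rep(c("a", "b"), each = 5)
  train <- 1:8
  held <- imgs[[10]]
  for (mode in c("z", "pca")) {
    ext <- extract_features(imgs[train], labels[train], mode = mode, k = 3)
    f1 <- extract(ext, held)
    # perturbing a non-training image cannot change the held-out features
    imgs2 <- imgs
    imgs2[[9]] <- imgs2[[9]] + 100
    ext2 <- extract_features(imgs2[train], labels[train], mode = mode, k = 3)
    expect_identical(extract(ext2, held), f1)
  }
})

test_that("ROC/AUC agree with hand cases and the rank-statistic oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(0, 0, 1, 1))$auc, 0)

  set.seed(93)
  for (i in 1:20) {
    dv <- rnorm(8) + sample(0:1, 8, TRUE)
    lab <- sample(c(0, 1), 8, replace = TRUE)
    if (length(unique(lab)) < 2) next
    r <- roc_auc(dv, lab)
    u <- wilcox.test(dv[lab == 1], dv[lab == 0], exact = FALSE)$statistic
    expect_equal(r$auc, unname(u) / (sum(lab == 1) * sum(lab == 0)))
    # invariance under strictly increasing transforms
    expect_equal(roc_auc(exp(2 * dv), lab)$auc, r$auc)
    # ROC curve is monotone and AUC is its trapezoidal area
    expect_true(all(diff(r$roc_points$tpr) >= 0))
    expect_true(all(diff(r$roc_points$fpr) >= 0))
  }

  # cross-check against pROC when available
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(94)
    dv <- rnorm(20)
    lab <- rep(c(0, 1), 10)
    expect_equal(roc_auc(dv, lab)$auc,
                 as.numeric(pROC::auc(pROC::roc(lab, dv, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("leave-one-out SVM separates planted groups", {
  eff <- list(center = c(9, 9), radius = 3, band = c(3, 8), amplitude = 1)
  a <- simulate_scalp_images(6, dims = c(12, 12, 10), effect = eff, seed = 95)
  b <- simulate_scalp_images(6, dims = c(12, 12, 10), seed = 96)
  imgs <- c(a$images, b$images)
  labels <- rep(c("patient", "control"), each = 6)
  res <- loocv_linear_svm(imgs, labels, feature_mode = "pca", k = 3,
                          n_repeats = 2, seed = 1)
  expect_equal(res$auc, 1)
  expect_length(res$per_subject_decision_values, 12)
  expect_error(loocv_linear_svm(imgs[c(1, 7, 8)],
                                factor(c("patient", "control", "control")),
                                n_repeats = 1, seed = 1))
})
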