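#' Fit a feature extractor on training images
#'
#' Two feature modes, both fitted strictly on the training subjects so the
#' extractor can be applied leakage-free to held-out images:
#' `"z"` computes a per-voxel two-group Z statistic on the training set and
#' keeps the `k` voxels with the largest `|Z|` (the held-out feature vector
#' is the image values at those voxels); `"pca"` takes the top-`k` principal
#' components of the vectorized training images and projects held-out images
#' onto them.
#'
#' @param train_images list of 3D arrays (or `scalp_frequency_image`s).
#' @param train_labels factor or vector of two group labels, one per image.
#' @param mode `"z"` or `"pca"`.
#' @param k number of voxels (`"z"`, default 1000) or components (`"pca"`).
#' @return An object of class `feature_extractor`; apply it with
#'   [extract()] or `predict()`.
#' @export
extract_features <- function(train_images, train_labels, mode = c("z", "pca"),
                             k = if (mode == "pca") 10L else 1000L) {
  mode <- match.arg(mode)
  X <- images_to_matrix(train_images)          # subjects x voxels
  lab <- as.factor(train_labels)
  stopifnot(nlevels(lab) == 2, nrow(X) == length(lab))
  keep_vox <- which(apply(is.finite(X), 2, all))
  Xk <- X[, keep_vox, drop = FALSE]
  if (mode == "z") {
    a <- lab == levels(lab)[1]
    na <- sum(a)
    nb <- sum(!a)
    ma <- colMeans(Xk[a, , drop = FALSE])
    mb <- colMeans(Xk[!a, , drop = FALSE])
    va <- apply(Xk[a, , drop = FALSE], 2, var)
    vb <- apply(Xk[!a, , drop = FALSE], 2, var)
    pooled <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    z <- (ma - mb) / sqrt(pooled * (1 / na + 1 / nb))
    z[!is.finite(z)] <- 0
    k <- min(k, length(z))
    sel <- order(-abs(z))[seq_len(k)]
    ext <- list(mode = "z", voxels = keep_vox[sel], z = z[sel])
  } else {
    k <- as.integer(k)
    mu <- colMeans(Xk)
    Xc <- sweep(Xk, 2, mu)
    sv <- svd(Xc, nu = 0, nv = min(k, min(dim(Xc))))
    rank_x <- sum(sv$d > max(sv$d) * 1e-10)
    if (k > rank_x) stop("k = ", k, " exceeds the training rank (", rank_x, ")")
    ext <- list(mode = "pca", voxels = keep_vox, mean = mu,
                rotation = sv$v[, seq_len(k), drop = FALSE],
                explained = sv$d[seq_len(k)]^2 / sum(sv$d^2))
  }
  structure(ext, class = "feature_extractor")
}

#' Apply a feature extractor to images
#'
#' @param extractor a `feature_extractor`.
#' @param images list of 3D arrays (or a single array).
#' @return Matrix, subjects x features.
#' @export
extract <- function(extractor, images) {
  stopifnot(inherits(extractor, "feature_extractor"))
  X <- images_to_matrix(images)
  if (extractor$mode == "z") {
    X[, extractor$voxels, drop = FALSE]
  } else {
    sweep(X[, extractor$voxels, drop = FALSE], 2, extractor$mean) %*%
      extractor$rotation
  }
}

#' @export
predict.feature_extractor <- function(object, newdata, ...) {
  extract(object, newdata)
}

images_to_matrix <- function(images) {
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  if (inherits(images, "scalp_frequency_image")) images <- list(images)
  arrays <- lapply(images, function(im) {
    if (inherits(im, "scalp_frequency_image")) im$grid else im
  })
  t(vapply(arrays, as.numeric, numeric(length(arrays[[1]]))))
}

#' Leave-one-out cross-validated linear SVM classification
#'
#' For every held-out subject a feature extractor and a linear soft-margin
#' SVM are fitted on the remaining subjects only; the SVM cost parameter is
#' searched on a log grid inside (0, 1] by internal cross-validation on the
#' training fold.  Training folds are balanced: subjects are randomly
#' dropped from the majority class until both classes are equally
#' represented, which removes the below-chance bias that plain
#' leave-one-out induces under the null (the held-out subject's class is
#' otherwise always the training minority).  The full leave-one-out loop is
#' repeated `n_repeats` times with re-randomized balancing and internal
#' fold assignment, and the held-out decision values are averaged before
#' the ROC is computed.
#'
#' @param images list of 3D arrays or `scalp_frequency_image`s.
#' @param labels two-class factor (second level is treated as positive).
#' @param feature_mode `"z"` or `"pca"`.
#' @param k features per fold (see [extract_features()]).
#' @param cost_grid candidate SVM cost values in (0, 1].
#' @param n_repeats repetitions of the full leave-one-out loop (default 10).
#' @param seed integer seed.
#' @return An object of class `classification_result`: averaged
#'   `per_subject_decision_values`, `true_labels`, `auc`, `roc_points`,
#'   `n_repeats`, `feature_mode`.
#' @export
loocv_linear_svm <- function(images, labels, feature_mode = c("z", "pca"),
                             k = if (feature_mode == "pca") 5L else 200L,
                             cost_grid = 10^seq(-2, 0, length.out = 5),
                             n_repeats = 10L, seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(all(cost_grid > 0), all(cost_grid <= 1))
  lab <- as.factor(labels)
  stopifnot(nlevels(lab) == 2, min(table(lab)) >= 2)
  arrays <- lapply(if (is.list(images)) images else list(images),
                   function(im) if (inherits(im, "scalp_frequency_image")) im$grid else im)
  n <- length(arrays)
  stopifnot(n == length(lab))
  pos <- levels(lab)[2]
  dec <- matrix(NA_real_, n, n_repeats)
  withr::with_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      for (i in seq_len(n)) {
        tr <- setdiff(seq_len(n), i)
        if (nlevels(droplevels(lab[tr])) < 2) stop("single-class training fold")
        # balance the training fold by subsampling the majority class
        repeat {
          tab <- table(lab[tr])
          excess <- tab - min(tab)
          if (all(excess == 0)) break
          maj <- names(excess)[which.max(excess)]
          pool <- tr[lab[tr] == maj]
          tr <- setdiff(tr, pool[sample.int(length(pool), max(excess))])
        }
        ext <- extract_features(arrays[tr], lab[tr], mode = feature_mode, k = k)
        ftr <- extract(ext, arrays[tr])
        fte <- extract(ext, arrays[i])
        cost <- pick_cost(ftr, lab[tr], cost_grid)
        fit <- e1071::svm(x = ftr, y = droplevels(lab[tr]),
                          kernel = "linear", cost = cost, scale = FALSE)
        dv <- attr(predict(fit, fte, decision.values = TRUE),
                   "decision.values")
        # orient so that larger values favour the positive class
        lv <- strsplit(colnames(dv), "/")[[1]]
        sign_flip <- if (lv[1] == pos) 1 else -1
        dec[i, rep_i] <- sign_flip * dv[1]
      }
    }
  })
  dvals <- rowMeans(dec)
  roc <- roc_auc(dvals, lab, positive = pos)
  structure(list(per_subject_decision_values = dvals,
                 true_labels = lab,
                 auc = roc$auc,
                 roc_points = roc$roc_points,
                 n_repeats = n_repeats,
                 feature_mode = feature_mode),
            class = "classification_result")
}

# small internal CV over the cost grid; ties go to the largest cost
pick_cost <- function(features, labels, cost_grid) {
  if (length(cost_grid) == 1) return(cost_grid)
  n <- nrow(features)
  folds <- sample(rep_len(seq_len(min(3, n)), n))
  acc <- vapply(cost_grid, function(cc) {
    correct <- 0L
    for (f in unique(folds)) {
      tr <- folds != f
      if (nlevels(droplevels(labels[tr])) < 2) return(NA_real_)
      fit <- e1071::svm(x = features[tr, , drop = FALSE],
                        y = droplevels(labels[tr]),
                        kernel = "linear", cost = cc, scale = FALSE)
      pr <- predict(fit, features[!tr, , drop = FALSE])
      correct <- correct + sum(pr == labels[!tr])
    }
    correct / n
  }, numeric(1))
  if (all(is.na(acc))) return(cost_grid[length(cost_grid)])
  cost_grid[max(which(acc == max(acc, na.rm = TRUE)))]
}

#' ROC curve and AUC from decision values
#'
#' Threshold sweep over the unique decision values with trapezoidal area;
#' tied values are handled by the trapezoid (equivalently, the rank-based
#' Mann-Whitney estimator with ties counted 1/2).
#'
#' @param decision_values numeric vector, larger favouring the positive
#'   class.
#' @param labels two-class factor or vector.
#' @param positive positive class label (default: second factor level).
#' @return A list with `roc_points` (data frame `fpr`, `tpr`, monotone
#'   non-decreasing) and `auc`.
#' @export
roc_auc <- function(decision_values, labels, positive = NULL) {
  lab <- as.factor(labels)
  stopifnot(nlevels(lab) == 2, length(decision_values) == length(lab))
  if (is.null(positive)) positive <- levels(lab)[2]
  is_pos <- lab == positive
  stopifnot(any(is_pos), any(!is_pos))
  np <- sum(is_pos)
  nn <- sum(!is_pos)
  thr <- sort(unique(decision_values), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(decision_values >= t & is_pos) / np,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(decision_values >= t & !is_pos) / nn,
                numeric(1))
  roc_points <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc_points$fpr) *
               (head(roc_points$tpr, -1) + roc_points$tpr[-1]) / 2)
  list(roc_points = roc_points, auc = auc)
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s features, %d repeats, AUC = %.3f\n",
              x$feature_mode, x$n_repeats, x$auc))
  invisible(x)
}
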