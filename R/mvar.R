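#' MVAR model container
#'
#' @param A array `d` x `d` x `p` of lag matrices; entry `(i, j)` of lag `r`
#'   couples channel `j` at lag `r` into channel `i`.
#' @param sigma `d` x `d` innovation covariance (symmetrized on input).
#' @param sampling_rate sampling rate in Hz.
#' @param bic optional BIC value of the fit.
#' @param .stability precomputed stability index; used internally when the
#'   index is known analytically (e.g. preserved by back-projection) so the
#'   companion eigendecomposition can be skipped.
#' @return An object of class `mvar_model` with the stability index
#'   precomputed.
#' @export
mvar_model <- function(A, sigma, sampling_rate = 1, bic = NA_real_,
                       .stability = NULL) {
  if (length(dim(A)) == 2) A <- array(A, dim = c(dim(A), 1))
  stopifnot(length(dim(A)) == 3, dim(A)[1] == dim(A)[2],
            all(is.finite(A)), all(is.finite(sigma)))
  sigma <- (sigma + t(sigma)) / 2
  m <- structure(list(A = A, sigma = sigma, order = dim(A)[3],
                      dimension = dim(A)[1], sampling_rate = sampling_rate,
                      bic = bic, stability_index = NA_real_),
                 class = "mvar_model")
  m$stability_index <- if (is.null(.stability)) stability_index(m) else .stability
  m
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> d = %d, p = %d, stability index = %.4f%s\n",
              x$dimension, x$order, x$stability_index,
              if (is.finite(x$bic)) sprintf(", BIC = %.1f", x$bic) else ""))
  invisible(x)
}

companion_matrix <- function(A) {
  d <- dim(A)[1]
  p <- dim(A)[3]
  C <- matrix(0, d * p, d * p)
  C[seq_len(d), ] <- matrix(A, nrow = d)
  if (p > 1) {
    idx <- seq_len(d * (p - 1))
    C[cbind(d + idx, idx)] <- 1
  }
  C
}

#' Stability index of an MVAR model
#'
#' The natural log of the spectral radius of the companion matrix.  The
#' process is stationary if and only if the index is negative.
#'
#' @param model an `mvar_model` (or a `d` x `d` x `p` coefficient array).
#' @return A scalar; `-Inf` for an all-zero model.
#' @export
stability_index <- function(model) {
  A <- if (inherits(model, "mvar_model")) model$A else model
  if (length(dim(A)) == 2) A <- array(A, dim = c(dim(A), 1))
  ev <- eigen(companion_matrix(A), only.values = TRUE)$values
  log(max(Mod(ev)))
}

# Vieira-Morf (Morf-Vieira-Kailath / Nuttall-Strand family) lattice
# recursion on forward/backward prediction errors.  The partial correlation
# is normalized by the Cholesky factors of the recursively updated error
# covariances (the geometric-mean normalization that distinguishes this
# estimator from per-direction least squares), and the error covariances are
# themselves updated through the normalized coefficient:
#   P_f <- L_f (I - rho rho') L_f',   P_b <- L_b (I - rho' rho) L_b'.
# Returns the coefficient set and forward error covariance at every order up
# to p_max, so BIC selection costs a single pass.
vieira_morf_lattice <- function(x, p_max) {
  d <- nrow(x)
  n <- ncol(x)
  ef <- eb <- x
  r0 <- tcrossprod(x) / n
  pf <- pb <- r0
  A <- vector("list", 0)   # current forward coefficients A_1..A_m
  B <- vector("list", 0)   # backward coefficients
  per_order <- vector("list", p_max)
  eye <- diag(d)
  for (m in seq_len(p_max)) {
    idx_f <- (m + 1):n
    idx_b <- m:(n - 1)
    delta <- tcrossprod(ef[, idx_f, drop = FALSE],
                        eb[, idx_b, drop = FALSE]) / (n - m)
    lf <- t(safe_chol(pf))
    lb <- t(safe_chol(pb))
    rho <- forwardsolve(lf, t(forwardsolve(lb, t(delta))))
    # the normalized partial correlation has spectral norm <= 1 in exact
    # arithmetic; ill-conditioned inputs can push it over, so project back
    sv <- svd(rho)
    if (sv$d[1] > 1 - 1e-8) {
      rho <- sv$u %*% (pmin(sv$d, 1 - 1e-8) * t(sv$v))
    }
    kf <- t(backsolve(t(lb), t(lf %*% rho)))     # (lf rho) %*% lb^-1
    kb <- t(backsolve(t(lf), t(lb %*% t(rho))))  # (lb rho') %*% lf^-1
    A_new <- vector("list", m)
    B_new <- vector("list", m)
    A_new[[m]] <- kf
    B_new[[m]] <- kb
    if (m > 1) {
      for (i in seq_len(m - 1)) {
        A_new[[i]] <- A[[i]] - kf %*% B[[m - i]]
        B_new[[i]] <- B[[i]] - kb %*% A[[m - i]]
      }
    }
    ef_new <- ef
    eb_new <- eb
    ef_new[, idx_f] <- ef[, idx_f, drop = FALSE] - kf %*% eb[, idx_b, drop = FALSE]
    eb_new[, idx_f] <- eb[, idx_b, drop = FALSE] - kb %*% ef[, idx_f, drop = FALSE]
    ef <- ef_new
    eb <- eb_new
    A <- A_new
    B <- B_new
    pf <- lf %*% (eye - tcrossprod(rho)) %*% t(lf)
    pb <- lb %*% (eye - crossprod(rho)) %*% t(lb)
    per_order[[m]] <- list(A = A, sigma = pf)
  }
  per_order
}

# Cholesky with escalating ridge jitter: near-deterministic channels (e.g.
# noiseless rank-deficient projections) drive the recursive error
# covariances to the PSD boundary.
safe_chol <- function(s) {
  out <- tryCatch(chol(s), error = function(e) NULL)
  if (!is.null(out)) return(out)
  scale <- mean(diag(s))
  for (eps in 10^c(-12, -10, -8, -6)) {
    out <- tryCatch(chol(s + diag(eps * scale, nrow(s))),
                    error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  stop("singular error covariance in the lattice recursion: degenerate input")
}

ls_mvar <- function(x, p) {
  d <- nrow(x)
  n <- ncol(x)
  y <- x[, (p + 1):n, drop = FALSE]
  z <- do.call(rbind, lapply(seq_len(p), function(r) {
    x[, (p + 1 - r):(n - r), drop = FALSE]
  }))
  zz <- tcrossprod(z)
  a_flat <- tcrossprod(y, z) %*% solve(zz)
  res <- y - a_flat %*% z
  list(A = array(a_flat, dim = c(d, d, p)),
       sigma = tcrossprod(res) / (n - p))
}

coef_list_to_array <- function(A_list) {
  d <- nrow(A_list[[1]])
  array(unlist(A_list), dim = c(d, d, length(A_list)))
}

#' Fit an MVAR model
#'
#' The default estimator is the Vieira-Morf (Nuttall-Strand) lattice
#' recursion on forward and backward prediction errors, with the innovation
#' covariance taken from the final forward error covariance.  Ordinary least
#' squares (`method = "ls"`) is available as a reference estimator; the two
#' agree to O(1/sqrt(n)) on long stationary data.
#'
#' @param data `d` x `n_samples` matrix (channels in rows).  Channel means
#'   are removed before fitting.
#' @param order model order `p >= 1`.
#' @param sampling_rate sampling rate in Hz stored on the model.
#' @param method `"vm"` (Vieira-Morf, default) or `"ls"`.
#' @return An `mvar_model` with BIC filled in.
#' @export
fit_mvar <- function(data, order, sampling_rate = 1, method = c("vm", "ls")) {
  method <- match.arg(method)
  data <- as.matrix(data)
  d <- nrow(data)
  n <- ncol(data)
  stopifnot(order >= 1, n > order)
  if (n < 10 * d * order) {
    warning("n_samples < 10 * d * order; estimates may be unstable")
  }
  x <- data - rowMeans(data)
  fit <- if (method == "vm") {
    st <- vieira_morf_lattice(x, order)[[order]]
    list(A = coef_list_to_array(st$A), sigma = st$sigma)
  } else {
    ls_mvar(x, order)
  }
  mvar_model(fit$A, fit$sigma, sampling_rate,
             bic = mvar_bic(fit$sigma, d, order, n))
}

# n_eff * log det(Sigma) + (free AR parameters) * log(n_eff)
mvar_bic <- function(sigma, d, p, n) {
  n_eff <- n - p
  ld <- determinant(sigma, logarithm = TRUE)
  if (ld$sign <= 0) return(NA_real_)
  n_eff * as.numeric(ld$modulus) + p * d^2 * log(n_eff)
}

#' Select the MVAR model order by BIC
#'
#' Fits all orders `1..p_max` (one lattice pass for the Vieira-Morf method)
#' and returns the order minimizing
#' `n_eff * log det(Sigma_p) + p * d^2 * log(n_eff)` with
#' `n_eff = n_samples - p`.  Orders with non-finite BIC are excluded.
#'
#' @inheritParams fit_mvar
#' @param p_max largest candidate order.
#' @return A list with `p_opt`, `bic_curve` (length `p_max`, `NA` where
#'   excluded) and `model`, the refitted model at `p_opt`.
#' @export
select_order_bic <- function(data, p_max, sampling_rate = 1,
                             method = c("vm", "ls")) {
  method <- match.arg(method)
  data <- as.matrix(data)
  d <- nrow(data)
  n <- ncol(data)
  stopifnot(p_max >= 1, n > p_max)
  x <- data - rowMeans(data)
  fits <- if (method == "vm") {
    lapply(vieira_morf_lattice(x, p_max), function(st) {
      list(A = coef_list_to_array(st$A), sigma = st$sigma)
    })
  } else {
    lapply(seq_len(p_max), function(p) ls_mvar(x, p))
  }
  bic <- vapply(seq_len(p_max), function(p) {
    mvar_bic(fits[[p]]$sigma, d, p, n)
  }, numeric(1))
  if (all(!is.finite(bic))) stop("BIC non-finite at every order")
  p_opt <- which.min(replace(bic, !is.finite(bic), Inf))
  model <- mvar_model(fits[[p_opt]]$A, fits[[p_opt]]$sigma, sampling_rate,
                      bic = bic[p_opt])
  list(p_opt = p_opt, bic_curve = bic, model = model)
}

#' Back-project an MVAR model fitted in principal-component space
#'
#' Maps a model fitted on K principal-component scores back to the original
#' location space through the orthonormal loading matrix `L`:
#' `A_r -> L A_r t(L)` and `Sigma -> L Sigma t(L)` (the Moore-Penrose
#' back-projection; `t(L) L = I`).  The nonzero companion eigenvalues, and
#' hence the stability index, are preserved.
#'
#' @param model an `mvar_model` of dimension K.
#' @param reduction a `pc_reduction` from [reduce_dimensionality()] with K
#'   components.
#' @return An `mvar_model` of dimension `n_locations`.
#' @export
backproject_mvar <- function(model, reduction) {
  stopifnot(inherits(model, "mvar_model"), inherits(reduction, "pc_reduction"))
  L <- reduction$loadings
  if (ncol(L) != model$dimension) {
    stop("model dimension (", model$dimension,
         ") does not match number of components (", ncol(L), ")")
  }
  p <- model$order
  d_out <- nrow(L)
  A <- array(0, dim = c(d_out, d_out, p))
  for (r in seq_len(p)) A[, , r] <- L %*% model$A[, , r] %*% t(L)
  # the nonzero companion eigenvalues are invariant under the orthonormal
  # back-projection, so the stability index carries over unchanged
  mvar_model(A, L %*% model$sigma %*% t(L), model$sampling_rate,
             .stability = model$stability_index)
}
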