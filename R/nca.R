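#' NCA configuration
#'
#' @param sigma Kernel width of `kappa(z) = exp(-z / sigma)` applied to the
#'   weighted distance; 1 is appropriate for standardized features.
#' @param lambda_grid Candidate regularisation strengths, expressed in
#'   units of `1 / N_t` (`N_t` = training-set size); the absolute value used
#'   is `lambda_grid[i] / N_t`.
#' @param tau Relative selection-threshold tolerance: features with weight
#'   above `tau * max(w)` are kept.
#' @param folds Cross-validation folds for tuning lambda.
#' @param learning_rate Initial gradient-ascent step size.
#' @param max_iters Maximum ascent iterations.
#' @param grad_tolerance Stop when the largest gradient magnitude over
#'   active coordinates falls below this.
#' @param seed Seed for fold assignment.
#' @return An object of class `nca_config`.
#' @export
nca_config <- function(sigma = 1, lambda_grid = c(5, 25, 50, 100, 200),
                       tau = 0.02, folds = 5L, learning_rate = 0.05,
                       max_iters = 300L, grad_tolerance = 1e-4, seed = 1L) {
  if (tau <= 0) stop("tau must be > 0")
  if (any(lambda_grid < 0)) stop("all lambda values must be >= 0")
  if (folds < 2L) stop("folds must be >= 2")
  structure(list(sigma = sigma, lambda_grid = lambda_grid, tau = tau,
                 folds = as.integer(folds), learning_rate = learning_rate,
                 max_iters = as.integer(max_iters),
                 grad_tolerance = grad_tolerance, seed = as.integer(seed)),
            class = "nca_config")
}

#' Weighted L1 distance with squared feature weights
#'
#' `D_w(xi, xj) = sum_l w_l^2 * |xi_l - xj_l|`.
#'
#' @param xi,xj Feature vectors of equal length.
#' @param w Weight vector of the same length.
#' @return A scalar distance.
#' @export
weighted_distance <- function(xi, xj, w) {
  if (length(xi) != length(xj) || length(xi) != length(w))
    stop("xi, xj and w must have equal length")
  sum(w^2 * abs(xi - xj))
}

# Pairwise |x_il - x_jl| slabs, one N x N matrix per feature.
abs_diff_slabs <- function(X) {
  lapply(seq_len(ncol(X)), function(l) abs(outer(X[, l], X[, l], "-")))
}

neighbour_prob_core <- function(A, y, w, sigma) {
  N <- length(y)
  D <- matrix(0, N, N)
  for (l in seq_along(A)) D <- D + w[l]^2 * A[[l]]
  diag(D) <- Inf                      # p_ii = 0
  D0 <- apply(D, 1L, min)             # row-wise stabilisation
  K <- exp(-(D - D0) / sigma)
  K[!is.finite(K)] <- 0
  P <- K / rowSums(K)
  Y <- outer(y, y, "==") * 1
  diag(Y) <- 0
  p_i <- rowSums(P * Y)
  list(p_ij = P, p_i = p_i, Y = Y)
}

#' Soft nearest-neighbour reference probabilities
#'
#' Returns the matrix `p_ij` of probabilities that sample `i` picks sample
#' `j` as its reference point (kernelised weighted distance, rows sum to 1,
#' zero diagonal) and the vector `p_i` of leave-one-out probabilities of
#' correct classification.
#'
#' @param X N x d feature matrix (standardized).
#' @param y Class labels, length N.
#' @param w Feature weights, length d.
#' @param sigma Kernel width.
#' @return A list with `p_ij` (N x N) and `p_i` (length N).
#' @export
neighbour_probabilities <- function(X, y, w, sigma = 1) {
  if (nrow(X) < 2L) stop("need at least two samples")
  res <- neighbour_prob_core(abs_diff_slabs(as.matrix(X)), y, w, sigma)
  res[c("p_ij", "p_i")]
}

objective_core <- function(A, y, w, sigma, lambda) {
  np <- neighbour_prob_core(A, y, w, sigma)
  P <- np$p_ij; p_i <- np$p_i; Y <- np$Y
  PY <- P * Y
  grad <- numeric(length(A))
  for (l in seq_along(A)) {
    S <- rowSums(P * A[[l]])
    grad[l] <- (2 / sigma) * (sum(p_i * S) - sum(PY * A[[l]])) * w[l] -
      2 * lambda * w[l]
  }
  list(F = sum(p_i) - lambda * sum(w^2), grad = grad, p_i = p_i)
}

#' NCA objective and its analytic gradient
#'
#' `F(w) = sum_i p_i - lambda * sum_l w_l^2`, with the exact derivative
#' `dF/dw_l = (2/sigma) * sum_i (p_i * sum_k p_ik |x_il - x_kl| -
#' sum_j y_ij p_ij |x_il - x_jl|) * w_l - 2 lambda w_l`.
#'
#' @inheritParams neighbour_probabilities
#' @param lambda Regularisation strength.
#' @return A list with `F` (scalar) and `grad` (length d).
#' @export
objective_and_gradient <- function(X, y, w, sigma = 1, lambda = 0) {
  res <- objective_core(abs_diff_slabs(as.matrix(X)), y, w, sigma, lambda)
  res[c("F", "grad")]
}

#' Fit NCA feature weights by projected gradient ascent
#'
#' Maximises the regularised leave-one-out objective from the all-ones
#' start, projecting onto the non-negative orthant after every step, with
#' backtracking step halving so the objective trace is non-decreasing over
#' accepted steps.
#'
#' @inheritParams neighbour_probabilities
#' @param config An [nca_config()].
#' @param lambda Absolute regularisation strength (not grid units).
#' @return An object of class `nca_result`: `weights`, `objective_trace`,
#'   `lambda`, `sigma`, `threshold`, `selected` (indices with weight above
#'   the threshold), `converged`.
#' @export
fit_nca <- function(X, y, config = nca_config(), lambda = 1 / nrow(X)) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  A <- abs_diff_slabs(X)
  d <- ncol(X)
  w <- rep(1, d)
  lr <- config$learning_rate
  cur <- objective_core(A, y, w, config$sigma, lambda)
  trace <- cur$F
  converged <- FALSE
  for (it in seq_len(config$max_iters)) {
    g <- cur$grad
    active <- w > 0 | g > 0
    if (max(abs(g[active]), 0) < config$grad_tolerance) { converged <- TRUE; break }
    accepted <- FALSE
    for (bt in 1:30) {
      w_new <- pmax(w + lr * g, 0)
      nxt <- objective_core(A, y, w_new, config$sigma, lambda)
      if (nxt$F >= cur$F - 1e-12) { accepted <- TRUE; break }
      lr <- lr / 2
    }
    if (!accepted) break
    w <- w_new
    cur <- nxt
    trace <- c(trace, cur$F)
    lr <- min(lr * 1.2, 10 * config$learning_rate)
  }
  if (!converged && length(trace) > 1L &&
      abs(trace[length(trace)] - trace[length(trace) - 1L]) < 1e-10)
    converged <- TRUE
  if (!converged)
    warning("NCA gradient ascent did not converge in ", config$max_iters,
            " iterations")
  res <- list(weights = w, objective_trace = trace, lambda = lambda,
              sigma = config$sigma, threshold = config$tau * max(w),
              selected = select_features(w, config$tau, quiet = TRUE),
              converged = converged,
              feature_names = colnames(X))
  class(res) <- "nca_result"
  res
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> lambda=%.4g  T=%.4g  selected %d/%d features\n",
              x$lambda, x$threshold, length(x$selected), length(x$weights)))
  invisible(x)
}

#' Relative-threshold feature selection
#'
#' Keeps features whose weight exceeds `T = tau * max(w)`, preserving the
#' original order.
#'
#' @param w Weight vector or an `nca_result`.
#' @param tau Relative tolerance.
#' @param quiet Suppress the all-zero warning.
#' @return Integer indices of the selected features.
#' @export
select_features <- function(w, tau = 0.02, quiet = FALSE) {
  if (inherits(w, "nca_result")) w <- w$weights
  if (max(w) == 0) {
    if (!quiet) warning("all feature weights are zero; nothing selected")
    return(integer(0))
  }
  which(w > tau * max(w))
}

# 1-NN under the squared-weight L1 distance.
predict_1nn <- function(X_train, y_train, X_test, w) {
  w2 <- w^2
  apply(X_test, 1L, function(xt) {
    d <- colSums(w2 * abs(t(X_train) - xt))
    y_train[which.min(d)]
  })
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Tune the NCA regularisation strength by cross-validation
#'
#' Evaluates each candidate (in units of `1 / N_t`, `N_t` the fold's
#' training-set size) by the k-fold misclassification loss of the 1-NN
#' classifier under the learned weighted distance, and returns the
#' candidate minimising the mean loss (ties go to the smallest lambda).
#'
#' @inheritParams fit_nca
#' @return A list: `best_lambda` (grid units), `best_lambda_abs` (absolute,
#'   at `N_t = N`), `loss` (mean CV loss per candidate).
#' @export
tune_lambda <- function(X, y, config = nca_config()) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (N < config$folds) stop("fewer samples than folds")
  with_seed(config$seed, {
    fold <- stratified_folds(y, config$folds)
    loss <- matrix(NA_real_, config$folds, length(config$lambda_grid))
    for (f in seq_len(config$folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2L) next
      N_t <- sum(tr)
      for (g in seq_along(config$lambda_grid)) {
        fit <- fit_nca(X[tr, , drop = FALSE], y[tr], config,
                       lambda = config$lambda_grid[g] / N_t)
        pred <- predict_1nn(X[tr, , drop = FALSE], y[tr],
                            X[!tr, , drop = FALSE], fit$weights)
        loss[f, g] <- mean(pred != y[!tr])
      }
    }
    mean_loss <- colMeans(loss, na.rm = TRUE)
    best <- which(mean_loss == min(mean_loss))[1L]   # ties -> smallest lambda
    list(best_lambda = config$lambda_grid[best],
         best_lambda_abs = config$lambda_grid[best] / N,
         loss = mean_loss)
  })
}

#' Standardize, tune, fit and select in one call
#'
#' Convenience wrapper: z-scores the feature columns, tunes lambda by
#' cross-validation, refits on the full data at the tuned strength and
#' applies the relative-threshold selection.
#'
#' @inheritParams fit_nca
#' @param tune Tune lambda by CV; otherwise use `lambda` (default `1 / N`).
#' @return An `nca_result` with extra fields `center`, `scale`,
#'   `best_lambda` (grid units).
#' @export
run_nca_selection <- function(X, y, config = nca_config(), tune = TRUE,
                              lambda = NULL) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  if (tune) {
    tuned <- tune_lambda(Xs, y, config)
    lambda <- tuned$best_lambda_abs
    best <- tuned$best_lambda
  } else {
    if (is.null(lambda)) lambda <- 1 / nrow(X)
    best <- NA_real_
  }
  res <- fit_nca(Xs, y, config, lambda = lambda)
  res$selected <- select_features(res$weights, config$tau)
  res$center <- ctr
  res$scale <- scl
  res$best_lambda <- best
  res
}

#' Write the NCA weights report
#'
#' One row per feature: name, learned weight, selected flag, plus the
#' threshold, lambda and sigma used (bar-plot-ready).
#'
#' @param result An `nca_result`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_nca_report <- function(result, path) {
  nm <- result$feature_names
  if (is.null(nm)) nm <- paste0("f", seq_along(result$weights))
  df <- data.frame(feature = nm, weight = result$weights,
                   selected = seq_along(result$weights) %in% result$selected,
                   threshold = result$threshold, lambda = result$lambda,
                   sigma = result$sigma)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
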