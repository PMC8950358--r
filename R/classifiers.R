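#' Network architecture specification
#'
#' Describes a single-hidden-layer binary classifier in the naming
#' convention `"<kind> <inputs>-<hidden>-2"`. MLPs are trained by
#' quasi-Newton (BFGS) minimisation of the sum-of-squares or cross-entropy
#' error; RBF networks use Gaussian basis units with data-driven centers
#' ("RBFT"). The exponential output activation is implemented as exp units
#' renormalised across the two outputs, i.e. a softmax — this guarantees
#' valid probabilities.
#'
#' @param kind `"MLP"` or `"RBF"`.
#' @param n_hidden Hidden units.
#' @param hidden_activation `"logistic"` or `"linear"` for MLP; RBF is
#'   always `"gauss"`.
#' @param output_activation `"exponential"`, `"softmax"` or `"linear"`.
#' @param error_function `"SOS"` or `"entropy"` (entropy requires a
#'   softmax-family output).
#' @param max_iterations Optimizer iteration cap (MLP).
#' @param n_restarts Random restarts, best training loss kept (MLP).
#' @param ridge Ridge penalty for the RBF linear output solve (0 = exact
#'   interpolation when `n_hidden = n_train`).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(kind = c("MLP", "RBF"), n_hidden = 9L,
                         hidden_activation = NULL, output_activation = NULL,
                         error_function = NULL, max_iterations = 200L,
                         n_restarts = 5L, ridge = 1e-8) {
  kind <- match.arg(kind)
  if (kind == "RBF") {
    hidden_activation <- "gauss"
    if (is.null(output_activation)) output_activation <- "softmax"
    if (is.null(error_function))
      error_function <- if (output_activation == "linear") "SOS" else "entropy"
  } else {
    if (is.null(hidden_activation)) hidden_activation <- "logistic"
    if (is.null(output_activation)) output_activation <- "exponential"
    if (is.null(error_function)) error_function <- "SOS"
  }
  if (!hidden_activation %in% c("logistic", "linear", "gauss"))
    stop("unknown hidden activation")
  if (!output_activation %in% c("exponential", "softmax", "linear"))
    stop("unknown output activation")
  if (error_function == "entropy" && output_activation == "linear")
    stop("entropy error requires a softmax/exponential output")
  structure(list(kind = kind, n_hidden = as.integer(n_hidden),
                 n_outputs = 2L, hidden_activation = hidden_activation,
                 output_activation = output_activation,
                 error_function = error_function,
                 train_algorithm = if (kind == "MLP") "BFGS" else "RBFT",
                 max_iterations = as.integer(max_iterations),
                 n_restarts = as.integer(n_restarts), ridge = ridge),
            class = "network_spec")
}

network_name <- function(spec, n_inputs) {
  sprintf("%s %d-%d-%d", spec$kind, n_inputs, spec$n_hidden, spec$n_outputs)
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %s  h=%d  %s/%s  err=%s  alg=%s\n", x$kind,
              x$n_hidden, x$hidden_activation, x$output_activation,
              x$error_function, x$train_algorithm))
  invisible(x)
}

#' Stratified 70/15/15 train/test/validation split
#'
#' Training gets `round(0.7 n)`; the remainder is split
#' `floor(r / 2)` test, `r - floor(r / 2)` validation. With labels given the
#' split is stratified by class (largest-remainder allocation, repaired to
#' the exact overall sizes).
#'
#' @param n Number of samples.
#' @param seed RNG seed.
#' @param labels Optional class labels for stratification.
#' @return A list of disjoint index vectors `train`, `test`, `validation`
#'   whose union is `1:n`.
#' @export
split_dataset <- function(n, seed = 1L, labels = NULL) {
  n_train <- round(0.7 * n)
  r <- n - n_train
  n_test <- floor(r / 2)
  n_val <- r - n_test
  sizes <- c(train = n_train, test = n_test, validation = n_val)
  with_seed(seed, {
    if (is.null(labels)) {
      perm <- sample.int(n)
      out <- split(perm, rep(names(sizes), sizes))
    } else {
      labels <- as.character(labels)
      classes <- unique(labels)
      counts <- matrix(0L, length(classes), 3L,
                       dimnames = list(classes, names(sizes)))
      frac <- counts * 0
      for (ci in seq_along(classes)) {
        q <- sum(labels == classes[ci]) * sizes / n
        counts[ci, ] <- floor(q)
        frac[ci, ] <- q - floor(q)
      }
      # distribute leftovers by largest fractional remainder, respecting
      # both per-class totals and per-partition totals
      left_class <- vapply(classes, function(cl) sum(labels == cl),
                           integer(1)) - rowSums(counts)
      left_part <- sizes - colSums(counts)
      while (any(left_class > 0L)) {
        cand <- which(outer(left_class > 0L, left_part > 0L, "&"),
                      arr.ind = TRUE)
        pick <- cand[which.max(frac[cand]), , drop = FALSE]
        counts[pick[1L], pick[2L]] <- counts[pick[1L], pick[2L]] + 1L
        left_class[pick[1L]] <- left_class[pick[1L]] - 1L
        left_part[pick[2L]] <- left_part[pick[2L]] - 1L
        frac[pick[1L], pick[2L]] <- -1
      }
      out <- list(train = integer(0), test = integer(0),
                  validation = integer(0))
      for (ci in seq_along(classes)) {
        idx <- sample(which(labels == classes[ci]))
        splits <- rep(names(sizes), counts[ci, ])
        for (p in names(sizes))
          out[[p]] <- c(out[[p]], idx[splits == p])
      }
    }
    lapply(out[c("train", "test", "validation")], sort)
  })
}

logistic <- function(z) 1 / (1 + exp(-z))

softmax2 <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

mlp_unpack <- function(par, d, h) {
  k <- 2L
  i <- 0L
  W1 <- matrix(par[i + seq_len(d * h)], d, h); i <- i + d * h
  b1 <- par[i + seq_len(h)]; i <- i + h
  W2 <- matrix(par[i + seq_len(h * k)], h, k); i <- i + h * k
  b2 <- par[i + seq_len(k)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

mlp_forward <- function(p, X, spec) {
  Z1 <- sweep(X %*% p$W1, 2L, p$b1, "+")
  H <- if (spec$hidden_activation == "logistic") logistic(Z1) else Z1
  Z2 <- sweep(H %*% p$W2, 2L, p$b2, "+")
  P <- if (spec$output_activation == "linear") Z2 else softmax2(Z2)
  list(Z1 = Z1, H = H, Z2 = Z2, P = P)
}

mlp_loss_grad <- function(par, X, T1, spec) {
  d <- ncol(X); h <- spec$n_hidden; n <- nrow(X)
  p <- mlp_unpack(par, d, h)
  fw <- mlp_forward(p, X, spec)
  P <- fw$P
  if (spec$error_function == "entropy") {
    loss <- -sum(T1 * log(pmax(P, 1e-12))) / n
    dZ2 <- (P - T1) / n
  } else if (spec$output_activation == "linear") {
    loss <- sum((fw$Z2 - T1)^2) / n
    dZ2 <- 2 * (fw$Z2 - T1) / n
  } else {  # SOS on softmax probabilities
    loss <- sum((P - T1)^2) / n
    dP <- 2 * (P - T1) / n
    dZ2 <- P * (dP - rowSums(dP * P))
  }
  dW2 <- t(fw$H) %*% dZ2
  db2 <- colSums(dZ2)
  dH <- dZ2 %*% t(p$W2)
  dZ1 <- if (spec$hidden_activation == "logistic")
    dH * fw$H * (1 - fw$H) else dH
  dW1 <- t(X) %*% dZ1
  db1 <- colSums(dZ1)
  list(loss = loss, grad = c(dW1, db1, dW2, db2))
}

scale_params <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}

#' Train a multilayer perceptron
#'
#' Single hidden layer; weights fitted by BFGS quasi-Newton minimisation of
#' the configured error with analytic gradients, over several seeded random
#' restarts (best final training loss kept). Inputs are z-scored
#' internally; the scaling is folded into the model.
#'
#' @param features Numeric matrix / data.frame of inputs.
#' @param labels Two-class labels (factor or character).
#' @param spec A [network_spec()] with `kind = "MLP"`.
#' @param seed RNG seed for initialisation.
#' @return An object of class `c("vag_mlp", "vag_classifier")`.
#' @export
train_mlp <- function(features, labels, spec = network_spec("MLP"),
                      seed = 1L) {
  if (spec$kind != "MLP") stop("spec$kind must be 'MLP'")
  X <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("need exactly two classes in the training data")
  sc <- scale_params(X)
  Xs <- scale(X, sc$center, sc$scale)
  T1 <- cbind(as.integer(y == levels(y)[1L]), as.integer(y == levels(y)[2L]))
  d <- ncol(X); h <- spec$n_hidden
  npar <- d * h + h + h * 2L + 2L
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(spec$n_restarts)) {
      init <- runif(npar, -0.5, 0.5) / sqrt(d)
      fit <- optim(init,
                   fn = function(par) mlp_loss_grad(par, Xs, T1, spec)$loss,
                   gr = function(par) mlp_loss_grad(par, Xs, T1, spec)$grad,
                   method = "BFGS",
                   control = list(maxit = spec$max_iterations))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  })
  clf <- list(spec = spec, par = best$par, n_inputs = d,
              center = sc$center, scale = sc$scale, levels = levels(y),
              train_loss = best$value, seed = seed,
              name = network_name(spec, d))
  class(clf) <- c("vag_mlp", "vag_classifier")
  clf
}

#' @export
predict.vag_mlp <- function(object, newdata, ...) {
  X <- scale(as.matrix(newdata), object$center, object$scale)
  p <- mlp_unpack(object$par, object$n_inputs, object$spec$n_hidden)
  P <- mlp_forward(p, X, object$spec)$P
  if (object$spec$output_activation == "linear") {
    P <- pmin(pmax(P, 1e-9), 1)
    P <- P / rowSums(P)
  }
  colnames(P) <- object$levels
  P
}

#' Train a radial-basis-function network
#'
#' Gaussian hidden units with centers chosen from the training data
#' (k-means; the training points themselves when `n_hidden = n_train`),
#' widths set from the nearest-center spacing. The output layer is fitted
#' by (optionally ridge-regularised) least squares for a linear output, or
#' by binomial IRLS (maximum likelihood) for a softmax output.
#'
#' @inheritParams train_mlp
#' @param spec A [network_spec()] with `kind = "RBF"`.
#' @return An object of class `c("vag_rbf", "vag_classifier")`.
#' @export
train_rbf <- function(features, labels, spec = network_spec("RBF"),
                      seed = 1L) {
  if (spec$kind != "RBF") stop("spec$kind must be 'RBF'")
  X <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("need exactly two classes in the training data")
  n <- nrow(X)
  if (spec$n_hidden > n) stop("n_hidden must not exceed the training size")
  if (all(apply(X, 2L, function(col) length(unique(col)) == 1L)))
    stop("all features are constant; RBF centers/widths are undefined")
  sc <- scale_params(X)
  Xs <- scale(X, sc$center, sc$scale)
  centers <- with_seed(seed, {
    if (spec$n_hidden == n) Xs
    else kmeans(Xs, spec$n_hidden, nstart = 5L, iter.max = 100L)$centers
  })
  centers <- as.matrix(centers)
  cd <- as.matrix(stats::dist(centers))
  diag(cd) <- Inf
  widths <- apply(cd, 1L, min)
  fallback <- if (any(is.finite(widths) & widths > 0))
    stats::median(widths[is.finite(widths) & widths > 0]) else 1
  widths[!is.finite(widths) | widths == 0] <- fallback
  Phi <- rbf_design(Xs, centers, widths)
  if (spec$output_activation == "linear") {
    T1 <- cbind(as.integer(y == levels(y)[1L]),
                as.integer(y == levels(y)[2L]))
    if (spec$ridge > 0) {
      G <- crossprod(Phi) + spec$ridge * diag(ncol(Phi))
      beta <- solve(G, crossprod(Phi, T1))
    } else {
      beta <- qr.coef(qr(Phi), T1)
      beta[is.na(beta)] <- 0
    }
  } else {
    y01 <- as.integer(y == levels(y)[2L])
    fit <- suppressWarnings(glm.fit(Phi, y01, family = binomial()))
    beta <- coef(fit)
    beta[is.na(beta)] <- 0
  }
  clf <- list(spec = spec, centers = centers, widths = widths, beta = beta,
              n_inputs = ncol(X), center = sc$center, scale = sc$scale,
              levels = levels(y), seed = seed,
              name = network_name(spec, ncol(X)))
  class(clf) <- c("vag_rbf", "vag_classifier")
  clf
}

rbf_design <- function(Xs, centers, widths) {
  n <- nrow(Xs)
  Phi <- matrix(0, n, nrow(centers))
  for (j in seq_len(nrow(centers))) {
    d2 <- rowSums(sweep(Xs, 2L, centers[j, ], "-")^2)
    Phi[, j] <- exp(-d2 / (2 * widths[j]^2))
  }
  cbind(1, Phi)
}

#' @export
predict.vag_rbf <- function(object, newdata, ...) {
  Xs <- scale(as.matrix(newdata), object$center, object$scale)
  Phi <- rbf_design(Xs, object$centers, object$widths)
  if (object$spec$output_activation == "linear") {
    P <- Phi %*% object$beta
    P <- pmin(pmax(P, 1e-9), 1)
    P <- P / rowSums(P)
  } else {
    p2 <- logistic(as.numeric(Phi %*% object$beta))
    P <- cbind(1 - p2, p2)
  }
  colnames(P) <- object$levels
  P
}

#' @export
print.vag_classifier <- function(x, ...) {
  cat(sprintf("<%s> classes %s/%s\n", x$name, x$levels[1L], x$levels[2L]))
  invisible(x)
}

classifier_accuracy <- function(clf, X, y) {
  if (length(y) == 0L) return(NA_real_)
  P <- predict(clf, X)
  pred <- clf$levels[max.col(P, ties.method = "first")]
  mean(pred == as.character(y))
}

#' Automatic network search
#'
#' Trains every candidate specification on the training partition and keeps,
#' per network kind, the candidate with the highest validation accuracy
#' (ties go to fewer hidden units). Returns a summary table in the
#' `"<kind> <in>-<hidden>-<out>"` naming convention with learning, testing
#' and validation quality (percent correct).
#'
#' @param features Input matrix.
#' @param labels Two-class labels.
#' @param grid List of [network_spec()] candidates.
#' @param seed Seed controlling the split and training initialisation.
#' @param split Optional precomputed [split_dataset()] result.
#' @return A list: `best` (named list by kind of trained classifiers),
#'   `summary` (data.frame), `split`.
#' @export
auto_search <- function(features, labels, grid = default_network_grid(),
                        seed = 1L, split = NULL) {
  if (length(grid) == 0L) stop("candidate grid is empty")
  X <- as.matrix(features)
  y <- factor(labels)
  if (is.null(split)) split <- split_dataset(nrow(X), seed, labels = y)
  tr <- split$train; te <- split$test; va <- split$validation
  rows <- list(); fits <- list()
  for (i in seq_along(grid)) {
    spec <- grid[[i]]
    fit <- if (spec$kind == "MLP")
      train_mlp(X[tr, , drop = FALSE], y[tr], spec, seed = seed + i)
    else
      train_rbf(X[tr, , drop = FALSE], y[tr], spec, seed = seed + i)
    fits[[i]] <- fit
    rows[[i]] <- data.frame(
      network_name = fit$name, kind = spec$kind, n_hidden = spec$n_hidden,
      quality_learning = round(100 * classifier_accuracy(fit, X[tr, , drop = FALSE], y[tr]), 2),
      quality_testing = round(100 * classifier_accuracy(fit, X[te, , drop = FALSE], y[te]), 2),
      quality_validation = round(100 * classifier_accuracy(fit, X[va, , drop = FALSE], y[va]), 2),
      learning_algorithm = spec$train_algorithm,
      error_function = spec$error_function,
      activation_hidden = spec$hidden_activation,
      activation_output = spec$output_activation,
      stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  best <- list()
  for (kind in unique(summary$kind)) {
    sub <- which(summary$kind == kind)
    ord <- sub[order(-summary$quality_validation[sub], summary$n_hidden[sub])]
    best[[kind]] <- fits[[ord[1L]]]
  }
  list(best = best, summary = summary, split = split)
}

#' Default candidate grid for the automatic search
#'
#' @param mlp_hidden,rbf_hidden Hidden-unit counts to try per kind.
#' @return A list of [network_spec()] objects.
#' @export
default_network_grid <- function(mlp_hidden = c(5L, 9L, 12L),
                                 rbf_hidden = c(5L, 10L, 20L)) {
  c(lapply(mlp_hidden, function(h) network_spec("MLP", h)),
    lapply(rbf_hidden, function(h) network_spec("RBF", h)))
}

#' Serialize a trained classifier to JSON
#'
#' @param clf A `vag_classifier`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
save_classifier <- function(clf, path) {
  obj <- unclass(clf)
  obj$spec <- unclass(obj$spec)
  obj$class <- class(clf)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a classifier saved by [save_classifier()]
#'
#' @param path JSON file path.
#' @return The restored `vag_classifier`.
#' @export
load_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$class
  obj$class <- NULL
  obj$spec <- structure(obj$spec, class = "network_spec")
  if ("vag_rbf" %in% cls) {
    obj$centers <- as.matrix(obj$centers)
    if (obj$spec$output_activation == "linear")
      obj$beta <- as.matrix(obj$beta)
  }
  structure(obj, class = cls)
}
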