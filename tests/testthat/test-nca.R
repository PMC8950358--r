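test_that("weighted distance follows the squared-weight L1 form", {
  expect_equal(weighted_distance(c(1, 0), c(0, 0), c(2, 5)), 4)
  expect_equal(weighted_distance(c(3, 7), c(3, 7), c(1, 9)), 0)
  expect_equal(weighted_distance(c(1, 2), c(5, -2), c(0, 0)), 0)
  expect_error(weighted_distance(1:3, 1:2, 1:3), "equal length")
})

test_that("reference probabilities are row-stochastic with known limits", {
  # two points: each picks the other with probability one
  np2 <- neighbour_probabilities(matrix(c(0, 3), 2, 1), c(1, 2), w = 2)
  expect_equal(np2$p_ij[1, 2], 1)
  expect_equal(np2$p_ij[2, 1], 1)

  # zero weights: uniform off-diagonal, p_i = (n_class - 1)/(N - 1)
  set.seed(2)
  X <- matrix(rnorm(30), 10, 3)
  y <- rep(c(1, 2), c(6, 4))
  np <- neighbour_probabilities(X, y, w = c(0, 0, 0))
  expect_equal(np$p_ij[1, 2], 1 / 9)
  expect_equal(np$p_i, ifelse(y == 1, 5 / 9, 3 / 9))

  # three printed points, hand evaluation of the kernel ratio
  np3 <- neighbour_probabilities(matrix(c(0, 0, 10), 3, 1), c(1, 1, 2),
                                 w = 1, sigma = 1)
  expect_equal(np3$p_i[1], 1 / (1 + exp(-10)), tolerance = 1e-12)

  # general case: rows sum to one, p_i within [0, 1]
  w <- runif(3)
  npg <- neighbour_probabilities(X, y, w)
  expect_equal(unname(rowSums(npg$p_ij)), rep(1, 10))
  expect_true(all(npg$p_i >= 0 & npg$p_i <= 1))
  expect_true(all(diag(npg$p_ij) == 0))
})

test_that("analytic gradient matches central finite differences", {
  set.seed(11)
  for (rep in 1:5) {
    X <- matrix(rnorm(40), 10, 4)
    y <- sample(rep(1:2, 5))
    w <- runif(4, 0.2, 2)
    lambda <- runif(1, 0, 0.5)
    og <- objective_and_gradient(X, y, w, sigma = 1, lambda = lambda)
    h <- 1e-6
    fd <- sapply(1:4, function(l) {
      wp <- w; wm <- w
      wp[l] <- wp[l] + h; wm[l] <- wm[l] - h
      (objective_and_gradient(X, y, wp, 1, lambda)$F -
         objective_and_gradient(X, y, wm, 1, lambda)$F) / (2 * h)
    })
    expect_lt(max(abs(og$grad - fd) / pmax(abs(fd), 1e-3)), 1e-5)
  }
})

test_that("objective limits: w = 0 value, upper bound, zero penalty gradient", {
  set.seed(3)
  X <- matrix(rnorm(24), 12, 2)
  y <- rep(1:2, 6)
  og0 <- objective_and_gradient(X, y, c(0, 0), sigma = 1, lambda = 0.7)
  expect_equal(og0$F, sum((table(y)[as.character(y)] - 1) / (12 - 1)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # separated classes with large weights: F approaches its bound N
  Xs <- matrix(c(rnorm(6, 0, 0.01), rnorm(6, 50, 0.01)), ncol = 1)
  ys <- rep(1:2, each = 6)
  og <- objective_and_gradient(scale(Xs), ys, w = 20, lambda = 0)
  expect_gt(og$F, 12 - 1e-6)
  expect_lte(og$F, 12)
})

test_that("the objective is invariant to sample and feature permutations", {
  set.seed(9)
  X <- matrix(rnorm(60), 15, 4)
  y <- sample(rep(1:2, c(8, 7)))
  w <- runif(4)
  f0 <- objective_and_gradient(X, y, w, lambda = 0.1)$F
  p <- sample(15)
  expect_equal(objective_and_gradient(X[p, ], y[p], w, lambda = 0.1)$F, f0,
               tolerance = 1e-12)
  q <- sample(4)
  expect_equal(objective_and_gradient(X[, q], y, w[q], lambda = 0.1)$F, f0,
               tolerance = 1e-12)
})

test_that("gradient ascent keeps the objective trace non-decreasing", {
  dat <- make_informative_noise(1)
  fit <- suppressWarnings(fit_nca(scale(dat$X), dat$y, nca_config(),
                                  lambda = 0.5))
  expect_true(all(diff(fit$objective_trace) >= -1e-9))
  expect_true(all(fit$weights >= 0))
})

test_that("informative feature is kept and noise rejected across seeds", {
  hits <- sapply(1:25, function(s) {
    dat <- make_informative_noise(s)
    fit <- suppressWarnings(fit_nca(scale(dat$X), dat$y, nca_config(),
                                    lambda = 2))
    w <- fit$weights
    (w[1] > fit$threshold) && all(w[2:4] <= fit$threshold)
  })
  expect_gte(mean(hits), 0.95)
})

test_that("extreme regularisation drives every weight to zero", {
  dat <- make_informative_noise(4)
  fit <- suppressWarnings(fit_nca(scale(dat$X), dat$y, nca_config(),
                                  lambda = 100))
  expect_lt(max(fit$weights), 1e-3)
})

test_that("duplicated feature columns receive equal weights", {
  set.seed(6)
  x1 <- c(rnorm(40, 0), rnorm(40, 3))
  X <- cbind(x1, x1, rnorm(80))
  y <- rep(1:2, each = 40)
  fit <- suppressWarnings(fit_nca(scale(X), y, nca_config(), lambda = 0.5))
  expect_lt(abs(fit$weights[1] - fit$weights[2]), 1e-3)
})

test_that("lambda tuning behaves as an argmin with sensible edge cases", {
  dat <- make_informative_noise(12)
  Xs <- scale(dat$X)
  one <- tune_lambda(Xs, dat$y, nca_config(lambda_grid = 7, folds = 3))
  expect_identical(one$best_lambda, 7)

  cfg <- nca_config(lambda_grid = c(25, 200), folds = 3, max_iters = 150)
  tuned <- tune_lambda(Xs, dat$y, cfg)
  expect_lte(min(tuned$loss), tuned$loss[length(tuned$loss)])

  expect_error(tune_lambda(Xs[1:3, ], dat$y[1:3],
                           nca_config(folds = 5)), "fewer samples")
})

test_that("permuted labels give chance-level tuned CV loss", {
  dat <- make_informative_noise(20)
  set.seed(20)
  y_perm <- sample(dat$y)
  cfg <- nca_config(lambda_grid = c(25, 100), folds = 4, max_iters = 100)
  tuned <- suppressWarnings(tune_lambda(scale(dat$X), y_perm, cfg))
  expect_lt(abs(min(tuned$loss) - 0.5), 0.1 + 1e-9)
})

test_that("relative-threshold selection follows T = tau * max(w)", {
  expect_identical(select_features(c(1, 0.5, 0.01), tau = 0.02), c(1L, 2L))
  expect_identical(select_features(rep(0.3, 5), tau = 0.02), 1:5)
  expect_warning(sel <- select_features(rep(0, 4)), "zero")
  expect_identical(sel, integer(0))
})
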