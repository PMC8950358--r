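test_that("70/15/15 split sizes, determinism and stratification", {
  sp <- split_dataset(1000, 1)
  expect_identical(lengths(sp), c(train = 700L, test = 150L,
                                  validation = 150L))
  expect_identical(sort(unlist(sp, use.names = FALSE)), 1:1000)

  sp10 <- split_dataset(10, 2)
  expect_identical(lengths(sp10), c(train = 7L, test = 1L, validation = 2L))

  expect_identical(split_dataset(137, 9), split_dataset(137, 9))

  y <- rep(c("HC", "OA"), c(600, 400))
  sps <- split_dataset(1000, 5, labels = y)
  expect_identical(lengths(sps), c(train = 700L, test = 150L,
                                   validation = 150L))
  expect_identical(sort(unlist(sps, use.names = FALSE)), 1:1000)
  # class balance preserved in each partition
  for (p in sps) expect_lt(abs(mean(y[p] == "OA") - 0.4), 0.02)
})

test_that("MLP fits separable blobs perfectly and XOR nonlinearly", {
  blobs <- make_blobs(100, gap = 5, seed = 1)
  clf <- train_mlp(blobs$X, blobs$y, network_spec("MLP", 5), seed = 2)
  P <- predict(clf, blobs$X)
  expect_equal(rowSums(P), rep(1, 200), tolerance = 1e-9)
  expect_equal(mean(clf$levels[max.col(P)] == blobs$y), 1)

  xor <- make_xor(200, seed = 2)
  clfx <- train_mlp(xor$X, xor$y, network_spec("MLP", 4), seed = 3)
  acc <- mean(clfx$levels[max.col(predict(clfx, xor$X))] == xor$y)
  expect_gte(acc, 0.95)

  expect_error(train_mlp(blobs$X, rep("HC", 200)), "two classes")
})

test_that("MLP on permuted labels scores at chance on held-out data", {
  accs <- sapply(1:3, function(s) {
    blobs <- make_blobs(200, gap = 5, seed = s)
    set.seed(s)
    y_perm <- sample(blobs$y)
    sp <- split_dataset(400, s, labels = y_perm)
    clf <- train_mlp(blobs$X[sp$train, ], y_perm[sp$train],
                     network_spec("MLP", 5), seed = s)
    P <- predict(clf, blobs$X[sp$validation, ])
    mean(clf$levels[max.col(P)] == y_perm[sp$validation])
  })
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("RBF separates blobs and interpolates at full capacity", {
  blobs <- make_blobs(60, gap = 5, seed = 4)
  sp <- split_dataset(120, 4, labels = blobs$y)
  clf <- train_rbf(blobs$X[sp$train, ], blobs$y[sp$train],
                   network_spec("RBF", 4), seed = 5)
  P <- predict(clf, blobs$X[sp$test, ])
  expect_gte(mean(clf$levels[max.col(P)] == blobs$y[sp$test]), 0.95)
  expect_equal(rowSums(P), rep(1, length(sp$test)), tolerance = 1e-9)

  set.seed(6)
  Xi <- matrix(rnorm(40), 20, 2)
  yi <- rep(c("A", "B"), 10)
  clfi <- train_rbf(Xi, yi, network_spec("RBF", 20,
                                         output_activation = "linear",
                                         ridge = 0), seed = 6)
  Ti <- cbind(yi == "A", yi == "B") * 1
  expect_lt(sum((predict(clfi, Xi) - Ti)^2), 1e-8)

  expect_error(train_rbf(matrix(1, 10, 3), rep(c("A", "B"), 5),
                         network_spec("RBF", 3)), "constant")
  expect_error(train_rbf(Xi, yi, network_spec("RBF", 50)), "n_hidden")
})

test_that("predictions are invariant to affine rescaling of the inputs", {
  blobs <- make_blobs(50, gap = 4, seed = 7)
  clf1 <- train_mlp(blobs$X, blobs$y, network_spec("MLP", 3), seed = 8)
  X2 <- sweep(blobs$X * 100, 2, c(3, -7), "+")
  clf2 <- train_mlp(X2, blobs$y, network_spec("MLP", 3), seed = 8)
  expect_equal(predict(clf1, blobs$X), predict(clf2, X2), tolerance = 1e-6)
})

test_that("the automatic search picks capacity where it is needed", {
  xor <- make_xor(240, seed = 9)
  grid <- list(network_spec("MLP", 1), network_spec("MLP", 6))
  out <- auto_search(xor$X, xor$y, grid, seed = 10)
  expect_identical(out$best$MLP$spec$n_hidden, 6L)
  expect_true(all(grepl("^MLP 2-\\d+-2$", out$summary$network_name)))

  single <- auto_search(xor$X, xor$y, list(network_spec("MLP", 3)),
                        seed = 11)
  expect_identical(single$best$MLP$spec$n_hidden, 3L)
  expect_error(auto_search(xor$X, xor$y, list(), seed = 1), "empty")
})

test_that("network naming and spec invariants match the reporting shape", {
  sp <- network_spec("RBF", 43)
  expect_identical(sp$hidden_activation, "gauss")
  expect_identical(sp$n_outputs, 2L)
  expect_identical(vagdx:::network_name(sp, 13), "RBF 13-43-2")
  expect_error(network_spec("MLP", 5, output_activation = "linear",
                            error_function = "entropy"), "entropy")
})

test_that("variant input assembly concatenates demographics and measures", {
  cfg <- fast_sim(n_hc = 2L, n_oa = 2L, seed = 13)
  ds <- generate_dataset(cfg)
  tab <- build_feature_table(ds, emd_cfg = NULL)

  one <- assemble_variant_inputs(tab, "CKC", selected = 1:7)
  expect_identical(ncol(one$X), 10L)        # 3 demographics + 7 measures
  expect_identical(colnames(one$X)[1:3], c("age", "sex", "bmi"))

  both <- assemble_variant_inputs(tab, c("CKC", "OKC"), selected = 1:24)
  expect_identical(ncol(both$X), 27L)       # 3 + 12 per chain
  expect_true(any(grepl("^ckc_", colnames(both$X))) &&
                any(grepl("^okc_", colnames(both$X))))

  expect_warning(none <- assemble_variant_inputs(tab, "CKC",
                                                 selected = integer(0)),
                 "demographics-only")
  expect_identical(ncol(none$X), 3L)
  expect_error(assemble_variant_inputs(tab, "CKC", selected = 99),
               "out of range")
})

test_that("classifier JSON round trip reproduces predictions", {
  blobs <- make_blobs(40, gap = 4, seed = 14)
  path <- withr::local_tempfile(fileext = ".json")
  clf <- train_mlp(blobs$X, blobs$y, network_spec("MLP", 3), seed = 15)
  save_classifier(clf, path)
  back <- load_classifier(path)
  expect_equal(predict(back, blobs$X), predict(clf, blobs$X),
               tolerance = 1e-12)

  clfr <- train_rbf(blobs$X, blobs$y, network_spec("RBF", 5), seed = 16)
  save_classifier(clfr, path)
  backr <- load_classifier(path)
  expect_equal(predict(backr, blobs$X), predict(clfr, blobs$X),
               tolerance = 1e-12)
})

test_that("MLP tends to match or beat RBF on default-effect cohorts", {
  accs <- t(sapply(1:20, function(s) {
    cfg <- fast_sim(n_hc = 6L, n_oa = 6L, seed = 100 + s)
    ds <- generate_dataset(cfg)
    ds$recordings <- Filter(function(r) r$chain == "CKC", ds$recordings)
    tab <- build_feature_table(ds, emd_cfg = NULL)
    vfm <- variant_feature_matrix(tab, "CKC")
    X <- cbind(as.matrix(vfm$demo), vfm$signal)
    sp <- split_dataset(nrow(X), s, labels = vfm$y)
    tr <- c(sp$train, sp$validation)
    mlp <- train_mlp(X[tr, ], vfm$y[tr], network_spec("MLP", 5), seed = s)
    rbf <- train_rbf(X[tr, ], vfm$y[tr], network_spec("RBF", 5), seed = s)
    c(mlp = mean(mlp$levels[max.col(predict(mlp, X[sp$test, ]))] ==
                   vfm$y[sp$test]),
      rbf = mean(rbf$levels[max.col(predict(rbf, X[sp$test, ]))] ==
                   vfm$y[sp$test]))
  }))
  expect_gte(mean(accs[, "mlp"]), mean(accs[, "rbf"]) - 0.05)
})
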