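test_that("envelope mean of symmetric oscillations is near zero", {
  t <- seq(0, 10, length.out = 4000)
  x <- sin(2 * pi * 3 * t)
  m <- sift_envelope_mean(x)
  interior <- 200:3800
  expect_lt(max(abs(m[interior])), 0.05)

  m2 <- sift_envelope_mean(x + 2.5)
  expect_lt(max(abs(m2[interior] - 2.5)), 0.05)

  tri <- 2 * abs((t * 3) %% 1 - 0.5) - 0.5   # symmetric triangle wave
  m3 <- sift_envelope_mean(tri)
  expect_lt(max(abs(m3[interior])), 0.05)

  expect_error(sift_envelope_mean(seq(0, 1, length.out = 50)),
               class = "vag_not_siftable")
})

test_that("EMD returns no IMFs for monotonic input and rejects bad input", {
  ramp <- seq(0, 5, length.out = 200)
  d <- emd(ramp, emd_config())
  expect_identical(d$n_imfs, 0L)
  expect_equal(d$residual, ramp, tolerance = 1e-14)
  expect_error(emd(c(ramp[1:50], NA)), "finite")
  expect_error(emd(1:10), "16 samples")
})

test_that("EMD decompositions always reconstruct the input", {
  set.seed(10)
  t <- seq(0, 2, length.out = 1500)
  signals <- list(
    sin(2 * pi * 5 * t) + sin(2 * pi * 50 * t),
    cumsum(rnorm(1500)),
    rnorm(1500),
    sin(2 * pi * 3 * t) + 0.5 * t
  )
  for (x in signals) {
    d <- emd(x, emd_config())
    recon <- rowSums(cbind(d$imfs, d$residual))
    expect_lt(max(abs(recon - x)), 1e-10 * max(abs(x)))
  }
})

test_that("well-separated tones split into frequency-ordered IMFs", {
  t <- seq(0, 2, length.out = 4096)
  x <- sin(2 * pi * 5 * t) + sin(2 * pi * 50 * t)
  d <- emd(x, emd_config())
  expect_gte(d$n_imfs, 2L)
  expect_gt(abs(cor(d$imfs[, 1], sin(2 * pi * 50 * t))), 0.95)
  zc_rate <- apply(d$imfs, 2, ref_zero_crossings)
  expect_true(all(diff(zc_rate) <= 0))
  # each accepted IMF satisfies the extrema/zero-crossing criterion
  for (j in seq_len(d$n_imfs)) {
    ex <- ref_extrema(d$imfs[, j])
    n_ext <- length(ex$maxima) + length(ex$minima)
    expect_lte(abs(n_ext - ref_zero_crossings(d$imfs[, j])), 1)
  }
})

test_that("sifting matches the independently coded reference loop", {
  t <- seq(0, 2, length.out = 1024)
  x <- sin(2 * pi * 5 * t) + 0.7 * sin(2 * pi * 40 * t)
  d <- emd(x, emd_config())
  r <- ref_emd(x)
  expect_identical(d$n_imfs, ncol(r$imfs))
  expect_lt(max(abs(d$imfs - r$imfs)), 1e-8)
  expect_lt(max(abs(d$residual - r$residual)), 1e-8)

  set.seed(3)
  xr <- cumsum(rnorm(400))
  d2 <- emd(xr, emd_config())
  r2 <- ref_emd(xr)
  expect_lt(max(abs(d2$residual - r2$residual)), 1e-8)
})

test_that("EEMD with zero noise reduces exactly to EMD", {
  set.seed(4)
  x <- sin(seq(0, 20, length.out = 600)) + rnorm(600, 0, 0.1)
  plain <- emd(x, emd_config())
  ens <- eemd(x, emd_config(noise_std_fraction = 0, ensemble_size = 25))
  expect_identical(ens$imfs, plain$imfs)
  expect_identical(ens$residual, plain$residual)
})

test_that("EEMD reconstruction error shrinks as the ensemble grows", {
  set.seed(5)
  t <- seq(0, 1, length.out = 512)
  x <- sin(2 * pi * 8 * t)
  err <- sapply(c(4, 64), function(N) {
    d <- eemd(x, emd_config(ensemble_size = N, noise_std_fraction = 0.2,
                            seed = 7))
    max(abs(rowSums(cbind(d$imfs, d$residual)) - x))
  })
  expect_lt(err[2], err[1])
})

test_that("ensemble averaging reduces mode mixing for tone plus impulses", {
  t <- seq(0, 2, length.out = 2048)
  tone <- sin(2 * pi * 12 * t)
  x <- tone
  x[seq(100, 1948, by = 264)] <- x[seq(100, 1948, by = 264)] + 1.5
  leakage <- function(dec) 1 - max(abs(cor(dec$imfs, tone)))
  plain <- emd(x, emd_config())
  ens <- eemd(x, emd_config(ensemble_size = 100, noise_std_fraction = 0.2,
                            seed = 2))
  expect_lt(leakage(ens), leakage(plain))
})

test_that("trend removal cancels drift while preserving oscillation", {
  n <- 600
  t <- seq(0, 3, length.out = n)
  zero_noise <- emd_config(noise_std_fraction = 0, ensemble_size = 1)

  ramp <- 2 * t
  out <- detrend_and_clean(ramp, zero_noise)
  expect_lt(max(abs(out)), 1e-6 * max(abs(ramp)))

  x <- sin(2 * pi * 6 * t) + 1.5 * t
  cleaned <- detrend_and_clean(x, emd_config(ensemble_size = 20, seed = 3))
  expect_gt(cor(cleaned, sin(2 * pi * 6 * t)), 0.99)
  slope_in <- coef(lm(x ~ t))[2]
  slope_out <- coef(lm(cleaned ~ t))[2]
  expect_lt(abs(slope_out), abs(slope_in) / 10)

  drift_free <- sin(2 * pi * 6 * t)
  out2 <- detrend_and_clean(drift_free, zero_noise)
  expect_gt(cor(out2, drift_free), 0.999)
  expect_error(detrend_and_clean(x, zero_noise, drop_noise_imfs = 50),
               "drop_noise_imfs")
})

test_that("normalization scales to unit peak and fixes the zero signal", {
  expect_equal(normalize_signal(c(2, -4)), c(0.5, -1))
  expect_identical(normalize_signal(numeric(5)), numeric(5))
  set.seed(1)
  x <- rnorm(100)
  expect_equal(max(abs(normalize_signal(x))), 1)
})

test_that("motion segmentation finds each flexion-extension cycle", {
  flat <- generate_encoder_trace("OKC", 1, 10, 2, 0.5)
  flat$angle[] <- 45
  expect_identical(nrow(detect_motion_segments(flat, 4096)), 0L)

  one <- generate_encoder_trace("OKC", 1, 10, 2, 0.5)
  seg <- detect_motion_segments(one, 4096, min_slope = 5, pad = 0.1)
  expect_identical(nrow(seg), 1L)
  # the cycle occupies [0.5, 2.5] s; endpoints within pad + one encoder tick
  expect_lt(abs(seg$start_s - 0.5), 0.25)
  expect_lt(abs(seg$end_s - 2.5), 0.25)

  four <- generate_encoder_trace("CKC", 4, 10, 2, 1)
  seg4 <- detect_motion_segments(four, 4096)
  expect_identical(nrow(seg4), 4L)
  expect_true(all(diff(seg4$start) > 0))
  expect_true(all(seg4$end[-4] <= seg4$start[-1]))
  expect_error(detect_motion_segments(structure(list(time = numeric(0)),
                                                class = "vag_encoder"),
                                      4096), "empty")
})
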