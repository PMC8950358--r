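# Independent reference implementations used as oracles. These mirror the
# documented algorithms with plain R (stats::splinefun etc.) and explicit
# loops; they are deliberately slow and kept free of package internals.

ref_extrema <- function(x) {
  n <- length(x)
  i <- 2:(n - 1)
  list(maxima = i[x[i] > x[i - 1] & x[i] > x[i + 1]],
       minima = i[x[i] < x[i - 1] & x[i] < x[i + 1]])
}

ref_envelope <- function(x, idx) {
  n <- length(x)
  pos <- idx - 1                      # 0-based positions as in the package
  left <- head(pos[pos > 0], 2)
  right <- tail(pos[pos < n - 1], 2)
  xs <- c(rev(-left), pos, 2 * (n - 1) - rev(right))
  ys <- c(x[rev(head(idx[pos > 0], 2))], x[idx],
          x[rev(tail(idx[pos < n - 1], 2))])
  if (length(xs) == 2) {
    slope <- diff(ys) / diff(xs)
    return(ys[1] + slope * ((0:(n - 1)) - xs[1]))
  }
  f <- stats::splinefun(xs, ys, method = "natural")
  f(0:(n - 1))
}

ref_envelope_mean <- function(x) {
  ex <- ref_extrema(x)
  if (length(ex$maxima) < 2 || length(ex$minima) < 2) return(NULL)
  (ref_envelope(x, ex$maxima) + ref_envelope(x, ex$minima)) / 2
}

ref_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  sum(diff(s) != 0)
}

ref_emd <- function(x, max_imf = 12, sd_tol = 0.2, max_sift = 100) {
  h <- as.numeric(x)
  imfs <- list()
  while (length(imfs) < max_imf) {
    ex <- ref_extrema(h)
    if (length(ex$maxima) < 2 || length(ex$minima) < 2) break
    d <- h
    accepted <- FALSE
    for (it in seq_len(max_sift)) {
      m <- ref_envelope_mean(d)
      if (is.null(m)) { accepted <- it > 1; break }
      sd_crit <- sum(m^2) / sum(d^2)
      d <- d - m
      accepted <- TRUE
      if (is.finite(sd_crit) && sd_crit < sd_tol) {
        ex2 <- ref_extrema(d)
        n_ext <- length(ex2$maxima) + length(ex2$minima)
        if (abs(n_ext - ref_zero_crossings(d)) <= 1) break
      }
    }
    if (!accepted) break
    imfs[[length(imfs) + 1]] <- d
    h <- h - d
  }
  list(imfs = if (length(imfs)) do.call(cbind, imfs) else
         matrix(0, length(x), 0),
       residual = h)
}

# Brute-force state indicators with explicit loops (no vectorised reuse).
ref_features <- function(x) {
  n <- length(x)
  mv <- 0; for (v in x) mv <- mv + v; mv <- mv / n
  sa <- 0; for (v in x) sa <- sa + abs(v); sa <- sa / n
  ss <- 0; for (v in x) ss <- ss + v^2
  rms <- sqrt(ss / n)
  pv <- max(abs(x))
  ppv <- abs(max(x) - min(x))
  m2 <- 0; m4 <- 0; m6 <- 0; m8 <- 0; vs <- 0
  for (v in x) {
    dv <- v - mv
    m2 <- m2 + dv^2; m4 <- m4 + dv^4; m6 <- m6 + dv^6; m8 <- m8 + dv^8
    vs <- vs + dv^2
  }
  m2 <- m2 / n; m4 <- m4 / n; m6 <- m6 / n; m8 <- m8 / n
  c(mv = mv, sa = sa, rms = rms, pv = pv, ppv = ppv,
    cf = pv / rms, if_ = pv / sa, sf = rms / sa,
    var = vs / (n - 1), kur = m4 / m2^2, m6a = m6 / m2^3, m8a = m8 / m2^4)
}

# Pairwise-comparison AUROC (probability a random positive outranks a
# random negative, ties counted half), by exhaustive enumeration.
ref_auroc <- function(y_true, scores) {
  pos <- scores[y_true == sort(unique(y_true))[2]]
  neg <- scores[y_true == sort(unique(y_true))[1]]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Two separable Gaussian blobs.
make_blobs <- function(n_per = 100, gap = 5, d = 2, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = gap), n_per, d))
  list(X = X, y = rep(c("HC", "OA"), each = n_per))
}

# XOR layout in two dimensions.
make_xor <- function(n = 200, seed = 1) {
  set.seed(seed)
  X <- matrix(runif(2 * n, -1, 1), n, 2)
  list(X = X, y = ifelse(X[, 1] * X[, 2] > 0, "A", "B"))
}

# 1 informative (class-shifted) + 3 noise features, n = 100.
make_informative_noise <- function(seed, gap = 6) {
  set.seed(seed)
  X <- cbind(c(rnorm(50, 0), rnorm(50, gap)), matrix(rnorm(300), 100, 3))
  list(X = X, y = rep(c(1L, 2L), each = 50))
}

# Small fast simulation settings used across pipeline tests.
fast_sim <- function(...) {
  vag_sim_config(n_cycles = 1L, cycle_s = 1, rest_s = 0.5, ...)
}

fast_emd <- function(...) {
  emd_config(ensemble_size = 2L, max_imfs = 10L, ...)
}
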