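#' EMD / EEMD configuration
#'
#' @param max_imfs Maximum number of intrinsic mode functions to extract.
#' @param sift_tolerance Cauchy-type sifting stoppage threshold
#'   `sum((d_prev - d_new)^2) / sum(d_prev^2)`.
#' @param max_sift_iterations Hard cap on sifting iterations per IMF.
#' @param ensemble_size Ensemble size N for EEMD (1 = plain EMD behaviour
#'   when the noise fraction is 0).
#' @param noise_std_fraction SD of the added white noise as a fraction of
#'   the signal SD.
#' @param seed Seed for the ensemble noise.
#' @return An object of class `emd_config`.
#' @export
emd_config <- function(max_imfs = 12L, sift_tolerance = 0.2,
                       max_sift_iterations = 100L, ensemble_size = 100L,
                       noise_std_fraction = 0.2, seed = 1L) {
  if (ensemble_size < 1) stop("ensemble_size must be >= 1")
  if (noise_std_fraction < 0) stop("noise_std_fraction must be >= 0")
  structure(list(max_imfs = as.integer(max_imfs),
                 sift_tolerance = sift_tolerance,
                 max_sift_iterations = as.integer(max_sift_iterations),
                 ensemble_size = as.integer(ensemble_size),
                 noise_std_fraction = noise_std_fraction,
                 seed = as.integer(seed)),
            class = "emd_config")
}

new_imf_decomposition <- function(imfs, residual) {
  structure(list(imfs = imfs, residual = residual,
                 source_length = length(residual),
                 n_imfs = ncol(imfs)),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition> %d IMFs + residual, %d samples\n",
              x$n_imfs, x$source_length))
  invisible(x)
}

#' Mean of the upper and lower cubic-spline envelopes
#'
#' One sifting step's envelope mean: a cubic spline is fitted through the
#' local maxima (upper envelope) and the local minima (lower envelope), with
#' two extrema mirrored across each end of the series, and the pointwise
#' mean of the two envelopes is returned.
#'
#' @param x Numeric series with at least two maxima and two minima.
#' @return Numeric series of the same length.
#' @export
sift_envelope_mean <- function(x) {
  if (anyNA(x) || any(!is.finite(x))) stop("x must be finite")
  res <- .envelope_mean_cpp(as.numeric(x))
  if (!res$ok)
    stop(structure(class = c("vag_not_siftable", "error", "condition"),
                   list(message = "series has fewer than two maxima or two minima (monotonic/residual)",
                        call = sys.call())))
  res$mean
}

#' Empirical mode decomposition
#'
#' Repeatedly sifts the input into intrinsic mode functions (IMFs), highest
#' frequency first, until the remainder is monotonic (fewer than two maxima
#' or minima) or `max_imfs` is reached. An IMF is accepted when the sifting
#' refinement falls below `sift_tolerance` and its extrema and zero-crossing
#' counts differ by at most one. The IMFs plus the residual reconstruct the
#' input to floating-point accuracy.
#'
#' @param x Finite numeric series, length >= 16.
#' @param config An [emd_config()].
#' @return An `imf_decomposition` with an `n x k` IMF matrix and the
#'   residual.
#' @export
emd <- function(x, config = emd_config()) {
  if (anyNA(x) || any(!is.finite(x))) stop("x must be finite")
  if (length(x) < 16L) stop("x must have at least 16 samples")
  res <- .emd_cpp(as.numeric(x), config$max_imfs, config$sift_tolerance,
                  config$max_sift_iterations)
  new_imf_decomposition(res$imfs, res$residual)
}

#' Ensemble empirical mode decomposition
#'
#' Runs [emd()] on `ensemble_size` copies of the input with added white
#' Gaussian noise (SD = `noise_std_fraction * sd(x)`), aligns the members'
#' IMFs by index (missing trailing IMFs padded with zeros) and returns the
#' per-index ensemble means plus the mean residual. With zero noise the
#' result equals plain EMD for any ensemble size.
#'
#' @inheritParams emd
#' @return An `imf_decomposition`.
#' @export
eemd <- function(x, config = emd_config()) {
  if (anyNA(x) || any(!is.finite(x))) stop("x must be finite")
  if (length(x) < 16L) stop("x must have at least 16 samples")
  noise_sd <- config$noise_std_fraction * sd(x)
  if (noise_sd == 0) return(emd(x, config))
  with_seed(config$seed, {
    n <- length(x)
    members <- vector("list", config$ensemble_size)
    for (m in seq_len(config$ensemble_size)) {
      y <- as.numeric(x) + rnorm(n, 0, noise_sd)
      members[[m]] <- .emd_cpp(y, config$max_imfs, config$sift_tolerance,
                               config$max_sift_iterations)
    }
    k <- max(vapply(members, function(d) ncol(d$imfs), integer(1)))
    imfs <- matrix(0, n, k)
    residual <- numeric(n)
    for (d in members) {
      if (ncol(d$imfs) > 0)
        imfs[, seq_len(ncol(d$imfs))] <-
          imfs[, seq_len(ncol(d$imfs)), drop = FALSE] + d$imfs
      residual <- residual + d$residual
    }
    new_imf_decomposition(imfs / config$ensemble_size,
                          residual / config$ensemble_size)
  })
}

#' Remove the monotonic trend (and optionally noise modes) from a signal
#'
#' Subtracts the EEMD residual — the monotonic drift captured during
#' decomposition — and optionally the first `drop_noise_imfs`
#' highest-frequency IMFs from the input.
#'
#' @inheritParams emd
#' @param drop_noise_imfs Number of leading (highest-frequency) IMFs to
#'   drop; default 0 keeps all oscillatory content.
#' @return The cleaned series.
#' @export
detrend_and_clean <- function(x, config = emd_config(), drop_noise_imfs = 0L) {
  dec <- eemd(x, config)
  if (drop_noise_imfs >= max(dec$n_imfs, 1L) && drop_noise_imfs > 0L)
    stop("drop_noise_imfs must be smaller than the number of IMFs (",
         dec$n_imfs, ")")
  out <- as.numeric(x) - dec$residual
  if (drop_noise_imfs > 0L)
    out <- out - rowSums(dec$imfs[, seq_len(drop_noise_imfs), drop = FALSE])
  out
}

#' Scale a series to unit peak amplitude
#'
#' @param x Numeric series.
#' @return `x / max(abs(x))`; an all-zero series is returned unchanged.
#' @export
normalize_signal <- function(x) {
  m <- max(abs(x))
  if (m == 0) return(x)
  x / m
}

#' Detect motion segments from the encoder trace
#'
#' Finds contiguous runs where the smoothed absolute angular velocity of the
#' encoder exceeds `min_slope`, merges runs separated by brief sub-threshold
#' dips (the zero-velocity instant at peak flexion), maps them from encoder
#' time to signal sample indices, pads each side by `pad` seconds and clips
#' to the signal extent. Indices are 0-based, half-open `[start, end)`.
#'
#' @param encoder A `vag_encoder`.
#' @param signal_rate Signal sampling rate (Hz).
#' @param min_slope Angular-velocity threshold (degrees/s).
#' @param pad Padding added to each side of a segment (s).
#' @param merge_gap Sub-threshold gaps shorter than this are bridged (s).
#' @param signal_length Signal length in samples; defaults to covering the
#'   encoder trace.
#' @return A data.frame with columns `cycle_id`, `start`, `end` (sample
#'   indices), `start_s`, `end_s`; zero rows when nothing moves.
#' @export
detect_motion_segments <- function(encoder, signal_rate, min_slope = 5,
                                   pad = 0.1, merge_gap = 0.5,
                                   signal_length = NULL) {
  if (length(encoder$time) == 0L) stop("encoder trace is empty")
  if (is.null(signal_length))
    signal_length <- floor(max(encoder$time) * signal_rate) + 1L
  t <- encoder$time
  a <- encoder$angle
  if (length(t) < 3L) return(empty_segments())
  vel <- c(0, diff(a) / diff(t))
  vel <- stats::filter(vel, rep(1 / 3, 3), sides = 2)
  vel[is.na(vel)] <- 0
  moving <- abs(as.numeric(vel)) > min_slope
  if (!any(moving)) return(empty_segments())
  r <- rle(moving)
  # bridge short FALSE runs between TRUE runs
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i] && i > 1L && i < length(r$values)) {
      if (t[ends[i]] - t[starts[i]] <= merge_gap) r$values[i] <- TRUE
    }
  }
  moving <- inverse.rle(r)
  r <- rle(moving)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(cycle_id = integer(0), start = integer(0),
                    end = integer(0), start_s = numeric(0),
                    end_s = numeric(0))
  cid <- 0L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    cid <- cid + 1L
    t0 <- max(t[starts[i]] - pad, 0)
    t1 <- min(t[ends[i]] + pad, max(t))
    s0 <- max(floor(t0 * signal_rate), 0L)
    s1 <- min(ceiling(t1 * signal_rate) + 1L, signal_length)
    seg <- rbind(seg, data.frame(cycle_id = cid, start = as.integer(s0),
                                 end = as.integer(s1), start_s = t0,
                                 end_s = t1))
  }
  seg
}

empty_segments <- function() {
  data.frame(cycle_id = integer(0), start = integer(0), end = integer(0),
             start_s = numeric(0), end_s = numeric(0))
}

#' Extract one motion segment from a recording channel
#'
#' @param rec A `vag_recording`.
#' @param segment One row of [detect_motion_segments()] output.
#' @param channel `"medial"` or `"lateral"`.
#' @return The numeric sub-series (0-based half-open indexing).
#' @export
extract_segment <- function(rec, segment, channel = c("medial", "lateral")) {
  channel <- match.arg(channel)
  x <- if (channel == "medial") rec$channel_medial else rec$channel_lateral
  x[(segment$start + 1L):segment$end]
}
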