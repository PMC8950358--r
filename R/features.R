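FEATURE_NAMES <- c("mv", "sa", "rms", "pv", "ppv", "cf", "if_", "sf",
                   "var", "kur", "m6a", "m8a")

#' Twelve time-domain vibration state indicators
#'
#' Computes, for one signal segment: mean value (MV), straightened average
#' (SA, the mean absolute value), root mean square (RMS), peak value (PV),
#' peak-to-peak value (PPV), crest factor (CF = PV/RMS), impact factor
#' (IF = PV/SA), shape factor (SF = RMS/SA), variance (VAR, N-1
#' denominator), kurtosis (KUR) and the impulse-sensitive higher-moment
#' ratios M6A and M8A (sixth/eighth central moment over variance to the
#' third/fourth power, population 1/N moments throughout the ratios).
#'
#' By default IF and SF use the straightened average as denominator: for
#' zero-mean oscillating signals the signed mean collapses to zero and the
#' literal ratios explode. `literal_mean = TRUE` restores the signed-mean
#' reading.
#'
#' On a constant series the moment-ratio features (CF when RMS = 0, IF, SF
#' when SA = 0, KUR, M6A, M8A) are undefined and returned as `NA` with a
#' warning; they are never silently NaN-propagated.
#'
#' @param x Numeric series, length >= 2.
#' @param literal_mean Use the signed mean (MV) as IF/SF denominator.
#' @return Named numeric vector with elements
#'   `mv, sa, rms, pv, ppv, cf, if_, sf, var, kur, m6a, m8a`.
#' @export
compute_features <- function(x, literal_mean = FALSE) {
  n <- length(x)
  if (n < 2L) stop("x must have at least 2 samples")
  if (anyNA(x) || any(!is.finite(x))) stop("x must be finite")
  mv  <- mean(x)
  sa  <- mean(abs(x))
  rms <- sqrt(mean(x^2))
  pv  <- max(abs(x))
  ppv <- abs(max(x) - min(x))
  vr  <- sum((x - mv)^2) / (n - 1)
  m2  <- mean((x - mv)^2)
  denom <- if (literal_mean) mv else sa
  cf  <- if (rms > 0) pv / rms else NA_real_
  if_ <- if (denom != 0) pv / denom else NA_real_
  sf  <- if (denom != 0) rms / denom else NA_real_
  if (m2 > 0) {
    kur <- mean((x - mv)^4) / m2^2
    m6a <- mean((x - mv)^6) / m2^3
    m8a <- mean((x - mv)^8) / m2^4
  } else {
    kur <- m6a <- m8a <- NA_real_
  }
  out <- c(mv = mv, sa = sa, rms = rms, pv = pv, ppv = ppv, cf = cf,
           if_ = if_, sf = sf, var = vr, kur = kur, m6a = m6a, m8a = m8a)
  if (anyNA(out))
    warning("undefined state indicators on degenerate segment: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Build the labelled feature table for a cohort
#'
#' Detects motion segments from each recording's encoder, optionally cleans
#' each segment by EEMD trend removal, computes the twelve state indicators
#' per channel per segment and returns one row per
#' (recording, segment, channel) together with demographics and the group
#' label. Recordings without detected motion, and degenerate segments with
#' undefined indicators, are skipped with a warning.
#'
#' @param dataset A `vag_dataset`.
#' @param emd_cfg An [emd_config()] used for cleaning; `NULL` skips the
#'   EEMD step (features on the raw segment).
#' @param min_slope,pad Segmentation controls, see
#'   [detect_motion_segments()].
#' @param drop_noise_imfs Passed to [detrend_and_clean()].
#' @param normalize Scale each cleaned segment to unit peak before feature
#'   extraction.
#' @return A data.frame; feature columns in the fixed order
#'   `mv ... m8a`, label column `group` last.
#' @export
build_feature_table <- function(dataset, emd_cfg = emd_config(),
                                min_slope = 5, pad = 0.1,
                                drop_noise_imfs = 0L, normalize = TRUE) {
  rows <- list()
  for (rec in dataset$recordings) {
    seg <- detect_motion_segments(rec$encoder, rec$sample_rate,
                                  min_slope = min_slope, pad = pad,
                                  signal_length = length(rec$channel_medial))
    if (nrow(seg) == 0L) {
      warning("recording ", rec$recording_id,
              ": no motion segments detected; skipped")
      next
    }
    for (i in seq_len(nrow(seg))) {
      for (ch in c("medial", "lateral")) {
        x <- extract_segment(rec, seg[i, ], ch)
        if (!is.null(emd_cfg))
          x <- detrend_and_clean(x, emd_cfg, drop_noise_imfs)
        if (normalize) x <- normalize_signal(x)
        fv <- suppressWarnings(compute_features(x))
        if (anyNA(fv)) {
          warning("recording ", rec$recording_id, " segment ",
                  seg$cycle_id[i], " channel ", ch,
                  ": undefined indicators; row skipped")
          next
        }
        s <- rec$subject
        rows[[length(rows) + 1L]] <- data.frame(
          recording_id = rec$recording_id, subject_id = s$subject_id,
          knee = rec$knee, chain = rec$chain, segment_id = seg$cycle_id[i],
          channel = ch, age = s$age, sex = as.integer(s$sex == "F"),
          bmi = s$bmi, as.list(fv), group = s$group,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame())
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$recording_id, tab$segment_id, tab$channel), ]
  rownames(tab) <- NULL
  tab
}

#' Write a feature table as CSV (fixed column order, label last)
#'
#' @param table Output of [build_feature_table()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  fixed <- c("recording_id", "subject_id", "knee", "chain", "segment_id",
             "channel", "age", "sex", "bmi", FEATURE_NAMES, "group")
  write.csv(table[, fixed], path, row.names = FALSE)
  invisible(path)
}
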