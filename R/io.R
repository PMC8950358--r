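#' Write a VAG recording in the device CSV dialect
#'
#' Emits `<id>_signal.csv` with columns `time_s, medial, lateral` and a
#' parallel `<id>_encoder.csv` with columns `time_s, angle_deg`.
#'
#' @param rec A `vag_recording`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_vag_recording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(rec$channel_medial)
  t <- (seq_len(n) - 1L) / rec$sample_rate
  sig_path <- file.path(dir, paste0(rec$recording_id, "_signal.csv"))
  enc_path <- file.path(dir, paste0(rec$recording_id, "_encoder.csv"))
  write.csv(data.frame(time_s = t, medial = rec$channel_medial,
                       lateral = rec$channel_lateral),
            sig_path, row.names = FALSE)
  write.csv(data.frame(time_s = rec$encoder$time,
                       angle_deg = rec$encoder$angle),
            enc_path, row.names = FALSE)
  invisible(c(signal = sig_path, encoder = enc_path))
}

#' Write a cohort: per-recording CSVs plus one metadata table
#'
#' @param dataset A `vag_dataset`.
#' @param dir Output directory.
#' @return Invisibly, the metadata CSV path.
#' @export
write_vag_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in dataset$recordings) write_vag_recording(rec, dir)
  meta <- do.call(rbind, lapply(dataset$recordings, function(r) {
    s <- r$subject
    data.frame(recording_id = r$recording_id, subject_id = s$subject_id,
               group = s$group, chain = r$chain, knee = r$knee,
               age = s$age, sex = s$sex, height = s$height,
               weight = s$weight, bmi = s$bmi, stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  path <- file.path(dir, "metadata.csv")
  write.csv(meta, path, row.names = FALSE)
  invisible(path)
}

#' Read one recording back from the device CSV dialect
#'
#' @param dir Directory containing the cohort files.
#' @param recording_id Recording identifier (file prefix).
#' @return A `vag_recording` (subject populated from `metadata.csv` when
#'   present).
#' @export
read_vag_recording <- function(dir, recording_id) {
  sig <- read.csv(file.path(dir, paste0(recording_id, "_signal.csv")))
  enc <- read.csv(file.path(dir, paste0(recording_id, "_encoder.csv")))
  fs <- 1 / stats::median(diff(sig$time_s))
  meta_path <- file.path(dir, "metadata.csv")
  subject <- NULL
  chain <- sub(".*_", "", recording_id)
  knee <- sub(".*_([LR])_[A-Z]+$", "\\1", recording_id)
  if (file.exists(meta_path)) {
    meta <- read.csv(meta_path, stringsAsFactors = FALSE)
    row <- meta[meta$recording_id == recording_id, ]
    if (nrow(row) == 1L) {
      subject <- structure(list(subject_id = row$subject_id, group = row$group,
                                age = row$age, sex = row$sex,
                                height = row$height, weight = row$weight,
                                bmi = row$bmi), class = "vag_subject")
      chain <- row$chain
      knee <- row$knee
    }
  }
  encoder <- structure(list(time = enc$time_s, angle = enc$angle_deg,
                            angle_ideal = enc$angle_deg, chain = chain,
                            rate = 1 / stats::median(diff(enc$time_s)),
                            n_cycles = NA_integer_), class = "vag_encoder")
  structure(list(subject = subject, chain = chain, knee = knee,
                 sample_rate = round(fs),
                 channel_medial = sig$medial, channel_lateral = sig$lateral,
                 encoder = encoder, n_cycles = NA_integer_,
                 recording_id = recording_id),
            class = "vag_recording")
}
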