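#' Default cohort demographics table
#'
#' Per-group means and standard deviations of the simulated cohort
#' characteristics: age (years), height (m) and body-mass index (kg/m^2),
#' plus the probability that a subject is female. The values describe a
#' young, lean healthy-control group and an older, heavier osteoarthritis
#' group, as typically recruited for knee vibroarthrography studies.
#' Weight is induced as `bmi * height^2` so that both the BMI and height
#' marginals match the table; see the methods vignette.
#'
#' @return A data.frame with columns `group`, `field`, `mean`, `sd`.
#' @export
default_demographics <- function() {
  data.frame(
    group = rep(c("HC", "OA"), each = 4L),
    field = rep(c("age", "height", "bmi", "p_female"), 2L),
    mean  = c(24.10, 1.71, 21.95, 24 / 33,
              56.15, 1.69, 31.19, 19 / 34),
    sd    = c(5.56, 0.09, 3.09, NA,
              12.99, 0.09, 4.83, NA),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for synthetic VAG cohorts
#'
#' Bundles every tunable of the synthetic vibroarthrography generator.
#' Amplitudes are dimensionless (the recording hardware's gain is not
#' modelled; signals are normalized downstream).
#'
#' @param n_hc,n_oa Number of healthy-control / osteoarthritis subjects.
#' @param seed Integer RNG seed; the whole cohort is reproducible from it.
#' @param impulse_rate_oa Crepitus impulse rate for OA knees (impulses/s,
#'   Poisson arrivals gated to joint motion).
#' @param impulse_amplitude Mean impulse amplitude (log-normal across
#'   impulses, relative units).
#' @param impulse_sdlog Log-scale SD of impulse amplitudes.
#' @param drift_amplitude Total monotonic sensor-drift excursion over a
#'   recording (relative units).
#' @param mains_freq Mains interference frequency (Hz).
#' @param mains_amplitude Mains interference amplitude (relative units).
#' @param noise_sigma White measurement-noise SD (relative units).
#' @param friction_amplitude Articular friction-noise amplitude; defaults to
#'   `2 * noise_sigma`.
#' @param modulation_floor Fraction of the friction envelope present at zero
#'   angular velocity; the remainder scales with |angular velocity|.
#' @param friction_band Band of the friction noise (Hz, length 2).
#' @param sample_rate Signal sampling rate (Hz); at least twice the 2 kHz
#'   sensor bandwidth.
#' @param encoder_rate Encoder sampling rate (Hz).
#' @param n_cycles Flexion-extension repetitions per recording.
#' @param cycle_s Duration of one flexion-extension cycle (s).
#' @param rest_s Rest before, between and after cycles (s).
#' @param demographics Demographics table, see [default_demographics()].
#' @return An object of class `vag_sim_config` (a named list).
#' @export
vag_sim_config <- function(n_hc = 33L, n_oa = 34L, seed = 1L,
                           impulse_rate_oa = 8, impulse_amplitude = 0.8,
                           impulse_sdlog = 0.3,
                           drift_amplitude = 0.2,
                           mains_freq = 50, mains_amplitude = 0.02,
                           noise_sigma = 0.05, friction_amplitude = NULL,
                           modulation_floor = 0.6,
                           friction_band = c(10, 1000),
                           sample_rate = 4096, encoder_rate = 10,
                           n_cycles = 4L, cycle_s = 4, rest_s = 1,
                           demographics = default_demographics()) {
  if (is.null(friction_amplitude)) friction_amplitude <- 2 * noise_sigma
  cfg <- list(n_hc = as.integer(n_hc), n_oa = as.integer(n_oa),
              seed = as.integer(seed),
              impulse_rate_oa = impulse_rate_oa,
              impulse_amplitude = impulse_amplitude,
              impulse_sdlog = impulse_sdlog,
              drift_amplitude = drift_amplitude,
              mains_freq = mains_freq, mains_amplitude = mains_amplitude,
              noise_sigma = noise_sigma,
              friction_amplitude = friction_amplitude,
              modulation_floor = modulation_floor,
              friction_band = friction_band,
              sample_rate = sample_rate, encoder_rate = encoder_rate,
              n_cycles = as.integer(n_cycles), cycle_s = cycle_s,
              rest_s = rest_s, demographics = demographics)
  rates <- c(cfg$impulse_rate_oa, cfg$impulse_amplitude, cfg$drift_amplitude,
             cfg$mains_amplitude, cfg$noise_sigma, cfg$friction_amplitude)
  if (any(rates < 0)) stop("rates and amplitudes must be >= 0")
  if (cfg$sample_rate < 4000) stop("sample_rate must cover the 2 kHz sensor band")
  class(cfg) <- "vag_sim_config"
  cfg
}

demo_par <- function(demographics, group, field) {
  row <- demographics[demographics$group == group & demographics$field == field, ]
  if (nrow(row) != 1L) stop("no demographic entry for group '", group,
                            "', field '", field, "'")
  row
}

rnorm_trunc <- function(mean, sd, lower, upper) {
  if (sd == 0) return(mean)
  for (i in 1:100) {
    x <- rnorm(1L, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
  min(max(mean, lower), upper)
}

#' Draw one synthetic subject's demographics
#'
#' Age, height and BMI are drawn from the configured per-group normal
#' distributions (truncated to plausible positive ranges); weight is induced
#' as `bmi * height^2` and the stored BMI is recomputed from weight and
#' height. Sex is Bernoulli with the group's configured female fraction.
#' Uses the current RNG stream.
#'
#' @param group `"HC"` or `"OA"`.
#' @param config A [vag_sim_config()].
#' @param subject_id Identifier string.
#' @return An object of class `vag_subject`.
#' @export
generate_subject <- function(group, config = vag_sim_config(),
                             subject_id = paste0(group, "01")) {
  if (!group %in% c("HC", "OA")) stop("unknown group '", group, "'")
  dm <- config$demographics
  age    <- rnorm_trunc(demo_par(dm, group, "age")$mean,
                        demo_par(dm, group, "age")$sd, 1, 100)
  height <- rnorm_trunc(demo_par(dm, group, "height")$mean,
                        demo_par(dm, group, "height")$sd, 1.30, 2.20)
  bmi0   <- rnorm_trunc(demo_par(dm, group, "bmi")$mean,
                        demo_par(dm, group, "bmi")$sd, 12, 60)
  weight <- bmi0 * height^2
  sex <- if (runif(1L) < demo_par(dm, group, "p_female")$mean) "F" else "M"
  subj <- list(subject_id = subject_id, group = group, age = age, sex = sex,
               height = height, weight = weight, bmi = weight / height^2)
  class(subj) <- "vag_subject"
  subj
}

#' @export
print.vag_subject <- function(x, ...) {
  cat(sprintf("<vag_subject> %s  group=%s  age=%.1f  sex=%s  bmi=%.1f\n",
              x$subject_id, x$group, x$age, x$sex, x$bmi))
  invisible(x)
}

ENCODER_STEP <- 360 / 1024  # 10-bit magnetic encoder code grid (degrees)

#' Generate a knee-angle encoder trace
#'
#' Produces a flexion-extension angle series between the hard stops at 0 and
#' 90 degrees: `n_cycles` smooth sinusoid-like cycles separated by rests,
#' sampled at the encoder rate and quantized to the 10-bit code grid
#' (360/1024 degrees). With `gentle = TRUE` the cycle is flattened at its
#' start and end (slower ramps, as seen in painful knees).
#'
#' @param chain `"OKC"` or `"CKC"` (recorded in the trace; the kinematics
#'   model is shared).
#' @param n_cycles Number of flexion-extension repetitions (>= 1).
#' @param rate Encoder sampling rate (Hz).
#' @param cycle_s Cycle duration (s).
#' @param rest_s Rest before, between and after cycles (s).
#' @param gentle Flatten cycle on/offsets (gentler slopes).
#' @return An object of class `vag_encoder` with fields `time` (s), `angle`
#'   (quantized degrees) and `angle_ideal` (the dequantized generating
#'   trace).
#' @export
generate_encoder_trace <- function(chain = c("OKC", "CKC"), n_cycles = 4L,
                                   rate = 10, cycle_s = 4, rest_s = 1,
                                   gentle = FALSE) {
  chain <- match.arg(chain)
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  total <- rest_s + n_cycles * (cycle_s + rest_s)
  time <- seq(0, total, by = 1 / rate)
  angle <- numeric(length(time))
  p <- if (gentle) 2 else 1
  for (k in seq_len(n_cycles)) {
    t0 <- rest_s + (k - 1) * (cycle_s + rest_s)
    inside <- time >= t0 & time <= t0 + cycle_s
    angle[inside] <- 90 * sin(pi * (time[inside] - t0) / cycle_s)^(2 * p)
  }
  angle <- pmin(pmax(angle, 0), 90)
  quant <- pmin(pmax(round(angle / ENCODER_STEP) * ENCODER_STEP, 0), 90)
  enc <- list(time = time, angle = quant, angle_ideal = angle,
              chain = chain, rate = rate, n_cycles = as.integer(n_cycles))
  class(enc) <- "vag_encoder"
  enc
}

#' @export
print.vag_encoder <- function(x, ...) {
  cat(sprintf("<vag_encoder> %s  %d cycles  %.1f s @ %g Hz\n",
              x$chain, x$n_cycles, max(x$time), x$rate))
  invisible(x)
}

# |angular velocity| of the encoder's ideal trace, interpolated onto the
# signal time grid and normalized to [0, 1].
angular_velocity_profile <- function(encoder, t_signal) {
  f <- splinefun(encoder$time, encoder$angle_ideal, method = "fmm")
  vel <- abs(f(t_signal, deriv = 1))
  vmax <- max(vel)
  if (vmax > 0) vel / vmax else vel
}

bandlimited_noise <- function(n, fs, band) {
  w <- rnorm(n)
  ny <- fs / 2
  lo <- max(band[1] / ny, 1e-4)
  hi <- min(band[2] / ny, 0.99)
  bf <- signal::butter(4, c(lo, hi), type = "pass")
  x <- as.numeric(signal::filter(bf, w))
  s <- sd(x)
  if (s > 0) x / s else x
}

damped_impulse <- function(fs, tau = 0.004, f_c = 500) {
  t <- seq(0, 6 * tau, by = 1 / fs)
  exp(-t / tau) * sin(2 * pi * f_c * t)
}

#' Synthesize one two-channel VAG recording
#'
#' Each channel is the sum of band-limited articular friction noise whose
#' envelope follows |angular velocity|, optional crepitus impulses (OA only:
#' Poisson-timed, motion-gated, log-normal amplitude, damped-oscillation
#' shape, shared timing across channels), a monotonic sensor-drift ramp,
#' mains interference and white measurement noise. Uses the current RNG
#' stream.
#'
#' @param subject A `vag_subject`.
#' @param encoder A `vag_encoder`.
#' @param config A [vag_sim_config()].
#' @param knee `"L"` or `"R"`.
#' @param impulses Force the crepitus impulse term on/off; defaults to
#'   `subject$group == "OA"`.
#' @return An object of class `vag_recording`.
#' @export
generate_vag_signal <- function(subject, encoder, config = vag_sim_config(),
                                knee = "L", impulses = NULL) {
  if (length(encoder$time) < 2L) stop("encoder trace is empty or degenerate")
  if (is.null(impulses)) impulses <- subject$group == "OA"
  fs <- config$sample_rate
  t_end <- max(encoder$time)
  t <- seq(0, t_end, by = 1 / fs)
  n <- length(t)
  wnorm <- angular_velocity_profile(encoder, t)
  envelope <- config$modulation_floor + (1 - config$modulation_floor) * wnorm

  imp_train <- numeric(n)
  if (impulses && config$impulse_rate_oa > 0 && config$impulse_amplitude > 0) {
    n_imp <- rpois(1L, config$impulse_rate_oa * t_end)
    if (n_imp > 0) {
      times <- sort(runif(n_imp, 0, t_end))
      keep <- wnorm[pmin(pmax(round(times * fs) + 1L, 1L), n)] > 0.1
      times <- times[keep]
      shape <- damped_impulse(fs)
      meanlog <- log(config$impulse_amplitude) - config$impulse_sdlog^2 / 2
      for (ti in times) {
        amp <- rlnorm(1L, meanlog, config$impulse_sdlog) * sample(c(-1, 1), 1L)
        i0 <- round(ti * fs) + 1L
        idx <- i0:min(i0 + length(shape) - 1L, n)
        imp_train[idx] <- imp_train[idx] + amp * shape[seq_along(idx)]
      }
    }
  }

  make_channel <- function() {
    fric <- if (config$friction_amplitude > 0)
      config$friction_amplitude * envelope *
        bandlimited_noise(n, fs, config$friction_band) else numeric(n)
    drift <- if (config$drift_amplitude > 0)
      sample(c(-1, 1), 1L) * config$drift_amplitude * t / t_end else numeric(n)
    mains <- if (config$mains_amplitude > 0)
      config$mains_amplitude * sin(2 * pi * config$mains_freq * t +
                                     runif(1L, 0, 2 * pi)) else numeric(n)
    white <- if (config$noise_sigma > 0) rnorm(n, 0, config$noise_sigma)
      else numeric(n)
    fric + imp_train + drift + mains + white
  }

  rec <- list(subject = subject, chain = encoder$chain, knee = knee,
              sample_rate = fs,
              channel_medial = make_channel(),
              channel_lateral = make_channel(),
              encoder = encoder, n_cycles = encoder$n_cycles,
              recording_id = paste(subject$subject_id, knee, encoder$chain,
                                   sep = "_"))
  class(rec) <- "vag_recording"
  rec
}

#' @export
print.vag_recording <- function(x, ...) {
  cat(sprintf("<vag_recording> %s  group=%s  %d samples @ %g Hz\n",
              x$recording_id, x$subject$group, length(x$channel_medial),
              x$sample_rate))
  invisible(x)
}

#' Generate a full synthetic VAG cohort
#'
#' Healthy controls contribute both knees, OA subjects only the affected
#' knee; every knee is recorded in both kinematic chains (OKC and CKC). The
#' whole dataset is reproducible from `config$seed`.
#'
#' @param config A [vag_sim_config()].
#' @return An object of class `vag_dataset`: a list with `recordings` (list
#'   of `vag_recording`), `subjects` and `config`.
#' @export
generate_dataset <- function(config = vag_sim_config()) {
  if (config$n_hc + config$n_oa == 0L) stop("need at least one subject")
  with_seed(config$seed, {
    subjects <- list()
    recordings <- list()
    add_recordings <- function(subj, knees) {
      gentle <- subj$group == "OA"
      for (knee in knees) for (chain in c("OKC", "CKC")) {
        enc <- generate_encoder_trace(chain, config$n_cycles,
                                      config$encoder_rate, config$cycle_s,
                                      config$rest_s, gentle = gentle)
        rec <- generate_vag_signal(subj, enc, config, knee = knee)
        recordings[[rec$recording_id]] <<- rec
      }
    }
    for (i in seq_len(config$n_hc)) {
      subj <- generate_subject("HC", config, sprintf("HC%02d", i))
      subjects[[subj$subject_id]] <- subj
      add_recordings(subj, c("L", "R"))
    }
    for (i in seq_len(config$n_oa)) {
      subj <- generate_subject("OA", config, sprintf("OA%02d", i))
      subjects[[subj$subject_id]] <- subj
      add_recordings(subj, sample(c("L", "R"), 1L))
    }
    ds <- list(recordings = recordings, subjects = subjects, config = config)
    class(ds) <- "vag_dataset"
    ds
  })
}

#' @export
print.vag_dataset <- function(x, ...) {
  groups <- vapply(x$recordings, function(r) r$subject$group, character(1))
  cat(sprintf("<vag_dataset> %d recordings (%d HC, %d OA knees x 2 chains), %d subjects\n",
              length(x$recordings), sum(groups == "HC") / 2,
              sum(groups == "OA") / 2, length(x$subjects)))
  invisible(x)
}
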