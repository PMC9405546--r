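# Synthetic paired ABP/PPG waveform generator.
#
# Every downstream stage (preprocessing, network training, BP estimation,
# grading, streaming) is exercised on these reproducible signals, which carry
# exact per-beat ground truth. The generator emulates the population the
# pipeline targets: 125 Hz paired fingertip PPG / arterial pressure records
# whose systolic/diastolic values span the four hypertension stages, with the
# PPG a lagged, smoothed, rescaled and noised transform of the ABP.

# Cohort-wide amplitude conventions. The ABP range is the span of the shipped
# normalization constants; the PPG range matches the shipped PPG constants so
# that default normalization is exercised end to end.
.abp_span <- c(50.33, 192.24) # mmHg
.ppg_span <- c(-2.4, 2.9)     # mV

#' Per-beat waveform parameters
#'
#' @param heart_rate_bpm heart rate in beats per minute (30-180).
#' @param sbp_mmHg target systolic (per-beat maximum) pressure, mmHg.
#' @param dbp_mmHg target diastolic (per-beat minimum) pressure, mmHg.
#' @param dicrotic_frac relative amplitude of the secondary (dicrotic) lobe,
#'   in `[0, 0.5]`.
#' @param hrv_jitter_frac uniform beat-interval jitter fraction, in `[0, 0.2]`.
#' @return a `bp_beat_params` list.
#' @export
beat_params <- function(heart_rate_bpm = 70, sbp_mmHg = 120, dbp_mmHg = 80,
                        dicrotic_frac = 0.2, hrv_jitter_frac = 0.05) {
  check_scalar(heart_rate_bpm, "heart_rate_bpm", 30, 180)
  check_scalar(sbp_mmHg, "sbp_mmHg", 40, 220)
  check_scalar(dbp_mmHg, "dbp_mmHg", 40, 220)
  check_scalar(dicrotic_frac, "dicrotic_frac", 0, 0.5)
  check_scalar(hrv_jitter_frac, "hrv_jitter_frac", 0, 0.2)
  if (dbp_mmHg >= sbp_mmHg) {
    fail_field("dbp_mmHg", "diastolic pressure must be below systolic")
  }
  structure(list(heart_rate_bpm = heart_rate_bpm, sbp_mmHg = sbp_mmHg,
                 dbp_mmHg = dbp_mmHg, dicrotic_frac = dicrotic_frac,
                 hrv_jitter_frac = hrv_jitter_frac),
            class = "bp_beat_params")
}

#' Simulation configuration
#'
#' @param fs_hz sampling rate in Hz; must exceed twice the upper passband edge
#'   of the preprocessing bandpass (8 Hz).
#' @param duration_s record length in seconds.
#' @param ppg_lag_samples non-negative integer delay of the PPG behind the ABP
#'   (the brachial-to-digital transit delay); must be below `fs_hz` (<= 1 s).
#' @param ppg_noise_sd additive Gaussian noise scale on the PPG, mV.
#' @param seed integer random seed; all randomness is derived from it.
#' @return a `bp_sim_config` list.
#' @export
sim_config <- function(fs_hz = 125, duration_s = 60, ppg_lag_samples = 25,
                       ppg_noise_sd = 0.05, seed = 1L) {
  check_scalar(fs_hz, "fs_hz", 16 + 1e-9, Inf)
  check_scalar(duration_s, "duration_s", 1e-9, Inf)
  check_scalar(ppg_lag_samples, "ppg_lag_samples", 0, Inf)
  if (ppg_lag_samples != round(ppg_lag_samples)) {
    fail_field("ppg_lag_samples", "must be an integer sample count")
  }
  if (ppg_lag_samples > fs_hz) {
    fail_field("ppg_lag_samples", "must be at most fs_hz (1 s of delay)")
  }
  check_scalar(ppg_noise_sd, "ppg_noise_sd", 0, Inf)
  check_scalar(seed, "seed", -Inf, Inf)
  structure(list(fs_hz = fs_hz, duration_s = duration_s,
                 ppg_lag_samples = as.integer(ppg_lag_samples),
                 ppg_noise_sd = ppg_noise_sd, seed = as.integer(seed)),
            class = "bp_sim_config")
}

# Unit-peak pulse shape on normalized phase t in [0, 1): a systolic lobe
# peaking at phase 0.3 plus a dicrotic bump peaking at 0.725, renormalized so
# max = 1 exactly; the baseline (phase >= 0.9 and 0) is exactly 0.
pulse_shape <- function(phase, dicrotic_frac) {
  s <- numeric(length(phase))
  m <- phase < 0.6
  s[m] <- sin(pi * phase[m] / 0.6)^2
  d <- phase >= 0.55 & phase < 0.9
  s[d] <- s[d] + dicrotic_frac * sin(pi * (phase[d] - 0.55) / 0.35)^2
  s / max(1, max(s))
}

#' Generate a beat-periodic arterial pressure series
#'
#' Each beat is `dbp + (sbp - dbp) * s(t)` where `s(t)` is a fixed unit-peak
#' pulse shape (systolic lobe plus dicrotic bump), so the per-beat maximum and
#' minimum equal the requested systolic and diastolic pressures. Beat
#' intervals are perturbed by the per-beat jitter fraction using the seeded
#' generator.
#'
#' @param beats a single [beat_params()] object or a list of them (one per
#'   beat, in order).
#' @param cfg a [sim_config()].
#' @return numeric pressure series in mmHg with attribute `beat_truth`, a
#'   data.frame of per-beat `(beat, start_sample, n_samples, sbp, dbp)`.
#' @export
generate_abp <- function(beats, cfg) {
  if (inherits(beats, "bp_beat_params")) beats <- list(beats)
  if (!length(beats)) stop("`beats` must be a nonempty list", call. = FALSE)
  lapply(beats, function(b) {
    if (!inherits(b, "bp_beat_params")) {
      stop("each element of `beats` must be built with beat_params()",
           call. = FALSE)
    }
  })
  stopifnot(inherits(cfg, "bp_sim_config"))
  with_seed(derive_seed(cfg$seed, "abp"), {
    out <- vector("list", length(beats))
    truth <- data.frame(beat = seq_along(beats), start_sample = NA_integer_,
                        n_samples = NA_integer_, sbp = NA_real_, dbp = NA_real_)
    pos <- 1L
    for (i in seq_along(beats)) {
      b <- beats[[i]]
      jitter <- runif(1, -1, 1) * b$hrv_jitter_frac
      n_b <- max(4L, as.integer(round(cfg$fs_hz * 60 / b$heart_rate_bpm *
                                        (1 + jitter))))
      phase <- (seq_len(n_b) - 1) / n_b
      s <- pulse_shape(phase, b$dicrotic_frac)
      out[[i]] <- b$dbp_mmHg + (b$sbp_mmHg - b$dbp_mmHg) * s
      truth$start_sample[i] <- pos
      truth$n_samples[i] <- n_b
      truth$sbp[i] <- b$sbp_mmHg
      truth$dbp[i] <- b$dbp_mmHg
      pos <- pos + n_b
    }
    structure(unlist(out), beat_truth = truth)
  })
}

#' Derive a PPG series from an arterial pressure series
#'
#' The PPG is `delay(smooth(affine(abp))) + noise`: a fixed cohort-wide affine
#' map takes the reference pressure span into the PPG amplitude convention
#' (approximately -2.4 to 2.9 mV), a symmetric Gaussian kernel smooths the
#' pulse (zero phase, so cross-correlation recovers the injected lag exactly),
#' the head of the delayed series is zero-padded, and seeded zero-mean noise
#' of scale `cfg$ppg_noise_sd` is added.
#'
#' @param abp pressure series, mmHg.
#' @param cfg a [sim_config()]; uses `ppg_lag_samples`, `ppg_noise_sd`, `seed`.
#' @return numeric PPG series in mV, same length as `abp`.
#' @export
derive_ppg <- function(abp, cfg) {
  stopifnot(inherits(cfg, "bp_sim_config"))
  n <- length(abp)
  if (!n) stop("`abp` must be nonempty", call. = FALSE)
  if (cfg$ppg_lag_samples >= n) {
    stop("ppg_lag_samples must be smaller than the series length",
         call. = FALSE)
  }
  a <- diff(.ppg_span) / diff(.abp_span)
  b <- .ppg_span[1] - a * .abp_span[1]
  x <- a * abp + b
  # symmetric (zero-phase) Gaussian smoothing, sd = 20 ms
  sd_s <- 0.02 * cfg$fs_hz
  half <- max(1L, as.integer(ceiling(4 * sd_s)))
  kern <- dnorm(seq(-half, half), sd = sd_s)
  kern <- kern / sum(kern)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  sm <- stats::filter(xp, kern, sides = 2)
  x <- as.numeric(sm[(half + 1):(half + n)])
  lag <- cfg$ppg_lag_samples
  if (lag > 0) x <- c(rep(0, lag), x[seq_len(n - lag)])
  if (cfg$ppg_noise_sd > 0) {
    x <- x + with_seed(derive_seed(cfg$seed, "ppg-noise"),
                       rnorm(n, 0, cfg$ppg_noise_sd))
  }
  x
}

#' Paired waveform record
#'
#' @param subject_id opaque subject label.
#' @param fs_hz sampling rate.
#' @param ppg PPG series, mV.
#' @param abp ABP series, mmHg; same length as `ppg`.
#' @param truth optional per-beat truth data.frame (`beat`, `start_sample`,
#'   `n_samples`, `sbp`, `dbp`), ordered in time.
#' @return a `bp_waveform_record`.
#' @export
waveform_record <- function(subject_id, fs_hz, ppg, abp, truth = NULL) {
  if (length(ppg) != length(abp)) {
    stop("`ppg` and `abp` must have equal length", call. = FALSE)
  }
  check_scalar(fs_hz, "fs_hz", 1e-9, Inf)
  if (!is.null(truth)) {
    stopifnot(is.data.frame(truth))
    if (is.unsorted(truth$start_sample)) {
      stop("`truth` beats must be ordered in time", call. = FALSE)
    }
  }
  structure(list(subject_id = as.character(subject_id), fs_hz = fs_hz,
                 ppg = as.numeric(ppg), abp = as.numeric(abp), truth = truth),
            class = "bp_waveform_record")
}

#' @export
print.bp_waveform_record <- function(x, ...) {
  cat(sprintf("<waveform record '%s': %d samples at %g Hz (%.1f s)%s>\n",
              x$subject_id, length(x$ppg), x$fs_hz, length(x$ppg) / x$fs_hz,
              if (is.null(x$truth)) "" else
                sprintf(", %d truth beats", nrow(x$truth))))
  invisible(x)
}

# Hypertension-stage sampling ranges (JNC7-style staging).
.stage_table <- data.frame(
  stage = c("normal", "prehypertension", "stage1", "stage2"),
  sbp_lo = c(95, 120, 140, 160), sbp_hi = c(119, 139, 159, 190),
  dbp_lo = c(60, 80, 90, 100), dbp_hi = c(79, 89, 99, 110),
  stringsAsFactors = FALSE
)

#' Generate a cohort of paired waveform records
#'
#' Subjects are assigned to hypertension stages by largest-remainder rounding
#' of `stage_mix` (deterministic: `n = 4` with an even mix yields exactly one
#' subject per stage), then each subject's systolic/diastolic targets are
#' drawn uniformly from the stage's range with a per-subject seed derived from
#' `cfg$seed`. Heart rate and dicrotic amplitude vary between subjects;
#' systolic/diastolic targets are held constant within a record so every beat
#' carries the same ground truth.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param stage_mix proportions over (normal, prehypertension, stage1,
#'   stage2); must sum to 1.
#' @param cfg a [sim_config()].
#' @return list of `bp_waveform_record`s with per-beat truth attached.
#' @export
generate_cohort <- function(n_subjects,
                            stage_mix = c(0.25, 0.25, 0.25, 0.25),
                            cfg = sim_config()) {
  check_scalar(n_subjects, "n_subjects", 1, Inf)
  if (length(stage_mix) != 4 || any(stage_mix < 0) || !sum(stage_mix)) {
    fail_field("stage_mix", "must be 4 nonnegative proportions")
  }
  if (abs(sum(stage_mix) - 1) > 1e-8) {
    fail_field("stage_mix", "must sum to 1")
  }
  stopifnot(inherits(cfg, "bp_sim_config"))
  n_subjects <- as.integer(n_subjects)
  # largest-remainder apportionment
  raw <- stage_mix * n_subjects
  counts <- floor(raw)
  left <- n_subjects - sum(counts)
  if (left > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(left)]] <- counts[order_rem[seq_len(left)]] + 1
  }
  stages <- rep(.stage_table$stage, counts)
  records <- vector("list", n_subjects)
  n_total <- as.integer(cfg$duration_s * cfg$fs_hz)
  for (i in seq_len(n_subjects)) {
    srow <- .stage_table[.stage_table$stage == stages[i], ]
    sseed <- derive_seed(cfg$seed, paste0("subject-", i))
    pars <- with_seed(sseed, list(
      sbp = runif(1, srow$sbp_lo, srow$sbp_hi),
      dbp = runif(1, srow$dbp_lo, srow$dbp_hi),
      hr = runif(1, 55, 95),
      dic = runif(1, 0.1, 0.35)
    ))
    n_beats <- ceiling(cfg$duration_s * pars$hr / 60) + 3L
    beats <- replicate(n_beats, beat_params(
      heart_rate_bpm = pars$hr, sbp_mmHg = pars$sbp, dbp_mmHg = pars$dbp,
      dicrotic_frac = pars$dic, hrv_jitter_frac = 0.05
    ), simplify = FALSE)
    scfg <- cfg
    scfg$seed <- sseed
    abp <- generate_abp(beats, scfg)
    truth <- attr(abp, "beat_truth")
    abp <- as.numeric(abp)[seq_len(n_total)]
    truth <- truth[truth$start_sample <= n_total, ]
    ppg <- derive_ppg(abp, scfg)
    records[[i]] <- waveform_record(sprintf("S%03d", i), cfg$fs_hz, ppg, abp,
                                    truth)
    records[[i]]$stage <- stages[i]
  }
  records
}
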