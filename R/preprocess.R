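# Signal preparation: bandpass filtering, phase matching, segmentation,
# quality screening and min-max normalization.
#
# Fixed stage order: filter -> align -> segment -> screen -> shuffle ->
# normalize. Only the PPG channel is filtered; the ABP channel is the
# regression target and keeps its absolute pressure level.

#' Preprocessing configuration
#'
#' @param fs_hz sampling rate, Hz.
#' @param passband_hz two-element passband edges, Hz (default 0.5-8).
#' @param transition_hz transition widths below/above the passband, Hz. The
#'   defaults place the stopbands at 0.25 and 10 Hz.
#' @param stopband_db minimum stopband attenuation, dB.
#' @param window_samples segment length (the network input size).
#' @param max_lag_samples cross-correlation search bound for phase matching.
#' @param flatline_sd screening: reject a window whose standard deviation is
#'   below this (units of the channel).
#' @param clip_run screening: reject if this many consecutive samples sit at
#'   the window extreme (saturation).
#' @param min_rate_bpm,max_rate_bpm screening: admissible pulse-rate band
#'   implied by the window's extrema count.
#' @param shuffle shuffle segments (seeded) before normalization/splitting.
#' @param seed stage seed for the shuffle.
#' @return a `bp_preprocess_config`.
#' @export
preprocess_config <- function(fs_hz = 125, passband_hz = c(0.5, 8),
                              transition_hz = c(0.25, 2), stopband_db = 40,
                              window_samples = 256, max_lag_samples = 125,
                              flatline_sd = 0.01, clip_run = 25,
                              min_rate_bpm = 30, max_rate_bpm = 180,
                              shuffle = TRUE, seed = 1L) {
  if (length(passband_hz) != 2 || passband_hz[1] <= 0 ||
      passband_hz[1] >= passband_hz[2] || passband_hz[2] >= fs_hz / 2) {
    fail_field("passband_hz", "needs 0 < low < high < fs/2")
  }
  if (length(transition_hz) != 2 || any(transition_hz <= 0) ||
      transition_hz[1] >= passband_hz[1]) {
    fail_field("transition_hz", "transitions must be positive and leave a low stopband")
  }
  check_scalar(window_samples, "window_samples", 2, Inf)
  check_scalar(max_lag_samples, "max_lag_samples", 1, Inf)
  check_scalar(stopband_db, "stopband_db", 10, 120)
  structure(list(fs_hz = fs_hz, passband_hz = passband_hz,
                 transition_hz = transition_hz, stopband_db = stopband_db,
                 window_samples = as.integer(window_samples),
                 max_lag_samples = as.integer(max_lag_samples),
                 flatline_sd = flatline_sd, clip_run = as.integer(clip_run),
                 min_rate_bpm = min_rate_bpm, max_rate_bpm = max_rate_bpm,
                 shuffle = isTRUE(shuffle), seed = as.integer(seed)),
            class = "bp_preprocess_config")
}

fir_response <- function(b, f, fs) {
  k <- seq_along(b) - 1
  vapply(f, function(ff) Mod(sum(b * exp(-2i * pi * ff * k / fs))), 0)
}

#' Design the linear-phase FIR bandpass filter
#'
#' Designs a symmetric (linear-phase) FIR whose magnitude response is within
#' +/- 1 dB across the passband and at least `stopband_db` down in both
#' stopbands. The design uses a Kaiser window at the order implied by the
#' narrowest transition band, then verifies the realized response on a dense
#' frequency grid, growing the order until the template is met.
#'
#' @param cfg a [preprocess_config()].
#' @return a `bp_fir` object: `coefficients`, integer `group_delay`
#'   (`(n_taps - 1) / 2`), `fs_hz`, and the measured `achieved` response
#'   extremes.
#' @export
design_bandpass <- function(cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "bp_preprocess_config"))
  fs <- cfg$fs_hz
  nyq <- fs / 2
  pass <- cfg$passband_hz
  stop_lo <- pass[1] - cfg$transition_hz[1]
  stop_hi <- pass[2] + cfg$transition_hz[2]
  cut <- c(pass[1] - cfg$transition_hz[1] / 2, pass[2] + cfg$transition_hz[2] / 2)
  a_target <- cfg$stopband_db

  grid_stop <- c(seq(0, stop_lo, length.out = 120),
                 seq(stop_hi, nyq, length.out = 400))
  grid_pass <- seq(pass[1], pass[2], length.out = 400)

  a_design <- a_target
  for (attempt in 1:6) {
    beta <- if (a_design > 50) 0.1102 * (a_design - 8.7) else if (a_design >= 21)
      0.5842 * (a_design - 21)^0.4 + 0.07886 * (a_design - 21) else 0
    dw <- 2 * pi * min(cfg$transition_hz) / fs
    n <- ceiling((a_design - 7.95) / (2.285 * dw))
    if (n %% 2 == 1) n <- n + 1 # even order -> odd tap count, integer delay
    b <- signal::fir1(n, cut / nyq, type = "pass",
                      window = signal::kaiser(n + 1, beta))
    sb <- 20 * log10(max(fir_response(b, grid_stop, fs)))
    pb <- 20 * log10(range(fir_response(b, grid_pass, fs)))
    ok <- sb <= -a_target && pb[1] >= -1 && pb[2] <= 1
    if (ok) {
      return(structure(list(coefficients = as.numeric(b),
                            group_delay = as.integer(n %/% 2), fs_hz = fs,
                            achieved = list(stopband_db = -sb,
                                            passband_db = pb)),
                       class = "bp_fir"))
    }
    shortfall <- a_target - (-sb)
    a_design <- a_design + max(3, shortfall + 2) # grow and retry
  }
  stop(sprintf(paste0("bandpass spec unmeetable: achieved %.1f dB stopband ",
                      "attenuation (target %.1f dB)"), -sb, a_target),
       call. = FALSE)
}

#' @export
print.bp_fir <- function(x, ...) {
  cat(sprintf("<FIR bandpass: %d taps, group delay %d samples (%.2f s), %.1f dB stopband>\n",
              length(x$coefficients), x$group_delay,
              x$group_delay / x$fs_hz, x$achieved$stopband_db))
  invisible(x)
}

#' Causally filter a signal
#'
#' Forward-only convolution with the FIR coefficients; the output has the
#' same length as the input (implicit zero initial state). The same
#' coefficients drive the offline pipeline and the streaming path, so
#' train-time and deploy-time filtering agree exactly.
#'
#' @param x numeric series, longer than the filter.
#' @param fir a `bp_fir` from [design_bandpass()], or a bare coefficient
#'   vector.
#' @return filtered series, same length as `x`.
#' @export
filter_signal <- function(x, fir) {
  b <- if (inherits(fir, "bp_fir")) fir$coefficients else as.numeric(fir)
  n <- length(x)
  if (n <= length(b)) {
    stop(sprintf("input (%d samples) must be longer than the filter (%d taps)",
                 n, length(b)), call. = FALSE)
  }
  # causal FFT convolution: y[t] = sum_j b[j] x[t - j + 1]
  y <- stats::convolve(x, rev(b), type = "open")
  y[seq_len(n)]
}

#' Estimate the inter-signal lag by normalized cross-correlation
#'
#' Returns the integer lag in `[-max_lag, max_lag]` maximizing the Pearson
#' correlation between `ppg[t]` and `abp[t - lag]` over the overlapping
#' support; a positive lag means the PPG lags the ABP. Ties break toward the
#' smallest `|lag|`. When the argmax sits on the search bound the estimate is
#' flagged low-confidence (attribute `low_confidence`).
#'
#' @param ppg,abp equal-length numeric series.
#' @param max_lag search bound in samples, below the series length.
#' @return integer lag with attributes `correlation` and `low_confidence`.
#' @export
estimate_lag <- function(ppg, abp, max_lag = 125) {
  n <- length(ppg)
  if (n != length(abp)) stop("series must have equal length", call. = FALSE)
  if (max_lag >= n) stop("max_lag must be below the series length", call. = FALSE)
  if (stats::sd(ppg) == 0 || stats::sd(abp) == 0) {
    stop("cross-correlation undefined for zero-variance input", call. = FALSE)
  }
  lags <- seq(-max_lag, max_lag)
  lags <- lags[order(abs(lags), lags)] # smallest |lag| first for tie-breaks
  best <- -Inf
  best_lag <- 0L
  for (l in lags) {
    if (l >= 0) {
      r <- suppressWarnings(stats::cor(ppg[(1 + l):n], abp[1:(n - l)]))
    } else {
      r <- suppressWarnings(stats::cor(ppg[1:(n + l)], abp[(1 - l):n]))
    }
    if (is.finite(r) && r > best) {
      best <- r
      best_lag <- l
    }
  }
  structure(as.integer(best_lag), correlation = best,
            low_confidence = abs(best_lag) == max_lag)
}

#' Phase-match a PPG/ABP pair at a known lag
#'
#' Shifts the lagging channel back by `lag` samples and truncates both series
#' to the common support.
#'
#' @param ppg,abp equal-length series.
#' @param lag integer lag as returned by [estimate_lag()].
#' @return list with aligned `ppg` and `abp`.
#' @export
align_pair <- function(ppg, abp, lag) {
  n <- length(ppg)
  stopifnot(length(abp) == n, abs(lag) < n)
  lag <- as.integer(lag)
  if (lag > 0) {
    list(ppg = ppg[(1 + lag):n], abp = abp[1:(n - lag)])
  } else if (lag < 0) {
    list(ppg = ppg[1:(n + lag)], abp = abp[(1 - lag):n])
  } else {
    list(ppg = ppg, abp = abp)
  }
}

#' Segment a series into non-overlapping windows
#'
#' @param x numeric series.
#' @param window window length in samples (>= 2).
#' @return matrix with `floor(length(x)/window)` rows, one window per row;
#'   the tail remainder is dropped. Zero rows when `x` is shorter than one
#'   window.
#' @export
segment_signal <- function(x, window = 256) {
  check_scalar(window, "window", 2, Inf)
  window <- as.integer(window)
  n_seg <- length(x) %/% window
  if (n_seg == 0) return(matrix(numeric(0), nrow = 0, ncol = window))
  matrix(x[seq_len(n_seg * window)], nrow = n_seg, ncol = window, byrow = TRUE)
}

run_at_extreme <- function(w) {
  at <- (w == max(w)) | (w == min(w))
  r <- rle(at)
  if (any(r$values)) max(r$lengths[r$values]) else 0L
}

# Count pulse-scale maxima: interior local maxima in the upper half of the
# window's range, at least min_gap samples apart (robust to sub-mmHg noise
# ripples riding on the pulse).
count_window_extrema <- function(w, min_gap = 31L) {
  n <- length(w)
  if (n < 3) return(0L)
  interior <- 2:(n - 1)
  is_max <- w[interior] > w[interior - 1] & w[interior] >= w[interior + 1]
  idx <- interior[is_max]
  idx <- idx[w[idx] > min(w) + 0.5 * (max(w) - min(w))]
  if (!length(idx)) return(0L)
  idx <- idx[order(w[idx], decreasing = TRUE)]
  kept <- integer(0)
  for (i in idx) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  length(kept)
}

#' Screen a segment pair for artifacts
#'
#' Rule-based acceptable/unacceptable screening (a pluggable stand-in for a
#' trained artifact classifier): a window is rejected if either channel is
#' flat (sd below `flatline_sd`), saturated (`clip_run` consecutive samples at
#' the window extreme), or implies a pulse rate outside
#' `[min_rate_bpm, max_rate_bpm]` from its extrema count.
#'
#' @param ppg_window,abp_window windows of the configured length.
#' @param cfg a [preprocess_config()].
#' @return list `accepted` (logical) and `reason` (`"ok"`, `"flatline"`,
#'   `"clipping"`, or `"rate"`).
#' @export
screen_segment <- function(ppg_window, abp_window, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "bp_preprocess_config"))
  for (w in list(ppg_window, abp_window)) {
    if (pop_sd(w) < cfg$flatline_sd) {
      return(list(accepted = FALSE, reason = "flatline"))
    }
    if (run_at_extreme(w) >= cfg$clip_run) {
      return(list(accepted = FALSE, reason = "clipping"))
    }
  }
  rate <- count_window_extrema(ppg_window) /
    (length(ppg_window) / cfg$fs_hz) * 60
  if (rate < cfg$min_rate_bpm || rate > cfg$max_rate_bpm) {
    return(list(accepted = FALSE, reason = "rate"))
  }
  list(accepted = TRUE, reason = "ok")
}

#' Min-max normalization constants
#'
#' The shipped defaults are the deployment constants for the two channels:
#' PPG -2.4 / 2.9 mV, ABP 50.33 / 192.24 mmHg.
#'
#' @param x_min,x_max channel minimum and maximum (mV for PPG, mmHg for ABP).
#' @return a `bp_norm_constants`.
#' @export
norm_constants <- function(x_min, x_max) {
  check_scalar(x_min, "x_min")
  check_scalar(x_max, "x_max")
  if (x_max <= x_min) fail_field("x_max", "must exceed x_min")
  structure(list(x_min = x_min, x_max = x_max), class = "bp_norm_constants")
}

#' @rdname norm_constants
#' @export
ppg_constants <- function() norm_constants(-2.4, 2.9)

#' @rdname norm_constants
#' @export
abp_constants <- function() norm_constants(50.33, 192.24)

#' Min-max normalize / denormalize a series
#'
#' `normalize_signal` maps `x_min -> 0` and `x_max -> 1` affinely
#' (`(x - x_min) / (x_max - x_min)`); values outside the constants map outside
#' `[0, 1]` without clipping. `denormalize_signal` is the exact inverse.
#'
#' @param x numeric series (or matrix of windows).
#' @param constants a [norm_constants()].
#' @return transformed series of the same shape.
#' @export
normalize_signal <- function(x, constants) {
  stopifnot(inherits(constants, "bp_norm_constants"))
  (x - constants$x_min) / (constants$x_max - constants$x_min)
}

#' @rdname normalize_signal
#' @export
denormalize_signal <- function(x, constants) {
  stopifnot(inherits(constants, "bp_norm_constants"))
  x * (constants$x_max - constants$x_min) + constants$x_min
}

#' Fit normalization constants from accepted training segments
#'
#' Returns the extreme values over all supplied segments of one channel;
#' these constants are persisted with the trained model and reused for
#' denormalization at prediction time.
#'
#' @param segments numeric matrix (one window per row) or vector.
#' @return a [norm_constants()].
#' @export
fit_constants <- function(segments) {
  v <- as.numeric(segments)
  if (!length(v)) stop("cannot fit constants from empty input", call. = FALSE)
  norm_constants(min(v), max(v))
}

#' Run the full preprocessing pipeline over records
#'
#' filter (PPG only, causal FIR; the filter's integer group delay is
#' compensated before alignment) -> phase match per record (one integer lag
#' per record) -> segment both channels into non-overlapping windows ->
#' screen -> shuffle (seeded) -> fit constants (unless supplied) ->
#' normalize. Counts entering/leaving each stage are logged.
#'
#' @param records list of `bp_waveform_record`s.
#' @param cfg a [preprocess_config()].
#' @param constants optional list with `ppg` and `abp` [norm_constants()];
#'   fitted from the accepted segments when `NULL`.
#' @param fir optional prebuilt [design_bandpass()] result.
#' @return a `bp_segment_store`: matrices `ppg_norm`, `abp_norm` (one
#'   accepted window per row), `subject`, `segment_index`, `constants`,
#'   per-record `lags`, rejection tallies and a stage `log`.
#' @export
preprocess_records <- function(records, cfg = preprocess_config(),
                               constants = NULL, fir = NULL) {
  stopifnot(inherits(cfg, "bp_preprocess_config"), length(records) > 0)
  if (inherits(records, "bp_waveform_record")) records <- list(records)
  if (is.null(fir)) fir <- design_bandpass(cfg)
  gd <- fir$group_delay
  w <- cfg$window_samples
  ppg_all <- list()
  abp_all <- list()
  subject <- character(0)
  lags <- integer(0)
  n_segmented <- 0L
  reject <- c(flatline = 0L, clipping = 0L, rate = 0L)
  for (rec in records) {
    stopifnot(inherits(rec, "bp_waveform_record"))
    ppg_f <- filter_signal(rec$ppg, fir)
    n <- length(ppg_f)
    if (n <= gd + 2 * w) {
      stop(sprintf("record '%s' too short after group-delay compensation",
                   rec$subject_id), call. = FALSE)
    }
    # advance the filtered PPG by the known linear-phase delay
    ppg_c <- ppg_f[(gd + 1):n]
    abp_c <- rec$abp[1:(n - gd)]
    lag <- estimate_lag(ppg_c, abp_c, cfg$max_lag_samples)
    al <- align_pair(ppg_c, abp_c, lag)
    seg_p <- segment_signal(al$ppg, w)
    seg_a <- segment_signal(al$abp, w)
    n_segmented <- n_segmented + nrow(seg_p)
    keep <- logical(nrow(seg_p))
    for (i in seq_len(nrow(seg_p))) {
      v <- screen_segment(seg_p[i, ], seg_a[i, ], cfg)
      keep[i] <- v$accepted
      if (!v$accepted) reject[v$reason] <- reject[v$reason] + 1L
    }
    if (any(keep)) {
      ppg_all[[length(ppg_all) + 1L]] <- seg_p[keep, , drop = FALSE]
      abp_all[[length(abp_all) + 1L]] <- seg_a[keep, , drop = FALSE]
      subject <- c(subject, rep(rec$subject_id, sum(keep)))
    }
    lags <- c(lags, as.integer(lag))
  }
  ppg_m <- do.call(rbind, ppg_all)
  abp_m <- do.call(rbind, abp_all)
  if (is.null(ppg_m) || !nrow(ppg_m)) {
    stop("no segments survived screening", call. = FALSE)
  }
  ord <- seq_len(nrow(ppg_m))
  if (cfg$shuffle) {
    ord <- with_seed(derive_seed(cfg$seed, "shuffle"), sample(ord))
  }
  ppg_m <- ppg_m[ord, , drop = FALSE]
  abp_m <- abp_m[ord, , drop = FALSE]
  subject <- subject[ord]
  if (is.null(constants)) {
    constants <- list(ppg = fit_constants(ppg_m), abp = fit_constants(abp_m))
  }
  log <- data.frame(
    stage = c("records", "segmented", "screened", "normalized"),
    n = c(length(records), n_segmented, nrow(ppg_m), nrow(ppg_m))
  )
  structure(list(
    ppg_norm = normalize_signal(ppg_m, constants$ppg),
    abp_norm = normalize_signal(abp_m, constants$abp),
    subject = subject, segment_index = seq_len(nrow(ppg_m)),
    constants = constants, lags = lags, rejected = reject, log = log,
    window = w, fs_hz = cfg$fs_hz
  ), class = "bp_segment_store")
}

#' @export
print.bp_segment_store <- function(x, ...) {
  cat(sprintf("<segment store: %d accepted %d-sample windows from %d subjects>\n",
              nrow(x$ppg_norm), x$window, length(unique(x$subject))))
  invisible(x)
}
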