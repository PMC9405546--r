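# From predicted ABP-like waveforms to per-window SBP/DBP/MAP.
#
# The predicted normalized window is denormalized with the constants stored
# at training time, systolic peaks and diastolic troughs are located with a
# prominence- and spacing-constrained extrema detector, and the mean
# arterial pressure follows the standard one-third/two-thirds weighting
# MAP = (SBP + 2 DBP) / 3.

#' Peak-detection configuration
#'
#' @param min_distance_samples minimum spacing between detected extrema;
#'   the default 42 corresponds to 180 beats/min at 125 Hz.
#' @param min_prominence_mmHg minimum peak prominence, mmHg.
#' @param aggregate how multiple beats in a window are summarized: `"mean"`
#'   (mean of peak values / mean of trough values, robust to noise) or
#'   `"extreme"` (window max/min of the detected extrema).
#' @return a `bp_peak_config`.
#' @export
peak_config <- function(min_distance_samples = 42, min_prominence_mmHg = 10,
                        aggregate = c("mean", "extreme")) {
  check_scalar(min_distance_samples, "min_distance_samples", 1, Inf)
  check_scalar(min_prominence_mmHg, "min_prominence_mmHg", 0, Inf)
  structure(list(min_distance_samples = as.integer(min_distance_samples),
                 min_prominence_mmHg = min_prominence_mmHg,
                 aggregate = match.arg(aggregate)),
            class = "bp_peak_config")
}

#' Denormalize a predicted window to pressure units
#'
#' Exact inverse of the min-max normalization, using the constants persisted
#' from the training phase.
#'
#' @param window normalized window (vector or matrix of windows).
#' @param constants ABP [norm_constants()]; an error if missing.
#' @return pressure window in mmHg.
#' @export
denormalize_prediction <- function(window, constants) {
  if (is.null(constants)) {
    stop("no stored denormalization constants; train or supply them",
         call. = FALSE)
  }
  denormalize_signal(window, constants)
}

# Local maxima indices, collapsing flat plateaus to their midpoint.
plateau_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L
      if (j < n && x[j + 1L] < x[j]) {
        idx <- c(idx, as.integer((i + j) %/% 2L))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  idx
}

peak_prominence <- function(x, idx) {
  vapply(idx, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    higher_l <- which(left > h)
    base_l <- min(x[(if (length(higher_l)) max(higher_l) else 1L):i])
    right <- x[i:length(x)]
    higher_r <- which(right > h)
    base_r <- min(x[i:(if (length(higher_r)) i + min(higher_r) - 1L else length(x))])
    h - max(base_l, base_r)
  }, 0)
}

#' Detect systolic peaks and diastolic troughs in a pressure window
#'
#' Plateau-aware local extrema with a minimum spacing (greedy, keeping the
#' more extreme of two close neighbours) and a minimum prominence. Systolic
#' peaks must additionally lie in the upper half of the window's range and
#' diastolic troughs in the lower half, which keeps large dicrotic bumps out
#' of the systolic set. After detection, peaks and troughs are reconciled to
#' alternate: of two adjacent same-kind extrema the lesser one (for peaks;
#' the greater, for troughs) is dropped.
#'
#' @param x pressure window, mmHg.
#' @param cfg a [peak_config()].
#' @return list of integer vectors `peaks` and `troughs` (possibly empty).
#' @export
detect_extrema <- function(x, cfg = peak_config()) {
  stopifnot(inherits(cfg, "bp_peak_config"))
  if (length(x) < 2 * cfg$min_distance_samples) {
    stop("window too short for the configured extrema spacing", call. = FALSE)
  }
  mid <- (max(x) + min(x)) / 2
  pick <- function(v, lo) {
    idx <- plateau_maxima(v)
    if (!length(idx)) return(integer(0))
    idx <- idx[v[idx] >= lo]
    if (!length(idx)) return(integer(0))
    idx <- idx[peak_prominence(v, idx) >= cfg$min_prominence_mmHg]
    if (!length(idx)) return(integer(0))
    idx <- idx[order(v[idx], decreasing = TRUE)]
    kept <- integer(0)
    for (i in idx) {
      if (!length(kept) || all(abs(kept - i) >= cfg$min_distance_samples)) {
        kept <- c(kept, i)
      }
    }
    sort(kept)
  }
  peaks <- pick(x, mid)
  troughs <- pick(-x, -mid)
  # enforce alternation
  if (length(peaks) && length(troughs)) {
    ev <- data.frame(i = c(peaks, troughs),
                     kind = rep(c(1, -1), c(length(peaks), length(troughs))))
    ev <- ev[order(ev$i), ]
    keep <- rep(TRUE, nrow(ev))
    j <- 1L
    for (i in seq_len(nrow(ev))[-1]) {
      if (ev$kind[i] == ev$kind[j]) {
        a <- ev$i[j]; b <- ev$i[i]
        better_b <- if (ev$kind[i] == 1) x[b] > x[a] else x[b] < x[a]
        if (better_b) { keep[j] <- FALSE; j <- i } else keep[i] <- FALSE
      } else j <- i
    }
    ev <- ev[keep, ]
    peaks <- ev$i[ev$kind == 1]
    troughs <- ev$i[ev$kind == -1]
  }
  list(peaks = as.integer(peaks), troughs = as.integer(troughs))
}

#' Estimate SBP/DBP/MAP from one pressure window
#'
#' SBP aggregates the detected systolic peak values, DBP the diastolic trough
#' values (mean by default); MAP is exactly `(SBP + 2 DBP) / 3`. A window
#' with no usable beat is returned flagged invalid.
#'
#' @param x pressure window, mmHg.
#' @param cfg a [peak_config()].
#' @return a `bp_estimate` list: `sbp_mmHg`, `dbp_mmHg`, `map_mmHg`,
#'   `n_beats_detected`, `valid`.
#' @export
estimate_window_bp <- function(x, cfg = peak_config()) {
  ex <- detect_extrema(x, cfg)
  if (!length(ex$peaks) || !length(ex$troughs)) {
    return(structure(list(sbp_mmHg = NA_real_, dbp_mmHg = NA_real_,
                          map_mmHg = NA_real_, n_beats_detected = 0L,
                          valid = FALSE), class = "bp_estimate"))
  }
  sbp <- if (cfg$aggregate == "mean") mean(x[ex$peaks]) else max(x[ex$peaks])
  dbp <- if (cfg$aggregate == "mean") mean(x[ex$troughs]) else min(x[ex$troughs])
  structure(list(sbp_mmHg = sbp, dbp_mmHg = dbp,
                 map_mmHg = (sbp + 2 * dbp) / 3,
                 n_beats_detected = length(ex$peaks), valid = TRUE),
            class = "bp_estimate")
}

#' Predict per-window blood pressure for a set of PPG windows
#'
#' Runs the network on normalized PPG windows, denormalizes the predictions
#' with the stored ABP constants, and extracts SBP/DBP/MAP per window.
#'
#' @param model a trained `bp_model` with `constants` attached (see
#'   [run_pipeline()] / [train_model()]), or supply `constants`.
#' @param ppg_norm matrix of normalized PPG windows (one per row).
#' @param constants optional list with `abp` [norm_constants()] overriding
#'   the model's stored constants.
#' @param cfg a [peak_config()].
#' @return data.frame with one row per window: `window`, `sbp`, `dbp`, `map`,
#'   `n_beats`, `valid`.
#' @export
predict_bp <- function(model, ppg_norm, constants = NULL,
                       cfg = peak_config()) {
  consts <- if (!is.null(constants)) constants else model$constants
  if (is.null(consts$abp)) {
    stop("no stored ABP denormalization constants on the model", call. = FALSE)
  }
  pred <- predict_windows(model, ppg_norm)
  pred_mmHg <- denormalize_prediction(pred, consts$abp)
  rows <- lapply(seq_len(nrow(pred_mmHg)), function(i) {
    e <- estimate_window_bp(pred_mmHg[i, ], cfg)
    data.frame(window = i, sbp = e$sbp_mmHg, dbp = e$dbp_mmHg,
               map = e$map_mmHg, n_beats = e$n_beats_detected,
               valid = e$valid)
  })
  do.call(rbind, rows)
}
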