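# Real-time streaming inference: 30 Hz samples in, per-second SBP/DBP/MAP
# out. The stream resamples to the model rate by linear interpolation,
# filters each sample through the training-phase FIR coefficients via a
# persistent delay line, keeps the newest 256 filtered samples in a ring
# buffer, and once per second (every 125 accepted samples) normalizes the
# window, runs the network, denormalizes and reads off the pressures.
# Streaming output equals causal batch filtering of the same signal
# sample-for-sample; there is no phase alignment at deployment because no
# reference ABP exists.

#' Resample a uniformly sampled stream by linear interpolation
#'
#' Sample `k` of a rate-`r` stream is taken at time `k/r`; the output covers
#' the received span (`n` input samples produce `floor(n * to_hz / from_hz)`
#' output samples, never reaching past the last input), so the mapping is
#' streaming-safe. Target points earlier than the first input sample hold its
#' value; linear interpolation is exact on straight lines.
#'
#' @param x input samples at `from_hz`.
#' @param from_hz,to_hz input and output sampling rates.
#' @return interpolated samples at `to_hz`.
#' @export
resample_stream <- function(x, from_hz = 30, to_hz = 125) {
  check_scalar(from_hz, "from_hz", 1e-9, Inf)
  check_scalar(to_hz, "to_hz", 1e-9, Inf)
  n <- length(x)
  if (n < 2) return(numeric(0))
  t_in <- seq_len(n) / from_hz
  t_out <- seq_len(floor(n * to_hz / from_hz + 1e-9)) / to_hz
  stats::approx(t_in, x, xout = t_out, method = "linear", rule = 2)$y
}

#' Filter a signal through the per-sample streaming path
#'
#' Runs the same persistent delay line used by [push_sample()] over a whole
#' recording, one sample at a time. Its output equals causal batch filtering
#' ([filter_signal()]) of the same signal, sample for sample.
#'
#' @param x numeric series.
#' @param fir a [design_bandpass()] filter.
#' @return filtered series, same length as `x`.
#' @export
filter_signal_stream <- function(x, fir) {
  stopifnot(inherits(fir, "bp_fir"))
  b <- rev(fir$coefficients)
  ntaps <- length(b)
  delay <- numeric(ntaps)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    delay <- c(delay[-1L], x[i])
    out[i] <- sum(b * delay)
  }
  out
}

#' Initialize streaming state
#'
#' @param model trained `bp_model` with normalization constants attached, or
#'   pass `constants`.
#' @param fir the training-phase [design_bandpass()] filter.
#' @param constants optional list with `ppg` and `abp` [norm_constants()].
#' @param fs_hz model sampling rate.
#' @param emit_every_samples emission cadence once the buffer is full
#'   (default one second of samples).
#' @return a `bp_stream_state` environment.
#' @export
stream_init <- function(model, fir, constants = NULL, fs_hz = 125,
                        emit_every_samples = fs_hz) {
  stopifnot(inherits(model, "bp_model"), inherits(fir, "bp_fir"))
  consts <- if (!is.null(constants)) constants else model$constants
  if (is.null(consts$ppg) || is.null(consts$abp)) {
    stop("streaming requires stored PPG and ABP normalization constants",
         call. = FALSE)
  }
  st <- new.env(parent = emptyenv())
  st$model <- model
  st$b <- rev(fir$coefficients) # oldest-first weights for the delay line
  st$ntaps <- length(fir$coefficients)
  st$delay <- numeric(st$ntaps)
  st$window <- model$spec$window
  st$ring <- numeric(st$window)
  st$n_in_ring <- 0L
  st$n_accepted <- 0L
  st$since_emit <- 0L
  st$emit_every <- as.integer(emit_every_samples)
  st$constants <- consts
  st$peak_cfg <- peak_config()
  class(st) <- c("bp_stream_state", class(st))
  st
}

#' Push one 125 Hz PPG sample through the stream
#'
#' The sample is filtered with the persistent FIR delay line and appended to
#' the ring buffer (oldest sample dropped). Once the buffer has filled, an
#' estimate is emitted immediately and then after every `emit_every` accepted
#' samples: the current window is normalized, forwarded through the model,
#' denormalized, and summarized to SBP/DBP/MAP.
#'
#' @param state a `bp_stream_state`.
#' @param sample one raw PPG sample, mV.
#' @return `NULL`, or a `bp_estimate` when an emission fires.
#' @export
push_sample <- function(state, sample) {
  stopifnot(inherits(state, "bp_stream_state"))
  state$delay <- c(state$delay[-1L], sample)
  filtered <- sum(state$b * state$delay)
  state$ring <- c(state$ring[-1L], filtered)
  state$n_in_ring <- min(state$n_in_ring + 1L, state$window)
  state$n_accepted <- state$n_accepted + 1L
  state$since_emit <- state$since_emit + 1L
  if (state$n_in_ring < state$window) return(invisible(NULL))
  first_full <- state$n_accepted == state$window
  if (!first_full && state$since_emit < state$emit_every) {
    return(invisible(NULL))
  }
  state$since_emit <- 0L
  x <- normalize_signal(state$ring, state$constants$ppg)
  pred <- predict_windows(state$model, matrix(x, nrow = 1))
  w <- denormalize_prediction(pred[1, ], state$constants$abp)
  est <- estimate_window_bp(w, state$peak_cfg)
  est$t_s <- state$n_accepted / 125
  est
}

#' Run a recorded PPG signal through the stream
#'
#' Convenience driver: optionally resamples a low-rate recording to the
#' model rate, then pushes sample-by-sample and collects emissions.
#'
#' @param state a `bp_stream_state` from [stream_init()].
#' @param samples recorded PPG samples.
#' @param from_hz recording rate; resampled to 125 Hz when not already there.
#' @return data.frame of emissions: `t_s`, `sbp`, `dbp`, `map`, `n_beats`,
#'   `valid`.
#' @export
run_stream <- function(state, samples, from_hz = 125) {
  if (from_hz != 125) samples <- resample_stream(samples, from_hz, 125)
  out <- list()
  for (v in samples) {
    est <- push_sample(state, v)
    if (!is.null(est)) {
      out[[length(out) + 1L]] <- data.frame(
        t_s = est$t_s, sbp = est$sbp_mmHg, dbp = est$dbp_mmHg,
        map = est$map_mmHg, n_beats = est$n_beats_detected, valid = est$valid)
    }
  }
  if (!length(out)) {
    return(data.frame(t_s = numeric(0), sbp = numeric(0), dbp = numeric(0),
                      map = numeric(0), n_beats = integer(0),
                      valid = logical(0)))
  }
  do.call(rbind, out)
}
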