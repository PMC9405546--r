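# Shared fixtures, computed once per test session.

# Designing the bandpass takes ~0.5 s; reuse one instance.
fixture_fir <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- design_bandpass(preprocess_config())
    val
  }
})

# Magnitude response computed independently of the package internals.
dft_mag <- function(b, f, fs) {
  k <- seq_along(b) - 1
  vapply(f, function(ff) Mod(sum(b * exp(-2i * pi * ff * k / fs))), 0)
}

# A small noiseless record with known constant truth.
fixture_record <- function(sbp = 130, dbp = 85, hr = 60, duration_s = 10,
                           lag = 0, noise = 0, seed = 11, jitter = 0.05) {
  cfg <- sim_config(duration_s = duration_s, ppg_lag_samples = lag,
                    ppg_noise_sd = noise, seed = seed)
  n_beats <- ceiling(duration_s * hr / 60) + 2
  beats <- replicate(n_beats, beat_params(heart_rate_bpm = hr, sbp_mmHg = sbp,
                                          dbp_mmHg = dbp,
                                          hrv_jitter_frac = jitter),
                     simplify = FALSE)
  abp <- generate_abp(beats, cfg)
  truth <- attr(abp, "beat_truth")
  n <- as.integer(duration_s * cfg$fs_hz)
  abp <- as.numeric(abp)[seq_len(n)]
  ppg <- derive_ppg(abp, cfg)
  rec <- waveform_record("T001", cfg$fs_hz, ppg, abp,
                         truth[truth$start_sample <= n, ])
  rec
}

# A preprocessed store from a small cohort; memoized per parameter set.
fixture_store <- local({
  cache <- list()
  function(n_subjects = 4, duration_s = 60, seed = 21, noise = 0.05) {
    key <- paste(n_subjects, duration_s, seed, noise)
    if (is.null(cache[[key]])) {
      cfg <- sim_config(duration_s = duration_s, ppg_noise_sd = noise,
                        seed = seed)
      recs <- generate_cohort(n_subjects, cfg = cfg)
      cache[[key]] <<- preprocess_records(recs, preprocess_config(),
                                          fir = fixture_fir())
    }
    cache[[key]]
  }
})

# Independent brute-force extrema scan (oracle for beat counting): local
# maxima with a minimum spacing, found by exhaustive comparison.
brute_peaks <- function(x, min_gap, min_height = -Inf) {
  idx <- which(vapply(seq_along(x), function(i) {
    if (i == 1 || i == length(x)) return(FALSE)
    x[i] > x[i - 1] && x[i] >= x[i + 1] && x[i] >= min_height
  }, TRUE))
  keep <- integer(0)
  for (i in idx[order(x[idx], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  sort(keep)
}
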