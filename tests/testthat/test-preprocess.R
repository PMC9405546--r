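test_that("bandpass response meets the template at key frequencies", {
  fir <- fixture_fir()
  b <- fir$coefficients
  expect_lt(dft_mag(b, 0, 125), 0.01)      # DC rejected
  expect_gt(dft_mag(b, 4, 125), 0.89)      # mid-passband
  expect_lt(dft_mag(b, 4, 125), 1.12)
  expect_lt(dft_mag(b, 30, 125), 0.01)     # upper stopband
  # linear phase: symmetric taps, integer group delay
  expect_equal(b, rev(b))
  expect_identical(fir$group_delay, (length(b) - 1L) %/% 2L)
})

test_that("filtering is causal, linear and length-preserving", {
  fir <- fixture_fir()
  nt <- length(fir$coefficients)
  x <- rep(1, nt + 2000)
  y <- filter_signal(x, fir)
  expect_length(y, length(x))
  expect_lt(max(abs(y[(nt + 1):length(y)])), 0.01) # DC steady state

  set.seed(1)
  z <- rnorm(nt + 500)
  expect_equal(filter_signal(3.7 * z, fir), 3.7 * filter_signal(z, fir),
               tolerance = 1e-9)

  t <- (0:(nt + 3000)) / 125
  s <- sin(2 * pi * 2 * t)
  ys <- filter_signal(s, fir)
  steady <- ys[(2 * nt):length(ys)]
  expect_equal(max(abs(steady)), 1, tolerance = 0.15)

  expect_error(filter_signal(rnorm(10), fir), "longer")
})

test_that("cross-correlation lag estimation is exact with bounded search", {
  rec <- fixture_record(duration_s = 10, lag = 10, noise = 0)
  l <- estimate_lag(rec$ppg, rec$abp, 125)
  expect_identical(as.integer(l), 10L)
  expect_false(attr(l, "low_confidence"))

  l0 <- estimate_lag(rec$abp, rec$abp, 50)
  expect_identical(as.integer(l0), 0L)

  # lag beyond the bound: search is clipped and flagged
  rec2 <- fixture_record(duration_s = 10, lag = 45, noise = 0)
  lc <- estimate_lag(rec2$ppg, rec2$abp, 40)
  expect_lte(abs(as.integer(lc)), 40L)
  expect_true(attr(lc, "low_confidence"))

  expect_error(estimate_lag(rep(1, 100), rnorm(100), 10), "zero-variance")
})

test_that("segmentation drops the tail remainder", {
  expect_identical(nrow(segment_signal(rnorm(1000), 256)), 3L)
  x <- rnorm(256)
  s1 <- segment_signal(x, 256)
  expect_identical(nrow(s1), 1L)
  expect_equal(s1[1, ], x)
  expect_identical(nrow(segment_signal(rnorm(255), 256)), 0L)
})

test_that("quality screening fires the expected rules", {
  cfg <- preprocess_config()
  zero_w <- rep(0, 256)
  v <- screen_segment(zero_w, zero_w, cfg)
  expect_false(v$accepted)
  expect_identical(v$reason, "flatline")

  rec <- fixture_record(hr = 60, duration_s = 10, noise = 0)
  pw <- segment_signal(rec$ppg, 256)[2, ]
  aw <- segment_signal(rec$abp, 256)[2, ]
  expect_true(screen_segment(pw, aw, cfg)$accepted)

  clipped <- aw
  clipped[100:149] <- max(aw) # 50 samples pinned at the extreme
  vc <- screen_segment(pw, clipped, cfg)
  expect_false(vc$accepted)
  expect_identical(vc$reason, "clipping")
})

test_that("normalization uses the shipped constants and inverts exactly", {
  expect_equal(normalize_signal(2.9, ppg_constants()), 1)
  expect_equal(normalize_signal(-2.4, ppg_constants()), 0)
  expect_equal(normalize_signal(50.33, abp_constants()), 0)
  expect_equal(denormalize_signal(1, abp_constants()), 192.24)

  set.seed(2)
  x <- rnorm(500, 100, 30)
  expect_equal(denormalize_signal(normalize_signal(x, abp_constants()),
                                  abp_constants()), x, tolerance = 1e-9)
  expect_error(norm_constants(5, 5), "x_max")
})

test_that("constants are fitted as the extremes of the training segments", {
  m <- rbind(seq(60, 180, length.out = 10), seq(70, 150, length.out = 10))
  c1 <- fit_constants(m)
  expect_equal(c1$x_min, 60)
  expect_equal(c1$x_max, 180)
  expect_error(fit_constants(matrix(numeric(0), 0, 0)), "empty")
  expect_error(fit_constants(rep(5, 10)), "x_max")
})

test_that("pipeline aligns pairs and normalizes the training set into [0,1]", {
  store <- fixture_store()
  expect_gte(min(store$ppg_norm), 0)
  expect_lte(max(store$ppg_norm), 1)
  expect_gte(min(store$abp_norm), 0)
  expect_lte(max(store$abp_norm), 1)
  expect_true(all(diff(store$log$n) <= 0 | store$log$stage[-1] == "segmented"))

  # the estimated per-record lags absorb the simulator's injected delay
  expect_true(all(store$lags == 25))

  # after alignment, per-window PPG and ABP pulse peaks coincide closely
  ppg_w <- denormalize_signal(store$ppg_norm, store$constants$ppg)
  abp_w <- denormalize_signal(store$abp_norm, store$constants$abp)
  offs <- vapply(seq_len(min(40, nrow(ppg_w))), function(i) {
    pp <- brute_peaks(ppg_w[i, ], 42)
    pa <- brute_peaks(abp_w[i, ], 42)
    if (!length(pp) || !length(pa)) return(NA_real_)
    mean(vapply(pa, function(j) min(abs(pp - j)), 0))
  }, 0)
  expect_lte(median(offs, na.rm = TRUE), 2)
})

test_that("lag recoverability holds across the admissible range", {
  for (L in c(0L, 7L, 60L, 125L)) {
    rec <- fixture_record(duration_s = 12, lag = L, noise = 0, seed = 50 + L)
    expect_identical(as.integer(estimate_lag(rec$ppg, rec$abp, 125)), L)
  }
})
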