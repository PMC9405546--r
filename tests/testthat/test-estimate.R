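test_that("denormalization inverts the stored training constants", {
  expect_equal(denormalize_prediction(rep(1, 256), abp_constants()),
               rep(192.24, 256))
  expect_equal(denormalize_prediction(rep(0, 256), abp_constants()),
               rep(50.33, 256))
  set.seed(3)
  w <- runif(256)
  expect_equal(normalize_signal(denormalize_prediction(w, abp_constants()),
                                abp_constants()), w, tolerance = 1e-9)
  expect_error(denormalize_prediction(w, NULL), "constants")
})

test_that("extrema detection handles sinusoids, ramps and plateaus", {
  t <- (0:255) / 125
  s <- 100 + 20 * sin(2 * pi * 2 * t) # 2 Hz, +/-20 mmHg
  ex <- detect_extrema(s, peak_config())
  expect_length(ex$peaks, 4)
  expect_length(ex$troughs, 4)
  # alternation
  merged <- sort(c(ex$peaks, ex$troughs))
  kinds <- merged %in% ex$peaks
  expect_true(all(diff(kinds) != 0))
  # against the closed form: sin = 1 at t = 1/8 + k/2 s (between-sample)
  expected <- (0.125 + 0.5 * (0:3)) * 125 + 1
  for (p in ex$peaks) expect_lte(min(abs(expected - p)), 1.5)

  ramp <- seq(60, 180, length.out = 256)
  exr <- detect_extrema(ramp, peak_config())
  expect_length(exr$peaks, 0)
  expect_length(exr$troughs, 0)

  expect_error(detect_extrema(rnorm(10), peak_config()), "too short")
})

test_that("simulator windows yield peaks at the true beat maxima", {
  rec <- fixture_record(sbp = 130, dbp = 85, hr = 60, noise = 0)
  w <- segment_signal(rec$abp, 256)[2, ]
  ex <- detect_extrema(w, peak_config())
  expect_identical(length(ex$peaks), 2L) # HR 60: two beats per 2.048 s
  truth_peaks <- brute_peaks(w, min_gap = 50, min_height = 120)
  for (p in ex$peaks) expect_lte(min(abs(truth_peaks - p)), 2)
})

test_that("window estimates satisfy the MAP identity and ordering", {
  rec <- fixture_record(sbp = 120, dbp = 60, hr = 70, noise = 0)
  w <- segment_signal(rec$abp, 256)[2, ]
  e <- estimate_window_bp(w, peak_config())
  expect_true(e$valid)
  expect_equal(e$sbp_mmHg, 120, tolerance = 1)
  expect_equal(e$dbp_mmHg, 60, tolerance = 1)
  expect_equal(e$map_mmHg, (e$sbp_mmHg + 2 * e$dbp_mmHg) / 3)
  expect_equal(e$map_mmHg, 80, tolerance = 1)
  expect_lte(e$dbp_mmHg, e$map_mmHg)
  expect_lte(e$map_mmHg, e$sbp_mmHg)

  rec2 <- fixture_record(sbp = 150, dbp = 75, hr = 70, noise = 0, seed = 12)
  e2 <- estimate_window_bp(segment_signal(rec2$abp, 256)[2, ], peak_config())
  expect_equal(e2$map_mmHg, 100, tolerance = 1)

  # a featureless window is flagged invalid, not an error
  e3 <- estimate_window_bp(seq(60, 180, length.out = 256), peak_config())
  expect_false(e3$valid)
  expect_identical(e3$n_beats_detected, 0L)
})

test_that("reference ABP windows recover the simulator truth within 1 mmHg", {
  for (s in list(c(130, 85), c(110, 70), c(165, 102))) {
    rec <- fixture_record(sbp = s[1], dbp = s[2], hr = 72, noise = 0,
                          seed = 60 + s[1])
    segs <- segment_signal(rec$abp, 256)
    for (i in 2:(nrow(segs) - 1)) {
      e <- estimate_window_bp(segs[i, ], peak_config())
      expect_true(e$valid)
      expect_lt(abs(e$sbp_mmHg - s[1]), 1)
      expect_lt(abs(e$dbp_mmHg - s[2]), 1)
    }
  }
})

test_that("predict_bp runs the full window path with stored constants", {
  store <- fixture_store()
  m <- build_network(network_spec(), seed = 4)
  m$constants <- store$constants
  out <- predict_bp(m, store$ppg_norm[1:3, , drop = FALSE])
  expect_identical(nrow(out), 3L)
  expect_true(all(c("sbp", "dbp", "map", "n_beats", "valid") %in% names(out)))
  m$constants <- NULL
  expect_error(predict_bp(m, store$ppg_norm[1:2, ]), "constants")
})
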