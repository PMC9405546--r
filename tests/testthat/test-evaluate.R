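test_that("error statistics match hand arithmetic", {
  es <- error_stats(c(1, 2, 4), c(1, 2, 3))
  expect_equal(es$me, 1 / 3)
  expect_equal(es$mae, 1 / 3)
  expect_equal(es$rmse, 1 / sqrt(3))
  expect_equal(es$std, sqrt(1 / 3 - 1 / 9))

  set.seed(8)
  base <- rnorm(50, 120, 15)
  ident <- error_stats(base, base)
  expect_equal(c(ident$me, ident$mae, ident$std, ident$rmse), rep(0, 4))
  off <- error_stats(base + 2, base)
  expect_equal(c(off$me, off$mae, off$std, off$rmse), c(2, 2, 0, 2))
  expect_equal(off$r, 1)

  expect_error(error_stats(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("rmse^2 = me^2 + std^2 on random error vectors", {
  for (s in 1:20) {
    set.seed(s)
    es <- error_stats(rnorm(40, 120, 20), rnorm(40, 118, 18))
    expect_lt(abs(es$rmse^2 - es$me^2 - es$std^2), 1e-9)
    expect_lte(es$mae, es$rmse + 1e-12)
    expect_true(es$r >= -1 && es$r <= 1)
  }
})

test_that("BHS grading reproduces the published comparison table", {
  # (pct<=5, pct<=10, pct<=15) -> printed grade, per method and quantity
  rows <- list(
    list(c(76.95, 95.72, 99.97), "A"), # BiLSTM DBP
    list(c(50.07, 76.40, 90.39), "B"), # ResLSTM SBP
    list(c(65.66, 89.77, 96.63), "A"),
    list(c(65.14, 89.58, 96.61), "A"),
    list(c(51.00, 81.00, 94.00), "B"), # multi-sensor regression SBP
    list(c(62.00, 92.00, 99.00), "A"),
    list(c(60.00, 90.00, 98.00), "A"),
    list(c(67.66, 89.82, 96.82), "A"), # CNN-LSTM SBP
    list(c(82.79, 96.12, 99.09), "A"),
    list(c(84.21, 97.38, 99.58), "A"),
    list(c(46.30, 72.10, 85.20), "C"), # RDAE SBP (uncalibrated)
    list(c(73.20, 91.90, 97.00), "A"),
    list(c(76.00, 92.30, 96.90), "A"),
    list(c(76.21, 93.66, 97.71), "A"), # U-net SBP
    list(c(93.51, 98.70, 99.46), "A"),
    list(c(64.20, 87.85, 95.26), "A"), # Squeeze U-net SBP
    list(c(95.58, 99.35, 99.67), "A"),
    list(c(90.80, 98.61, 99.51), "A")
  )
  for (r in rows) {
    expect_identical(bhs_grade(r[[1]][1], r[[1]][2], r[[1]][3]), r[[2]])
  }
  expect_identical(bhs_grade(100, 100, 100), "A")
  expect_identical(bhs_grade(10, 20, 30), "D")
  expect_error(bhs_grade(80, 70, 90), "nondecreasing")
})

test_that("BHS grading is monotone in every percentage", {
  rank <- c(A = 1, B = 2, C = 3, D = 4)
  grid <- seq(30, 100, by = 10)
  for (p5 in grid) for (p10 in grid) for (p15 in grid) {
    if (p5 > p10 || p10 > p15) next
    g <- rank[bhs_grade(p5, p10, p15)]
    for (bump in list(c(5, 0, 0), c(0, 5, 0), c(0, 0, 5))) {
      q <- pmin(c(p5, p10, p15) + bump, 100)
      if (q[1] > q[2] || q[2] > q[3]) next
      expect_lte(rank[bhs_grade(q[1], q[2], q[3])], g)
    }
  }
})

test_that("AAMI verdicts reproduce the published comparison rows", {
  # printed (ME, STD) with n = 100 where the cohort satisfies the standard
  expect_false(aami_check(4.638, 14.505, 100)$passed) # BiLSTM SBP
  expect_true(aami_check(3.155, 6.442, 100)$passed)   # BiLSTM DBP
  expect_false(aami_check(-0.11, 9.99, 100)$passed)   # ResLSTM SBP
  expect_true(aami_check(-0.03, 6.36, 100)$passed)
  expect_true(aami_check(-0.01, 6.29, 100)$passed)
  expect_false(aami_check(1.447, 10.375, 100)$passed) # RDAE SBP
  expect_true(aami_check(-0.417, 5.504, 100)$passed)
  expect_true(aami_check(0.204, 5.130, 100)$passed)
  expect_true(aami_check(-1.002, 4.78, 100)$passed)   # this model, SBP
  expect_true(aami_check(0.019, 2.98, 100)$passed)
  expect_true(aami_check(-0.315, 3.21, 100)$passed)

  # bounds
  expect_false(aami_check(0, 9, 100)$passed)  # std
  expect_false(aami_check(6, 1, 100)$passed)  # mean error
  expect_false(aami_check(0, 1, 50)$passed)   # subject count
  expect_true(aami_check(-4.9, 8, 85)$passed) # |me| convention, edge values
})

test_that("stage classification and confusion follow the thresholds", {
  expect_identical(as.character(classify_stage(119, "sbp")), "normal")
  expect_identical(as.character(classify_stage(120, "sbp")), "prehypertension")
  expect_identical(as.character(classify_stage(145, "sbp")), "stage1")
  expect_identical(as.character(classify_stage(160, "sbp")), "stage2")
  expect_identical(as.character(classify_stage(79, "dbp")), "normal")
  expect_identical(as.character(classify_stage(100, "dbp")), "stage2")

  ref <- c(110, 125, 150, 170, 115, 142)
  sc <- stage_confusion(ref, ref, "sbp")
  expect_true(all(sc$accuracy_pct[!is.na(sc$accuracy_pct)] == 100))

  sc2 <- stage_confusion(rep(130, 4), rep(150, 4), "sbp")
  expect_identical(unname(sc2$accuracy_pct["stage1"]), 0)
  expect_identical(unname(sc2$counts["stage1", "prehypertension"]), 4L)

  # mixed hand case against a brute-force tally
  pred <- c(118, 125, 141, 162, 138, 155)
  refx <- c(121, 125, 139, 160, 152, 148)
  sc3 <- stage_confusion(pred, refx, "sbp")
  tally <- table(classify_stage(refx, "sbp"), classify_stage(pred, "sbp"))
  expect_equal(unclass(sc3$counts), unclass(tally), ignore_attr = TRUE)
  expect_equal(rowSums(sc3$counts), rowSums(tally), ignore_attr = TRUE)
})

test_that("Bland-Altman bias and limits follow the definitions", {
  x <- c(100, 110, 120, 130)
  ba0 <- bland_altman(x, x)
  expect_equal(c(ba0$bias, ba0$loa_low, ba0$loa_high), c(0, 0, 0))
  ba3 <- bland_altman(x + 3, x)
  expect_equal(c(ba3$bias, ba3$loa_low, ba3$loa_high), c(3, 3, 3))
  ba <- bland_altman(c(99, 121), c(100, 120))
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa_low, -1.96)
  expect_equal(ba$loa_high, 1.96)
  expect_error(bland_altman(1, 1), "two pairs")
})
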