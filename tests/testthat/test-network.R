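# Independent per-layer parameter enumeration: recompute what each layer
# must hold from its recorded geometry alone (kernel * in-channels *
# out-channels + bias for convolutions; two vectors of out-channels for the
# channel-affine layers) and compare with the arrays actually allocated.
enumerate_parameters <- function(model) {
  total <- 0
  for (nd in model$nodes) {
    total <- total + switch(nd$op,
      conv = nd$k * nd$Cin * nd$Cout + nd$Cout,
      tconv = nd$k * nd$Cin * nd$Cout + nd$Cout,
      affine = 2 * nd$Cout,
      0)
  }
  total
}

test_that("fire modules expand channels and hold the hand-counted parameters", {
  bld <- bpnet:::new_builder(64L)
  inp <- bpnet:::add_input(bld, 64L, 64L)
  fid <- bpnet:::add_fire(bld, inp, fire_spec(16, 64, 64), "fire")
  out <- bld$nodes[[fid]]
  expect_identical(out$Cout, 128L) # e11 + e33: feature vectors double
  expect_identical(out$Lout, 64L)  # length preserved
  n_par <- sum(vapply(bld$nodes, function(nd) {
    sum(vapply(c("W", "b"), function(p) length(nd[[p]]), 0L))
  }, 0L))
  expect_identical(n_par, 5264L) # 64*16+16 + 16*64+64 + 16*3*64+64
})

test_that("fire specification rejects a too-wide squeeze", {
  expect_error(fire_spec(128, 64, 64), "s11")
  expect_error(fire_spec(0, 64, 64), "s11")
  expect_silent(fire_spec(127, 64, 64))
})

test_that("mismatched concatenation lengths fail at build time with names", {
  bld <- bpnet:::new_builder(32L)
  inp <- bpnet:::add_input(bld, 32L, 4L)
  p <- bpnet:::add_pool(bld, inp, name = "enc/pool")
  expect_error(bpnet:::add_concat(bld, p, inp, name = "bad/concat"),
               "bad/concat.*enc/pool", perl = TRUE)
})

test_that("parameter totals match the per-layer enumeration for both variants", {
  m_can <- build_network(network_spec(variant = "canonical"), seed = 1)
  m_rec <- build_network(network_spec(variant = "reconciled"), seed = 1)
  expect_identical(count_parameters(m_can), 818321L)
  expect_identical(count_parameters(m_rec), 819921L)
  expect_equal(enumerate_parameters(m_can), count_parameters(m_can))
  expect_equal(enumerate_parameters(m_rec), count_parameters(m_rec))
  # single conv sanity case: k3, 1 channel in, 64 filters, bias
  s <- model_summary(m_rec)
  expect_identical(s$parameters[s$layer == "cb1/conv"], 256L)
})

test_that("the decoder restores the input length (closure over window sizes)", {
  for (w in c(256L, 128L)) {
    m <- build_network(network_spec(window = w), seed = 2)
    y <- predict_windows(m, matrix(runif(w), 1))
    expect_identical(dim(y), c(1L, w))
  }
  expect_error(network_spec(window = 200), "divisible by 16")
})

test_that("forward inference has the shape, determinism and zero contracts", {
  m <- build_network(network_spec(), seed = 3)
  x <- matrix(runif(10 * 256), 10)
  y1 <- predict_windows(m, x)
  expect_identical(dim(y1), c(10L, 256L))
  expect_identical(y1, predict_windows(m, x)) # dropout off: bit-identical

  # zeroed final layer forces an all-zero output
  m0 <- m
  out_id <- m$output
  m0$nodes[[out_id]]$W[] <- 0
  m0$nodes[[out_id]]$b[] <- 0
  expect_true(all(predict_windows(m0, x) == 0))

  expect_error(predict_windows(m, matrix(runif(10), 1)), "window length")
})

test_that("analytic gradients match finite differences on a mixed graph", {
  set.seed(42)
  bld <- bpnet:::new_builder(16L)
  inp <- bpnet:::add_input(bld, 16L, 1L)
  c1 <- bpnet:::add_conv(bld, inp, 3, 2, 4, name = "c1")
  p1 <- bpnet:::add_pool(bld, c1)
  f1 <- bpnet:::add_fire(bld, p1, fire_spec(2, 3, 3), "f1")
  a1 <- bpnet:::add_affine(bld, f1)
  t1 <- bpnet:::add_tconv(bld, a1, 2, 1, 5, name = "t1")
  cc <- bpnet:::add_concat(bld, t1, p1)
  t2 <- bpnet:::add_tconv(bld, cc, 2, 2, 3, name = "t2")
  u1 <- bpnet:::add_upsample(bld, t2)
  c2 <- bpnet:::add_concat(bld, u1, inp)
  o <- bpnet:::add_conv(bld, c2, 3, 1, 1, name = "out")
  m <- structure(list(spec = list(leaky_slope = 0.3, window = 16L),
                      nodes = bld$nodes, output = o, input = inp),
                 class = "bp_model")
  N <- 2
  X <- matrix(rnorm(N * 16), ncol = 1)
  Yt <- matrix(rnorm(N * 16), ncol = 1)
  loss_of <- function(mm) {
    fwd <- bpnet:::net_forward(mm, X, N, training = FALSE, keep_cache = FALSE)
    mean((fwd$acts[[mm$output]] - Yt)^2)
  }
  fwd <- bpnet:::net_forward(m, X, N, training = TRUE)
  pred <- fwd$acts[[m$output]]
  g <- bpnet:::net_backward(m, fwd, 2 * (pred - Yt) / length(pred), N)
  eps <- 1e-6
  worst <- 0
  for (id in seq_along(m$nodes)) {
    for (p in c("W", "b", "gamma", "beta")) {
      if (is.null(m$nodes[[id]][[p]])) next
      gp <- g[[id]][[paste0("d", p)]]
      arr <- m$nodes[[id]][[p]]
      for (j in sample(length(arr), min(4, length(arr)))) {
        m2 <- m; m2$nodes[[id]][[p]][j] <- arr[j] + eps
        m3 <- m; m3$nodes[[id]][[p]][j] <- arr[j] - eps
        fd <- (loss_of(m2) - loss_of(m3)) / (2 * eps)
        worst <- max(worst, abs(fd - gp[j]) /
                       max(1e-8, abs(fd) + abs(gp[j])))
      }
    }
  }
  expect_lt(worst, 1e-5)
})
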