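# The 1D Squeeze U-net: a U-net encoder-decoder over 256-sample windows whose
# convolutional workhorses are SqueezeNet fire modules (a channel-reducing
# 1-wide "squeeze" convolution feeding parallel 1-wide and 3-wide "expand"
# convolutions whose outputs are concatenated). The encoder halves the
# sequence length four times (stride-2 input convolution plus three max
# pools); the decoder restores it with two stride-2 transposed convolutions
# and two nearest-neighbour upsamplings, with skip concatenations at every
# scale. Leaky-rectifier activation follows every convolution.

#' Fire module filter specification
#'
#' @param s11 squeeze filter count (1-wide convolution).
#' @param e11 expand filter count, 1-wide branch.
#' @param e33 expand filter count, 3-wide branch.
#' @return a `bp_fire_spec`. The squeeze width must be strictly below the
#'   total expansion width (`s11 < e11 + e33`).
#' @export
fire_spec <- function(s11, e11, e33) {
  for (f in c("s11", "e11", "e33")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v)) {
      fail_field(f, "must be a positive integer")
    }
  }
  if (s11 >= e11 + e33) {
    fail_field("s11", sprintf("squeeze width (%d) must be < e11 + e33 (%d)",
                              s11, e11 + e33))
  }
  structure(list(s11 = as.integer(s11), e11 = as.integer(e11),
                 e33 = as.integer(e33)), class = "bp_fire_spec")
}

#' Network topology specification
#'
#' The canonical topology follows the published block layout: CB1 stride-2
#' convolution (256 -> 128 samples, 64 filters), CB2 max pool, CB3/CB4 two
#' fire modules plus a max pool each, CB5 four fire modules, dropout, and a
#' two-stage stride-1 transposed-convolution/concatenate/fire bottleneck;
#' then EB1/EB2 (stride-2 transposed convolution, skip concatenation, fire)
#' and EB3/EB4 (2x upsampling, skip concatenation in EB3, 3-wide
#' convolution). `variant = "reconciled"` additionally inserts trainable
#' per-channel scale-and-offset (affine normalization) layers at three
#' decoder-entry points (512, 256 and 32 channels); this is the declared
#' configuration whose trainable parameter total matches the published count
#' of 819,921 (the canonical build counts 818,321).
#'
#' @param window input window length; must be divisible by 16 so the decoder
#'   restores it exactly.
#' @param leaky_slope negative-slope coefficient of the leaky rectifier.
#' @param dropout_rate dropout probability applied at the deepest encoder
#'   stage during training.
#' @param variant `"reconciled"` (default) or `"canonical"`.
#' @return a `bp_network_spec` including the per-block fire specifications.
#' @export
network_spec <- function(window = 256, leaky_slope = 0.3, dropout_rate = 0.5,
                         variant = c("reconciled", "canonical")) {
  check_scalar(window, "window", 16, Inf)
  if (window %% 16 != 0) {
    fail_field("window", "must be divisible by 16 (total down/up-sampling factor)")
  }
  check_scalar(leaky_slope, "leaky_slope", 0, 1)
  check_scalar(dropout_rate, "dropout_rate", 0, 1 - 1e-9)
  variant <- match.arg(variant)
  structure(list(
    window = as.integer(window), leaky_slope = leaky_slope,
    dropout_rate = dropout_rate, variant = variant,
    fires = list(
      cb3 = fire_spec(16, 64, 64), cb4 = fire_spec(32, 128, 128),
      cb5a = fire_spec(48, 192, 192), cb5b = fire_spec(64, 256, 256),
      neck1 = fire_spec(48, 192, 192), neck2 = fire_spec(32, 128, 128),
      eb1 = fire_spec(16, 64, 64), eb2 = fire_spec(16, 32, 32)
    )
  ), class = "bp_network_spec")
}

# ---- graph construction -----------------------------------------------------

new_builder <- function(window) {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$window <- window
  env
}

add_node <- function(bld, node) {
  node$id <- length(bld$nodes) + 1L
  bld$nodes[[node$id]] <- node
  node$id
}

node_out <- function(bld, id) bld$nodes[[id]]

add_input <- function(bld, L, C) {
  add_node(bld, list(op = "input", from = integer(0), Lout = L, Cout = C,
                     name = "input"))
}

init_w <- function(n_in, n_out, fan_in) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / fan_in)), n_in, n_out)
}

add_conv <- function(bld, from, k, stride, filters, act = TRUE, name = "conv") {
  src <- node_out(bld, from)
  g <- conv_geometry(src$Lout, k, stride)
  add_node(bld, list(op = "conv", from = from, k = as.integer(k),
                     stride = as.integer(stride), pad_left = g$pad_left,
                     Lin = src$Lout, Lout = g$Lout, Cin = src$Cout,
                     Cout = as.integer(filters), act = act, name = name,
                     W = init_w(k * src$Cout, filters, k * src$Cout),
                     b = numeric(filters)))
}

add_tconv <- function(bld, from, k, stride, filters, act = TRUE,
                      name = "tconv") {
  src <- node_out(bld, from)
  g <- tconv_geometry(src$Lout, k, stride)
  add_node(bld, list(op = "tconv", from = from, k = as.integer(k),
                     stride = as.integer(stride), Lfull = g$Lfull,
                     crop_start = g$crop_start, Lin = src$Lout, Lout = g$Lout,
                     Cin = src$Cout, Cout = as.integer(filters), act = act,
                     name = name,
                     W = init_w(k * src$Cout, filters, k * src$Cout),
                     b = numeric(filters)))
}

add_pool <- function(bld, from, name = "maxpool") {
  src <- node_out(bld, from)
  if (src$Lout %% 2 != 0) {
    stop(sprintf("structural error at %s: length %d not divisible by 2",
                 name, src$Lout), call. = FALSE)
  }
  add_node(bld, list(op = "pool", from = from, Lin = src$Lout,
                     Lout = src$Lout %/% 2L, Cin = src$Cout, Cout = src$Cout,
                     name = name))
}

add_upsample <- function(bld, from, name = "upsample") {
  src <- node_out(bld, from)
  add_node(bld, list(op = "upsample", from = from, Lin = src$Lout,
                     Lout = src$Lout * 2L, Cin = src$Cout, Cout = src$Cout,
                     name = name))
}

add_concat <- function(bld, a, b, name = "concat") {
  na <- node_out(bld, a)
  nb <- node_out(bld, b)
  if (na$Lout != nb$Lout) {
    stop(sprintf(
      "structural error: concat '%s' joins unequal lengths (%s: %d, %s: %d)",
      name, na$name, na$Lout, nb$name, nb$Lout), call. = FALSE)
  }
  add_node(bld, list(op = "concat", from = c(a, b), Lout = na$Lout,
                     C1 = na$Cout, Cout = na$Cout + nb$Cout, name = name))
}

add_dropout <- function(bld, from, rate, name = "dropout") {
  src <- node_out(bld, from)
  add_node(bld, list(op = "dropout", from = from, rate = rate,
                     Lout = src$Lout, Cin = src$Cout, Cout = src$Cout,
                     name = name))
}

add_affine <- function(bld, from, name = "chan_affine") {
  src <- node_out(bld, from)
  add_node(bld, list(op = "affine", from = from, Lout = src$Lout,
                     Cin = src$Cout, Cout = src$Cout, name = name,
                     gamma = rep(1, src$Cout), beta = numeric(src$Cout)))
}

#' Append a fire module to a network under construction
#'
#' Squeeze (1-wide convolution to `s11` channels), two parallel expands
#' (1-wide to `e11`, 3-wide to `e33`) applied to the squeeze output, then
#' channel concatenation: output channels `e11 + e33`, sequence length
#' preserved. Leaky-rectifier activation follows each convolution.
#' @noRd
add_fire <- function(bld, from, spec, name = "fire") {
  stopifnot(inherits(spec, "bp_fire_spec"))
  sq <- add_conv(bld, from, k = 1, stride = 1, filters = spec$s11,
                 name = paste0(name, "/squeeze"))
  e1 <- add_conv(bld, sq, k = 1, stride = 1, filters = spec$e11,
                 name = paste0(name, "/expand1"))
  e3 <- add_conv(bld, sq, k = 3, stride = 1, filters = spec$e33,
                 name = paste0(name, "/expand3"))
  add_concat(bld, e1, e3, name = paste0(name, "/concat"))
}

#' Build the 1D Squeeze U-net
#'
#' Constructs the full network graph from a [network_spec()] with
#' seed-controlled He-style weight initialization. Structural invariants
#' (every concatenation joins equal lengths; every fire satisfies
#' `s11 < e11 + e33`; the decoder restores the input length) are enforced at
#' build time.
#'
#' @param spec a [network_spec()].
#' @param seed integer seed for weight initialization.
#' @return a `bp_model` handle: the node graph, the spec, and slots for the
#'   normalization constants persisted at training time.
#' @export
build_network <- function(spec = network_spec(), seed = 1L) {
  stopifnot(inherits(spec, "bp_network_spec"))
  with_seed(derive_seed(seed, "init"), {
    bld <- new_builder(spec$window)
    f <- spec$fires
    rec <- identical(spec$variant, "reconciled")
    inp <- add_input(bld, spec$window, 1L)
    x01 <- add_conv(bld, inp, k = 3, stride = 2, filters = 64, name = "cb1/conv")
    x02 <- add_pool(bld, x01, name = "cb2/pool")
    x03 <- add_fire(bld, x02, f$cb3, "cb3/fire1")
    x04 <- add_fire(bld, x03, f$cb3, "cb3/fire2")
    x05 <- add_pool(bld, x04, name = "cb3/pool")
    x06 <- add_fire(bld, x05, f$cb4, "cb4/fire1")
    x07 <- add_fire(bld, x06, f$cb4, "cb4/fire2")
    x08 <- add_pool(bld, x07, name = "cb4/pool")
    x09 <- add_fire(bld, x08, f$cb5a, "cb5/fire1")
    x10 <- add_fire(bld, x09, f$cb5a, "cb5/fire2")
    x11 <- add_fire(bld, x10, f$cb5b, "cb5/fire3")
    x12 <- add_fire(bld, x11, f$cb5b, "cb5/fire4")
    deep <- if (rec) add_affine(bld, x12, "cb5/affine") else x12
    drp <- add_dropout(bld, deep, spec$dropout_rate, "cb5/dropout")
    t1 <- add_tconv(bld, drp, k = 2, stride = 1, filters = 192, name = "neck/tconv1")
    c1 <- add_concat(bld, t1, x10, "neck/concat1")
    f13 <- add_fire(bld, c1, f$neck1, "neck/fire1")
    t2 <- add_tconv(bld, f13, k = 2, stride = 1, filters = 128, name = "neck/tconv2")
    c2 <- add_concat(bld, t2, x08, "neck/concat2")
    f14 <- add_fire(bld, c2, f$neck2, "neck/fire2")
    junc <- if (rec) add_affine(bld, f14, "neck/affine") else f14
    t3 <- add_tconv(bld, junc, k = 2, stride = 2, filters = 64, name = "eb1/tconv")
    c3 <- add_concat(bld, t3, x05, "eb1/concat")
    f15 <- add_fire(bld, c3, f$eb1, "eb1/fire")
    t4 <- add_tconv(bld, f15, k = 2, stride = 2, filters = 32, name = "eb2/tconv")
    t4a <- if (rec) add_affine(bld, t4, "eb2/affine") else t4
    c4 <- add_concat(bld, t4a, x02, "eb2/concat")
    f16 <- add_fire(bld, c4, f$eb2, "eb2/fire")
    u1 <- add_upsample(bld, f16, "eb3/upsample")
    c5 <- add_concat(bld, u1, x01, "eb3/concat")
    e3c <- add_conv(bld, c5, k = 3, stride = 1, filters = 64, name = "eb3/conv")
    u2 <- add_upsample(bld, e3c, "eb4/upsample")
    out <- add_conv(bld, u2, k = 3, stride = 1, filters = 1, name = "eb4/conv")
    out_node <- node_out(bld, out)
    if (out_node$Lout != spec$window || out_node$Cout != 1L) {
      stop("structural error: decoder failed to restore the input window",
           call. = FALSE)
    }
    structure(list(spec = spec, nodes = bld$nodes, output = out,
                   input = inp, constants = NULL),
              class = "bp_model")
  })
}

#' Count trainable parameters
#'
#' Sums the lengths of every trainable array in the model (convolution and
#' transposed-convolution kernels and biases, channel-affine scales and
#' offsets). Deterministic and independent of any input.
#'
#' @param model a `bp_model`.
#' @return integer total.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "bp_model"))
  total <- 0L
  for (nd in model$nodes) {
    for (p in c("W", "b", "gamma", "beta")) {
      if (!is.null(nd[[p]])) total <- total + length(nd[[p]])
    }
  }
  total
}

#' Per-layer summary table
#'
#' @param model a `bp_model`.
#' @return data.frame of layer name, operation, output length, output
#'   channels, and parameter count; attribute `total` holds the sum.
#' @export
model_summary <- function(model) {
  stopifnot(inherits(model, "bp_model"))
  rows <- lapply(model$nodes, function(nd) {
    n_par <- sum(vapply(c("W", "b", "gamma", "beta"),
                        function(p) length(nd[[p]]), 0L))
    data.frame(layer = nd$name, op = nd$op, out_length = nd$Lout,
               out_channels = nd$Cout, parameters = n_par)
  })
  out <- do.call(rbind, rows)
  attr(out, "total") <- sum(out$parameters)
  out
}

# ---- forward / backward over the graph -------------------------------------

# Internal full forward pass. X is (N*window, 1); returns activations and
# per-node caches for backprop when `training`.
net_forward <- function(model, X, N, training = FALSE, keep_cache = training) {
  slope <- model$spec$leaky_slope
  acts <- vector("list", length(model$nodes))
  caches <- if (keep_cache) vector("list", length(model$nodes))
  for (nd in model$nodes) {
    out <- switch(nd$op,
      input = list(Y = X),
      conv = conv_fwd(nd, acts[[nd$from]], N, slope),
      tconv = tconv_fwd(nd, acts[[nd$from]], N, slope),
      pool = pool_fwd(nd, acts[[nd$from]], N),
      upsample = upsample_fwd(nd, acts[[nd$from]], N),
      concat = list(Y = cbind(acts[[nd$from[1]]], acts[[nd$from[2]]])),
      dropout = {
        Xin <- acts[[nd$from]]
        if (training && nd$rate > 0) {
          mask <- matrix(stats::runif(length(Xin)) >= nd$rate, nrow(Xin))
          list(Y = Xin * mask / (1 - nd$rate), mask = mask)
        } else list(Y = Xin)
      },
      affine = affine_fwd(nd, acts[[nd$from]]),
      stop("unknown op ", nd$op)
    )
    acts[[nd$id]] <- out$Y
    if (keep_cache) {
      out$Y <- NULL
      caches[[nd$id]] <- out
    }
  }
  list(acts = acts, caches = caches)
}

# Internal backward pass; returns per-node gradient lists (dW/db or
# dgamma/dbeta) given the gradient of the loss w.r.t. the output activation.
net_backward <- function(model, fwd, dOut, N, training = TRUE) {
  slope <- model$spec$leaky_slope
  nn <- length(model$nodes)
  dacts <- vector("list", nn)
  grads <- vector("list", nn)
  dacts[[model$output]] <- dOut
  for (id in rev(seq_len(nn))) {
    nd <- model$nodes[[id]]
    dY <- dacts[[id]]
    if (is.null(dY)) next
    if (nd$op == "input") next
    res <- switch(nd$op,
      conv = {
        r <- conv_bwd(nd, fwd$caches[[id]], dY, N, slope)
        grads[[id]] <- list(dW = r$dW, db = r$db)
        list(r$dX)
      },
      tconv = {
        r <- tconv_bwd(nd, fwd$caches[[id]], dY, N, slope)
        grads[[id]] <- list(dW = r$dW, db = r$db)
        list(r$dX)
      },
      pool = list(pool_bwd(nd, fwd$caches[[id]], dY, N)$dX),
      upsample = list(upsample_bwd(nd, dY, N)$dX),
      concat = list(dY[, seq_len(nd$C1), drop = FALSE],
                    dY[, (nd$C1 + 1L):nd$Cout, drop = FALSE]),
      dropout = {
        m <- fwd$caches[[id]]$mask
        list(if (!is.null(m)) dY * m / (1 - nd$rate) else dY)
      },
      affine = {
        r <- affine_bwd(nd, fwd$caches[[id]], dY)
        grads[[id]] <- list(dgamma = r$dgamma, dbeta = r$dbeta)
        list(r$dX)
      }
    )
    for (j in seq_along(nd$from)) {
      src <- nd$from[j]
      dacts[[src]] <- if (is.null(dacts[[src]])) res[[j]] else
        dacts[[src]] + res[[j]]
    }
    dacts[[id]] <- NULL # free
  }
  grads
}

# Flatten a batch matrix (n_windows x window) into the (N*L, 1) layout.
batch_to_input <- function(xb) {
  matrix(as.numeric(t(xb)), ncol = 1L)
}

#' Forward inference on a batch of normalized PPG windows
#'
#' Deterministic (dropout disabled): two calls with identical weights and
#' input produce bit-identical output.
#'
#' @param model a `bp_model`.
#' @param x numeric matrix (one window per row) or a single window vector;
#'   window length must match the spec.
#' @return matrix of predicted normalized ABP-like windows, same shape.
#' @export
predict_windows <- function(model, x) {
  stopifnot(inherits(model, "bp_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$spec$window) {
    stop(sprintf("window length %d does not match the network input (%d)",
                 ncol(x), model$spec$window), call. = FALSE)
  }
  N <- nrow(x)
  out <- matrix(0, N, ncol(x))
  # modest batching keeps peak memory bounded
  chunk <- 32L
  for (s in seq(1L, N, by = chunk)) {
    idx <- s:min(s + chunk - 1L, N)
    fwd <- net_forward(model, batch_to_input(x[idx, , drop = FALSE]),
                       length(idx), training = FALSE, keep_cache = FALSE)
    out[idx, ] <- matrix(fwd$acts[[model$output]], nrow = length(idx),
                         byrow = TRUE)
  }
  out
}

#' @export
print.bp_model <- function(x, ...) {
  cat(sprintf("<1D Squeeze U-net: window %d, %s variant, %s parameters%s>\n",
              x$spec$window, x$spec$variant,
              format(count_parameters(x), big.mark = ","),
              if (is.null(x$constants)) "" else ", trained constants attached"))
  invisible(x)
}
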