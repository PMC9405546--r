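# 1D layer primitives: forward and backward passes.
#
# Tensors are stored as dense matrices of shape (N*L, C): N batch items, L
# time samples, C channels; the row for sample t of item n is (n-1)*L + t.
# Every layer's geometry (input/output length and channels, kernel, stride,
# padding) is frozen at build time, so the only runtime variable is N. All
# heavy arithmetic is BLAS matrix multiplication (im2col convolutions).

rows_at <- function(N, L, t_sel) {
  rep((seq_len(N) - 1L) * L, each = length(t_sel)) + t_sel
}

leaky_fwd <- function(Z, slope) {
  neg <- Z < 0
  if (anyNA(neg)) neg[is.na(neg)] <- FALSE # let non-finite values propagate
  A <- Z
  A[neg] <- slope * Z[neg]
  list(A = A, neg = neg)
}

leaky_bwd <- function(dA, neg, slope) {
  dZ <- dA
  dZ[neg] <- slope * dA[neg]
  dZ
}

# 'same'-padding bookkeeping for stride-s convolution: output length
# ceil(L/s), total padding split with the extra sample on the right.
conv_geometry <- function(Lin, k, stride) {
  Lout <- as.integer(ceiling(Lin / stride))
  pad_total <- max((Lout - 1L) * stride + k - Lin, 0L)
  list(Lout = Lout, pad_left = pad_total %/% 2L)
}

conv_fwd <- function(node, X, N, slope) {
  k <- node$k
  Cin <- node$Cin
  pointwise <- k == 1L && node$stride == 1L
  if (pointwise) {
    Xcol <- X # 1-wide stride-1 convolution: im2col is the identity
  } else {
    Xcol <- matrix(0, N * node$Lout, k * Cin)
    for (d in seq_len(k)) {
      tin <- (seq_len(node$Lout) - 1L) * node$stride + d - node$pad_left
      ok <- tin >= 1L & tin <= node$Lin
      if (!any(ok)) next
      Xcol[rows_at(N, node$Lout, which(ok)), ((d - 1L) * Cin + 1L):(d * Cin)] <-
        X[rows_at(N, node$Lin, tin[ok]), , drop = FALSE]
    }
  }
  Z <- Xcol %*% node$W
  Z <- Z + rep(node$b, each = nrow(Z))
  if (node$act) {
    a <- leaky_fwd(Z, slope)
    list(Y = a$A, Xcol = Xcol, neg = a$neg)
  } else {
    list(Y = Z, Xcol = Xcol)
  }
}

conv_bwd <- function(node, cache, dY, N, slope) {
  dZ <- if (node$act) leaky_bwd(dY, cache$neg, slope) else dY
  dW <- crossprod(cache$Xcol, dZ)
  db <- colSums(dZ)
  dXcol <- tcrossprod(dZ, node$W)
  k <- node$k
  Cin <- node$Cin
  if (k == 1L && node$stride == 1L) {
    return(list(dX = dXcol, dW = dW, db = db))
  }
  dX <- matrix(0, N * node$Lin, Cin)
  for (d in seq_len(k)) {
    tin <- (seq_len(node$Lout) - 1L) * node$stride + d - node$pad_left
    ok <- tin >= 1L & tin <= node$Lin
    if (!any(ok)) next
    ri <- rows_at(N, node$Lin, tin[ok])
    dX[ri, ] <- dX[ri, , drop = FALSE] +
      dXcol[rows_at(N, node$Lout, which(ok)), ((d - 1L) * Cin + 1L):(d * Cin),
            drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

# Transposed convolution. Full output length (Lin-1)*stride + k is cropped to
# Lin*stride, dropping floor((k-stride)/2) head samples (for k=2 the crop is
# one tail sample at stride 1, none at stride 2).
tconv_geometry <- function(Lin, k, stride) {
  Lfull <- (Lin - 1L) * stride + k
  Lout <- Lin * stride
  list(Lfull = Lfull, Lout = Lout, crop_start = 1L + max((k - stride) %/% 2L, 0L))
}

tconv_fwd <- function(node, X, N, slope) {
  Cout <- node$Cout
  Zfull <- matrix(0, N * node$Lfull, Cout)
  for (d in seq_len(node$k)) {
    Wd <- node$W[((d - 1L) * node$Cin + 1L):(d * node$Cin), , drop = FALSE]
    tout <- (seq_len(node$Lin) - 1L) * node$stride + d
    rf <- rows_at(N, node$Lfull, tout)
    Zfull[rf, ] <- Zfull[rf, , drop = FALSE] + X %*% Wd
  }
  keep <- rows_at(N, node$Lfull, node$crop_start:(node$crop_start + node$Lout - 1L))
  Z <- Zfull[keep, , drop = FALSE]
  Z <- Z + rep(node$b, each = nrow(Z))
  if (node$act) {
    a <- leaky_fwd(Z, slope)
    list(Y = a$A, X = X, neg = a$neg)
  } else {
    list(Y = Z, X = X)
  }
}

tconv_bwd <- function(node, cache, dY, N, slope) {
  dZ <- if (node$act) leaky_bwd(dY, cache$neg, slope) else dY
  db <- colSums(dZ)
  dZfull <- matrix(0, N * node$Lfull, node$Cout)
  keep <- rows_at(N, node$Lfull, node$crop_start:(node$crop_start + node$Lout - 1L))
  dZfull[keep, ] <- dZ
  dX <- matrix(0, N * node$Lin, node$Cin)
  dW <- matrix(0, node$k * node$Cin, node$Cout)
  for (d in seq_len(node$k)) {
    cols <- ((d - 1L) * node$Cin + 1L):(d * node$Cin)
    Wd <- node$W[cols, , drop = FALSE]
    tout <- (seq_len(node$Lin) - 1L) * node$stride + d
    rf <- rows_at(N, node$Lfull, tout)
    dZd <- dZfull[rf, , drop = FALSE]
    dX <- dX + tcrossprod(dZd, Wd)
    dW[cols, ] <- crossprod(cache$X, dZd)
  }
  list(dX = dX, dW = dW, db = db)
}

pool_fwd <- function(node, X, N) {
  r1 <- rows_at(N, node$Lin, seq(1L, node$Lin, by = 2L))
  r2 <- rows_at(N, node$Lin, seq(2L, node$Lin, by = 2L))
  o1 <- X[r1, , drop = FALSE]
  o2 <- X[r2, , drop = FALSE]
  first <- o1 >= o2
  list(Y = pmax(o1, o2), first = first)
}

pool_bwd <- function(node, cache, dY, N) {
  dX <- matrix(0, N * node$Lin, node$Cin)
  r1 <- rows_at(N, node$Lin, seq(1L, node$Lin, by = 2L))
  r2 <- rows_at(N, node$Lin, seq(2L, node$Lin, by = 2L))
  dX[r1, ] <- dY * cache$first
  dX[r2, ] <- dY * !cache$first
  list(dX = dX)
}

upsample_fwd <- function(node, X, N) {
  idx <- rows_at(N, node$Lin, rep(seq_len(node$Lin), each = 2L))
  list(Y = X[idx, , drop = FALSE])
}

upsample_bwd <- function(node, dY, N) {
  r1 <- rows_at(N, node$Lout, seq(1L, node$Lout, by = 2L))
  r2 <- rows_at(N, node$Lout, seq(2L, node$Lout, by = 2L))
  list(dX = dY[r1, , drop = FALSE] + dY[r2, , drop = FALSE])
}

affine_fwd <- function(node, X) {
  list(Y = sweep(sweep(X, 2L, node$gamma, "*"), 2L, node$beta, "+"), X = X)
}

affine_bwd <- function(node, cache, dY) {
  list(dX = sweep(dY, 2L, node$gamma, "*"),
       dgamma = colSums(cache$X * dY), dbeta = colSums(dY))
}
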