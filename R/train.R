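# Training protocol: seeded 70/15/15 split, Adam on mean squared error,
# early stopping on validation loss with best-epoch checkpointing.

#' Training configuration
#'
#' Defaults follow the published protocol: 70/15/15 split, learning rate
#' 1e-4, batch size 10, mean-squared-error loss, early stopping after six
#' consecutive epochs without validation improvement.
#'
#' @param split fractions (train, validation, test); must sum to 1.
#' @param learning_rate Adam step size.
#' @param batch_size windows per gradient step.
#' @param patience_epochs consecutive non-improving epochs before stopping.
#' @param max_epochs hard epoch cap.
#' @param min_delta improvement threshold for early stopping (0: any strict
#'   decrease counts).
#' @param subject_split keep all of a subject's segments in one partition
#'   (leakage-free evaluation); default `FALSE` splits at segment level.
#' @param seed seed for the shuffle, batching and dropout.
#' @return a `bp_train_config`.
#' @export
train_config <- function(split = c(0.70, 0.15, 0.15), learning_rate = 1e-4,
                         batch_size = 10, patience_epochs = 6,
                         max_epochs = 30, min_delta = 0,
                         subject_split = FALSE, seed = 1L) {
  if (length(split) != 3 || any(split <= 0) || abs(sum(split) - 1) > 1e-8) {
    fail_field("split", "must be 3 positive fractions summing to 1")
  }
  check_scalar(learning_rate, "learning_rate", 1e-12, 1)
  check_scalar(batch_size, "batch_size", 1, Inf)
  check_scalar(patience_epochs, "patience_epochs", 1, Inf)
  check_scalar(max_epochs, "max_epochs", 1, Inf)
  check_scalar(min_delta, "min_delta", 0, Inf)
  structure(list(split = split, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience_epochs = as.integer(patience_epochs),
                 max_epochs = as.integer(max_epochs), min_delta = min_delta,
                 subject_split = isTRUE(subject_split),
                 seed = as.integer(seed)),
            class = "bp_train_config")
}

subset_store <- function(store, idx) {
  list(x = store$ppg_norm[idx, , drop = FALSE],
       y = store$abp_norm[idx, , drop = FALSE],
       subject = store$subject[idx])
}

#' Split a segment store into train/validation/test partitions
#'
#' Segments are shuffled with the seeded generator, then partitioned by the
#' configured fractions (disjoint and exhaustive up to rounding). In
#' subject-level mode whole subjects are assigned greedily so that no subject
#' id spans two partitions.
#'
#' @param store a `bp_segment_store` from [preprocess_records()].
#' @param cfg a [train_config()].
#' @return list of three lists (`train`, `val`, `test`), each with `x`
#'   (PPG windows), `y` (ABP windows) and `subject`.
#' @export
split_dataset <- function(store, cfg = train_config()) {
  stopifnot(inherits(store, "bp_segment_store"),
            inherits(cfg, "bp_train_config"))
  n <- nrow(store$ppg_norm)
  if (n < 3) stop("need at least 3 segments to split", call. = FALSE)
  if (!cfg$subject_split) {
    ord <- with_seed(derive_seed(cfg$seed, "split"), sample(n))
    n_tr <- round(cfg$split[1] * n)
    n_va <- round(cfg$split[2] * n)
    n_te <- n - n_tr - n_va
    if (min(n_tr, n_va, n_te) < 1) {
      stop("a partition is empty after rounding", call. = FALSE)
    }
    parts <- list(train = ord[seq_len(n_tr)],
                  val = ord[n_tr + seq_len(n_va)],
                  test = ord[n_tr + n_va + seq_len(n_te)])
  } else {
    subjects <- unique(store$subject)
    ord_s <- with_seed(derive_seed(cfg$seed, "split-subjects"),
                       sample(subjects))
    counts <- table(store$subject)[ord_s]
    cum <- cumsum(as.numeric(counts)) / n
    part_of <- cut(cum, breaks = c(0, cfg$split[1],
                                   cfg$split[1] + cfg$split[2], 1 + 1e-9),
                   labels = c("train", "val", "test"))
    assign_of <- stats::setNames(as.character(part_of), ord_s)
    parts <- lapply(c(train = "train", val = "val", test = "test"),
                    function(p) which(assign_of[store$subject] == p))
    if (any(vapply(parts, length, 0L) < 1)) {
      stop("a partition is empty; too few subjects for a subject-level split",
           call. = FALSE)
    }
  }
  lapply(parts, function(idx) subset_store(store, idx))
}

#' Early-stopping bookkeeping
#'
#' Pure helper implementing the stopping rule: training stops after
#' `patience` consecutive epochs without a validation-loss improvement of
#' more than `min_delta`; the checkpointed epoch is the loss minimum.
#'
#' @param val_losses numeric per-epoch validation losses, in order.
#' @param patience consecutive non-improving epochs tolerated.
#' @param min_delta strict improvement threshold.
#' @return list `stopped_epoch` (NA if never triggered) and `best_epoch`.
#' @export
early_stop_epoch <- function(val_losses, patience, min_delta = 0) {
  best <- Inf
  best_epoch <- NA_integer_
  bad <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best - min_delta) {
      best <- val_losses[e]
      best_epoch <- e
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) {
        return(list(stopped_epoch = e, best_epoch = best_epoch))
      }
    }
  }
  list(stopped_epoch = NA_integer_, best_epoch = best_epoch)
}

mse_loss <- function(pred, target) mean((pred - target)^2)

snapshot_params <- function(model) {
  lapply(model$nodes, function(nd) nd[c("W", "b", "gamma", "beta")])
}

restore_params <- function(model, snap) {
  for (id in seq_along(model$nodes)) {
    for (p in c("W", "b", "gamma", "beta")) {
      if (!is.null(snap[[id]][[p]])) model$nodes[[id]][[p]] <- snap[[id]][[p]]
    }
  }
  model
}

eval_loss <- function(model, data, batch = 32L) {
  n <- nrow(data$x)
  tot <- 0
  for (s in seq(1L, n, by = batch)) {
    idx <- s:min(s + batch - 1L, n)
    fwd <- net_forward(model, batch_to_input(data$x[idx, , drop = FALSE]),
                       length(idx), training = FALSE, keep_cache = FALSE)
    tot <- tot + sum((fwd$acts[[model$output]] -
                        batch_to_input(data$y[idx, , drop = FALSE]))^2)
  }
  tot / (n * ncol(data$x))
}

#' Train the network
#'
#' Adam (moment decays 0.9/0.999, epsilon 1e-7) on mean squared error between
#' predicted and reference normalized ABP windows. After each epoch the
#' validation loss is evaluated; the best-epoch weights are checkpointed and
#' restored at the end. Training stops early after `patience_epochs`
#' consecutive epochs without improvement, or at `max_epochs`. Fully seeded:
#' identical configuration and data reproduce the loss trace.
#'
#' @param model a `bp_model` from [build_network()].
#' @param train,val partitions from [split_dataset()] (lists with `x`, `y`).
#' @param cfg a [train_config()].
#' @param checkpoint_path optional file path; when given, the best model is
#'   serialized there with `saveRDS`.
#' @return a `bp_train_report`: `history` (per-epoch train/validation loss),
#'   `best_epoch`, `stopped_epoch`, `checkpoint` path (or `NULL`), `optimizer`
#'   settings, and `model`, the trained network with best-epoch weights
#'   restored.
#' @export
train_model <- function(model, train, val, cfg = train_config(),
                        checkpoint_path = NULL) {
  stopifnot(inherits(model, "bp_model"), inherits(cfg, "bp_train_config"))
  if (!nrow(train$x) || !nrow(val$x)) {
    stop("training and validation partitions must be nonempty", call. = FALSE)
  }
  lr <- cfg$learning_rate
  beta1 <- 0.9
  beta2 <- 0.999
  adam_eps <- 1e-7
  mstate <- lapply(model$nodes, function(nd) {
    out <- list()
    for (p in c("W", "b", "gamma", "beta")) {
      if (!is.null(nd[[p]])) out[[p]] <- list(m = nd[[p]] * 0, v = nd[[p]] * 0)
    }
    out
  })
  step <- 0L
  n_tr <- nrow(train$x)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf
  best_snap <- NULL
  best_epoch <- NA_integer_
  bad <- 0L
  stopped <- NA_integer_
  with_seed(derive_seed(cfg$seed, "train"), {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(n_tr)
      ep_loss <- 0
      for (s in seq(1L, n_tr, by = cfg$batch_size)) {
        idx <- ord[s:min(s + cfg$batch_size - 1L, n_tr)]
        N <- length(idx)
        X <- batch_to_input(train$x[idx, , drop = FALSE])
        Yt <- batch_to_input(train$y[idx, , drop = FALSE])
        fwd <- net_forward(model, X, N, training = TRUE)
        pred <- fwd$acts[[model$output]]
        loss <- mse_loss(pred, Yt)
        if (!is.finite(loss)) {
          stop(sprintf("training diverged (non-finite loss at epoch %d)",
                       epoch), call. = FALSE)
        }
        ep_loss <- ep_loss + loss * N
        grads <- net_backward(model, fwd, 2 * (pred - Yt) / length(Yt), N)
        step <- step + 1L
        corr <- sqrt(1 - beta2^step) / (1 - beta1^step)
        for (id in seq_along(model$nodes)) {
          gid <- grads[[id]]
          if (is.null(gid)) next
          for (p in names(mstate[[id]])) {
            g <- gid[[paste0("d", p)]]
            st <- mstate[[id]][[p]]
            st$m <- beta1 * st$m + (1 - beta1) * g
            st$v <- beta2 * st$v + (1 - beta2) * g * g
            mstate[[id]][[p]] <- st
            model$nodes[[id]][[p]] <- model$nodes[[id]][[p]] -
              lr * corr * st$m / (sqrt(st$v) + adam_eps)
          }
        }
      }
      val_loss <- eval_loss(model, val)
      history[epoch, ] <- list(epoch, ep_loss / n_tr, val_loss)
      if (val_loss < best_val - cfg$min_delta) {
        best_val <- val_loss
        best_epoch <- epoch
        best_snap <- snapshot_params(model)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= cfg$patience_epochs) {
          stopped <- epoch
          break
        }
      }
    }
  })
  if (!is.null(best_snap)) model <- restore_params(model, best_snap)
  report <- structure(list(
    history = history, best_epoch = best_epoch,
    stopped_epoch = if (is.na(stopped)) nrow(history) else stopped,
    early_stopped = !is.na(stopped),
    best_val_loss = best_val, checkpoint = checkpoint_path,
    optimizer = list(name = "adam", learning_rate = lr, beta1 = beta1,
                     beta2 = beta2, epsilon = adam_eps),
    model = model
  ), class = "bp_train_report")
  if (!is.null(checkpoint_path)) {
    saveRDS(list(model = model, report = report[setdiff(names(report), "model")]),
            checkpoint_path)
  }
  report
}

#' @export
print.bp_train_report <- function(x, ...) {
  cat(sprintf(
    "<training report: %d epochs (best %d, val MSE %.3g)%s>\n",
    nrow(x$history), x$best_epoch, x$best_val_loss,
    if (x$early_stopped) ", early-stopped" else ""))
  invisible(x)
}
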