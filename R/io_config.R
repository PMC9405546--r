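# Waveform/CSV readers and writers, pipeline configuration and the run log.

#' Write waveform records to CSV files
#'
#' One CSV per subject with columns `t`, `ppg_mv`, `abp_mmhg`, plus a
#' `truth.csv` of per-beat ground truth (`subject`, `beat_index`, `sbp`,
#' `dbp`) when available.
#'
#' @param records list of `bp_waveform_record`s.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_waveforms <- function(records, dir) {
  if (inherits(records, "bp_waveform_record")) records <- list(records)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  truth_rows <- list()
  for (rec in records) {
    stopifnot(inherits(rec, "bp_waveform_record"))
    df <- data.frame(t = (seq_along(rec$ppg) - 1) / rec$fs_hz,
                     ppg_mv = rec$ppg, abp_mmhg = rec$abp)
    p <- file.path(dir, paste0(rec$subject_id, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
    if (!is.null(rec$truth)) {
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        subject = rec$subject_id, beat_index = rec$truth$beat,
        sbp = rec$truth$sbp, dbp = rec$truth$dbp)
    }
  }
  if (length(truth_rows)) {
    tp <- file.path(dir, "truth.csv")
    utils::write.csv(do.call(rbind, truth_rows), tp, row.names = FALSE)
    paths <- c(paths, tp)
  }
  invisible(paths)
}

#' Read waveform records from CSV
#'
#' Accepts a single CSV file or a directory of them (schema `t`, `ppg_mv`,
#' `abp_mmhg`; a `truth.csv` in the directory is attached per subject). The
#' sampling rate is inferred from the time column and the timestamps checked
#' for regularity.
#'
#' @param path file or directory.
#' @return list of `bp_waveform_record`s.
#' @export
read_waveforms <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.csv$", full.names = TRUE)
  } else path
  files <- files[basename(files) != "truth.csv"]
  if (!length(files)) stop("no waveform CSV files at ", path, call. = FALSE)
  truth <- NULL
  if (dir.exists(path) && file.exists(file.path(path, "truth.csv"))) {
    truth <- utils::read.csv(file.path(path, "truth.csv"))
  }
  lapply(files, function(f) {
    df <- utils::read.csv(f)
    need <- c("t", "ppg_mv", "abp_mmhg")
    if (!all(need %in% names(df))) {
      stop(sprintf("'%s' lacks required columns (%s)", f,
                   paste(setdiff(need, names(df)), collapse = ", ")),
           call. = FALSE)
    }
    dt <- diff(df$t)
    if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * stats::median(dt) + 1e-9) {
      stop(sprintf("'%s' has irregular timestamps", f), call. = FALSE)
    }
    sid <- sub("\\.csv$", "", basename(f))
    tr <- if (!is.null(truth)) {
      tt <- truth[truth$subject == sid, ]
      if (nrow(tt)) data.frame(beat = tt$beat_index, start_sample = tt$beat_index,
                               n_samples = NA_integer_, sbp = tt$sbp,
                               dbp = tt$dbp) else NULL
    } else NULL
    waveform_record(sid, 1 / stats::median(dt), df$ppg_mv, df$abp_mmhg, tr)
  })
}

default_pipeline_config <- function() {
  list(
    simulate = list(n_subjects = 24, stage_mix = c(0.25, 0.25, 0.25, 0.25),
                    fs_hz = 125, duration_s = 180, ppg_lag_samples = 25,
                    ppg_noise_sd = 0.05),
    preprocess = list(passband_hz = c(0.5, 8), transition_hz = c(0.25, 2),
                      stopband_db = 40, window_samples = 256,
                      max_lag_samples = 125, flatline_sd = 0.01,
                      clip_run = 25, min_rate_bpm = 30, max_rate_bpm = 180,
                      shuffle = TRUE),
    network = list(window = 256, leaky_slope = 0.3, dropout_rate = 0.5,
                   variant = "reconciled"),
    train = list(split = c(0.70, 0.15, 0.15), learning_rate = 1e-4,
                 batch_size = 10, patience_epochs = 6, max_epochs = 10,
                 min_delta = 0, subject_split = FALSE),
    estimate = list(min_distance_samples = 42, min_prominence_mmHg = 10,
                    aggregate = "mean"),
    stream = list(input_hz = 30, emit_every_samples = 125),
    seed = 1
  )
}

check_known_keys <- function(cfg, template, path = "") {
  extra <- setdiff(names(cfg), names(template))
  if (length(extra)) {
    stop(sprintf("unknown config key%s at '%s': %s (valid: %s)",
                 if (length(extra) > 1) "s" else "", path,
                 paste(extra, collapse = ", "),
                 paste(names(template), collapse = ", ")), call. = FALSE)
  }
  for (k in names(cfg)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]]))) {
      check_known_keys(as.list(cfg[[k]]), template[[k]],
                       paste0(path, "/", k))
    }
  }
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      merge_config(defaults[[k]], user[[k]])
    } else user[[k]]
  }
  defaults
}

#' Load / save a pipeline configuration
#'
#' The YAML configuration mirrors the module sections (simulate, preprocess,
#' network, train, estimate, stream) plus a global `seed`; absent keys take
#' the shipped defaults (the published settings: 125 Hz, 0.5-8 Hz passband,
#' 256-sample windows, learning rate 1e-4, batch 10, patience 6, 70/15/15
#' split, the printed normalization constants). Unknown keys are rejected
#' with the list of valid ones; section constructors validate values.
#'
#' @param path YAML file (for `load_config`, may be empty or absent sections).
#' @return a validated `bp_pipeline_config` list.
#' @export
load_config <- function(path) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_pipeline_config()
  check_known_keys(user, defaults)
  cfg <- merge_config(defaults, user)
  validate_pipeline_config(cfg)
}

#' @rdname load_config
#' @param cfg a pipeline configuration list.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

validate_pipeline_config <- function(cfg) {
  # constructors perform the field validation
  sim_config(fs_hz = cfg$simulate$fs_hz, duration_s = cfg$simulate$duration_s,
             ppg_lag_samples = cfg$simulate$ppg_lag_samples,
             ppg_noise_sd = cfg$simulate$ppg_noise_sd, seed = cfg$seed)
  do.call(preprocess_config,
          c(cfg$preprocess, list(fs_hz = cfg$simulate$fs_hz, seed = cfg$seed)))
  do.call(network_spec, cfg$network)
  do.call(train_config, c(cfg$train, list(seed = cfg$seed)))
  do.call(peak_config, cfg$estimate)
  structure(cfg, class = "bp_pipeline_config")
}

#' Run the full pipeline from a single configuration
#'
#' simulate -> preprocess -> split -> build + train -> predict on the test
#' partition -> evaluate. Reference pressures come from feeding the reference
#' ABP windows through the same estimation stage as the predictions. All
#' stage seeds derive from the single global seed.
#'
#' @param cfg a `bp_pipeline_config` (see [load_config()]); defaults used
#'   when `NULL`.
#' @param verbose print stage progress.
#' @return list with the trained `model`, the `report` ([train_model()]),
#'   `store`, predictions, references and the `evaluation`
#'   ([evaluate_bp()]), plus a `run_log` of stage events.
#' @export
run_pipeline <- function(cfg = NULL, verbose = FALSE) {
  if (is.null(cfg)) cfg <- validate_pipeline_config(default_pipeline_config())
  stopifnot(inherits(cfg, "bp_pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  log <- list()
  note <- function(stage, detail) {
    log[[length(log) + 1L]] <<- data.frame(
      time = format(Sys.time(), "%H:%M:%S"), stage = stage, detail = detail)
  }

  scfg <- sim_config(fs_hz = cfg$simulate$fs_hz,
                     duration_s = cfg$simulate$duration_s,
                     ppg_lag_samples = cfg$simulate$ppg_lag_samples,
                     ppg_noise_sd = cfg$simulate$ppg_noise_sd,
                     seed = derive_seed(cfg$seed, "simulate"))
  say("simulating %d subjects x %gs", cfg$simulate$n_subjects,
      cfg$simulate$duration_s)
  records <- generate_cohort(cfg$simulate$n_subjects, cfg$simulate$stage_mix,
                             scfg)
  note("simulate", sprintf("%d records", length(records)))

  pcfg <- do.call(preprocess_config,
                  c(cfg$preprocess, list(fs_hz = cfg$simulate$fs_hz,
                                         seed = derive_seed(cfg$seed, "preprocess"))))
  fir <- design_bandpass(pcfg)
  store <- preprocess_records(records, pcfg, fir = fir)
  say("preprocessed: %d accepted segments", nrow(store$ppg_norm))
  note("preprocess", sprintf("%d segments accepted", nrow(store$ppg_norm)))

  tcfg <- do.call(train_config,
                  c(cfg$train, list(seed = derive_seed(cfg$seed, "train"))))
  parts <- split_dataset(store, tcfg)
  note("split", sprintf("%d/%d/%d", nrow(parts$train$x), nrow(parts$val$x),
                        nrow(parts$test$x)))

  model <- build_network(do.call(network_spec, cfg$network),
                         seed = derive_seed(cfg$seed, "network"))
  say("training %s parameters", format(count_parameters(model), big.mark = ","))
  report <- train_model(model, parts$train, parts$val, tcfg)
  model <- report$model
  model$constants <- store$constants
  note("train", sprintf("best epoch %d, val MSE %.4g", report$best_epoch,
                        report$best_val_loss))

  pk <- do.call(peak_config, cfg$estimate)
  pred <- predict_bp(model, parts$test$x, store$constants, pk)
  ref_windows <- denormalize_signal(parts$test$y, store$constants$abp)
  ref_rows <- lapply(seq_len(nrow(ref_windows)), function(i) {
    e <- estimate_window_bp(ref_windows[i, ], pk)
    data.frame(sbp = e$sbp_mmHg, dbp = e$dbp_mmHg, map = e$map_mmHg,
               valid = e$valid)
  })
  ref <- do.call(rbind, ref_rows)
  ok <- pred$valid & ref$valid
  evaluation <- evaluate_bp(pred[ok, c("sbp", "dbp", "map")],
                            ref[ok, c("sbp", "dbp", "map")],
                            parts$test$subject[ok])
  note("evaluate", sprintf("SBP MAE %.2f mmHg", evaluation$sbp$errors$mae))
  say("test SBP MAE: %.2f mmHg", evaluation$sbp$errors$mae)

  list(model = model, report = report, store = store, parts = parts,
       predictions = pred, references = ref, evaluation = evaluation,
       fir = fir, run_log = do.call(rbind, log), config = cfg)
}
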