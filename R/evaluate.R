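# Accuracy metrics and device-grading standards.
#
# Error statistics use the predicted-minus-reference convention and the
# population (divide-by-n) standard deviation, which makes the identity
# rmse^2 = me^2 + std^2 exact. Devices are graded against the British
# Hypertension Society cumulative-error table and the AAMI mean-error /
# standard-deviation / cohort-size criterion; per-window pressures are also
# classified into the four hypertension stages and compared with
# Bland-Altman agreement statistics.

#' Error statistics between predicted and reference pressures
#'
#' @param pred,ref equal-length numeric vectors, mmHg.
#' @return an `bp_error_summary` list: `me` (mean error), `mae`, `std`
#'   (population SD of the errors), `rmse`, `r` (Pearson correlation of
#'   `pred` vs `ref`), `n`.
#' @export
error_stats <- function(pred, ref) {
  n <- length(pred)
  if (n == 0 || n != length(ref)) {
    stop("pred and ref must be equal-length and nonempty", call. = FALSE)
  }
  if (stats::sd(pred) == 0 || stats::sd(ref) == 0) {
    stop("correlation undefined: zero variance in pred or ref", call. = FALSE)
  }
  e <- pred - ref
  structure(list(me = mean(e), mae = mean(abs(e)), std = pop_sd(e),
                 rmse = sqrt(mean(e^2)), r = stats::cor(pred, ref), n = n),
            class = "bp_error_summary")
}

.bhs_table <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))

#' BHS grade from cumulative error percentages
#'
#' Grades a device by the percentage of absolute errors within 5, 10 and
#' 15 mmHg: grade A requires 60/85/95, B 50/75/90, C 40/65/85 (all three
#' thresholds simultaneously); otherwise D.
#'
#' @param pct5,pct10,pct15 cumulative percentages in `[0, 100]`,
#'   nondecreasing.
#' @return `"A"`, `"B"`, `"C"` or `"D"`.
#' @export
bhs_grade <- function(pct5, pct10, pct15) {
  p <- c(pct5, pct10, pct15)
  if (any(p < 0 | p > 100)) fail_field("percentages", "must lie in [0, 100]")
  if (is.unsorted(p)) {
    fail_field("percentages", "cumulative percentages must be nondecreasing")
  }
  for (g in names(.bhs_table)) {
    if (all(p >= .bhs_table[[g]])) return(g)
  }
  "D"
}

#' BHS result from raw errors
#'
#' @param pred,ref equal-length pressure vectors, mmHg.
#' @return a `bp_bhs_result`: `pct_within_5/10/15` and `grade`.
#' @export
bhs_result <- function(pred, ref) {
  ae <- abs(pred - ref)
  p <- vapply(c(5, 10, 15), function(th) 100 * mean(ae <= th), 0)
  structure(list(pct_within_5 = p[1], pct_within_10 = p[2],
                 pct_within_15 = p[3], grade = bhs_grade(p[1], p[2], p[3])),
            class = "bp_bhs_result")
}

#' AAMI criterion check
#'
#' Passed when the absolute mean error is at most 5 mmHg, the error standard
#' deviation at most 8 mmHg, and the cohort has at least 85 subjects.
#'
#' @param me mean error, mmHg (sign ignored for the bound).
#' @param std error standard deviation, mmHg.
#' @param n_subjects number of distinct subjects behind the errors.
#' @return a `bp_aami_result`: inputs plus logical `passed`.
#' @export
aami_check <- function(me, std, n_subjects) {
  check_scalar(n_subjects, "n_subjects", 1, Inf)
  structure(list(me = me, std = std, n_subjects = as.integer(n_subjects),
                 passed = abs(me) <= 5 && std <= 8 && n_subjects >= 85),
            class = "bp_aami_result")
}

.stage_levels <- c("normal", "prehypertension", "stage1", "stage2")

#' Classify a pressure into a hypertension stage
#'
#' SBP: <120 normal, 120-139 prehypertension, 140-159 stage 1, >=160
#' stage 2. DBP: <80, 80-89, 90-99, >=100.
#'
#' @param value pressure(s), mmHg; vectorized.
#' @param kind `"sbp"` or `"dbp"`.
#' @return factor with levels normal/prehypertension/stage1/stage2.
#' @export
classify_stage <- function(value, kind = c("sbp", "dbp")) {
  kind <- match.arg(kind)
  br <- if (kind == "sbp") c(-Inf, 120, 140, 160, Inf) else
    c(-Inf, 80, 90, 100, Inf)
  cut(value, breaks = br, labels = .stage_levels, right = FALSE)
}

#' Stage confusion matrix and per-stage accuracy
#'
#' @param pred,ref equal-length pressure vectors, mmHg.
#' @param kind `"sbp"` or `"dbp"`.
#' @return a `bp_stage_confusion`: 4x4 `counts` (rows: reference stage) and
#'   `accuracy_pct` per stage (diagonal over row sum).
#' @export
stage_confusion <- function(pred, ref, kind = c("sbp", "dbp")) {
  kind <- match.arg(kind)
  if (!length(pred) || length(pred) != length(ref)) {
    stop("pred and ref must be equal-length and nonempty", call. = FALSE)
  }
  counts <- table(ref = classify_stage(ref, kind),
                  pred = classify_stage(pred, kind))
  rs <- rowSums(counts)
  acc <- ifelse(rs > 0, 100 * diag(counts) / rs, NA_real_)
  structure(list(counts = unclass(counts), accuracy_pct = acc),
            class = "bp_stage_confusion")
}

#' Bland-Altman agreement statistics
#'
#' @param pred,ref equal-length pressure vectors (n >= 2), mmHg.
#' @return a `bp_bland_altman`: `bias` (mean difference), `loa_low`,
#'   `loa_high` (bias -/+ 1.96 population SD of the differences), and the
#'   paired `means`/`differences`.
#' @export
bland_altman <- function(pred, ref) {
  n <- length(pred)
  if (n < 2 || n != length(ref)) {
    stop("need at least two pairs", call. = FALSE)
  }
  d <- pred - ref
  bias <- mean(d)
  s <- pop_sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s,
                 means = (pred + ref) / 2, differences = d),
            class = "bp_bland_altman")
}

#' Full evaluation report for one test set
#'
#' Computes, for each of SBP, DBP and MAP: error statistics, BHS grade from
#' raw errors, AAMI verdict, stage confusion (SBP/DBP only) and Bland-Altman
#' statistics.
#'
#' @param pred data.frame with columns `sbp`, `dbp`, `map` (predicted, mmHg).
#' @param ref data.frame with the same columns (reference, mmHg).
#' @param subjects optional character vector of subject ids per row; AAMI
#'   counts distinct subjects (defaults to one pseudo-subject per row).
#' @return a `bp_eval_report` nested list.
#' @export
evaluate_bp <- function(pred, ref, subjects = NULL) {
  stopifnot(is.data.frame(pred), is.data.frame(ref),
            nrow(pred) == nrow(ref))
  ok <- stats::complete.cases(pred[, c("sbp", "dbp", "map")]) &
    stats::complete.cases(ref[, c("sbp", "dbp", "map")])
  pred <- pred[ok, ]
  ref <- ref[ok, ]
  n_subj <- if (is.null(subjects)) nrow(pred) else
    length(unique(subjects[ok]))
  per_q <- lapply(c(sbp = "sbp", dbp = "dbp", map = "map"), function(q) {
    es <- error_stats(pred[[q]], ref[[q]])
    out <- list(errors = es, bhs = bhs_result(pred[[q]], ref[[q]]),
                aami = aami_check(es$me, es$std, n_subj),
                bland_altman = bland_altman(pred[[q]], ref[[q]]))
    if (q != "map") out$stages <- stage_confusion(pred[[q]], ref[[q]], q)
    out
  })
  structure(c(per_q, list(n_windows = nrow(pred), n_subjects = n_subj)),
            class = "bp_eval_report")
}

#' @export
print.bp_eval_report <- function(x, ...) {
  cat(sprintf("<evaluation: %d windows, %d subjects>\n", x$n_windows,
              x$n_subjects))
  for (q in c("sbp", "dbp", "map")) {
    e <- x[[q]]$errors
    cat(sprintf("  %s: MAE %.2f, ME %.2f, STD %.2f, RMSE %.2f, r %.3f | BHS %s | AAMI %s\n",
                toupper(q), e$mae, e$me, e$std, e$rmse, e$r, x[[q]]$bhs$grade,
                if (x[[q]]$aami$passed) "passed" else "failed"))
  }
  invisible(x)
}
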