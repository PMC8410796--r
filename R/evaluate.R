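# Sensitivity/specificity evaluation, ROC analysis, threshold selection and
# model-versus-reader comparison.
#
# Convention fixed throughout the package: an example is predicted positive
# iff its score >= threshold (ties go to the positive class).

#' Confusion counts at a threshold
#'
#' @inheritParams loss_mse
#' @param threshold Decision threshold; predicted positive iff
#'   `score >= threshold`. Default 0.5.
#' @return One-row tibble with integer columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  check_batch(scores, labels)
  check_scalar(threshold, "threshold")
  pred <- scores >= threshold
  tibble(tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
         tn = sum(!pred & labels == 0), fn = sum(!pred & labels == 1))
}

#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = TP / (TP + FN)` (recall on the positive class) and
#' `specificity = TN / (TN + FP)` (recall on the negative class).
#'
#' @param counts A data frame with columns `tp`, `fp`, `tn`, `fn` (e.g. from
#'   [confusion_counts()]); vectorised over rows.
#' @return Numeric vector.
#' @export
sensitivity <- function(counts) {
  if (any(counts$tp + counts$fn == 0)) {
    abort("Sensitivity undefined: no positive examples (tp + fn = 0).",
          class = "melbalance_undefined_metric")
  }
  counts$tp / (counts$tp + counts$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  if (any(counts$tn + counts$fp == 0)) {
    abort("Specificity undefined: no negative examples (tn + fp = 0).",
          class = "melbalance_undefined_metric")
  }
  counts$tn / (counts$tn + counts$fp)
}

check_both_classes <- function(labels, call = rlang::caller_env()) {
  if (!any(labels == 1) || !any(labels == 0)) {
    abort("Both classes must be present to compute ROC-type metrics.",
          class = "melbalance_undefined_metric", call = call)
  }
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold (descending, starting above
#' the maximum so the curve begins at SEN 0 / SPE 1 and ends at SEN 1 /
#' SPE 0) and computes the area under the curve by the trapezoidal rule,
#' which equals the Mann-Whitney pairwise-concordance statistic with half
#' credit for ties.
#'
#' @inheritParams loss_mse
#' @return A tibble of class `mb_roc` with columns `threshold` (descending,
#'   first entry `Inf`), `sen`, `spe`, `fpr`, and attribute `auc`;
#'   [glance()] returns the AUC.
#' @export
roc_curve <- function(scores, labels) {
  check_batch(scores, labels)
  check_both_classes(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  P <- sum(y == 1); N <- sum(y == 0)
  keep <- !duplicated(s, fromLast = TRUE)        # last index of each distinct score
  cum_tp <- cumsum(y == 1)[keep]
  cum_fp <- cumsum(y == 0)[keep]
  out <- tibble(threshold = c(Inf, s[keep]),
                sen = c(0, cum_tp / P),
                fpr = c(0, cum_fp / N))
  out$spe <- 1 - out$fpr
  out <- out[, c("threshold", "sen", "spe", "fpr")]
  auc <- sum(diff(out$fpr) * (head(out$sen, -1) + tail(out$sen, -1)) / 2)
  structure(out, class = c("mb_roc", class(tibble())),
            auc = auc, n_pos = P, n_neg = N)
}

#' Area under the ROC curve
#'
#' @inheritParams loss_mse
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  attr(roc_curve(scores, labels), "auc")
}

#' @describeIn roc_curve One-row summary (`auc`, class sizes).
#' @param x An `mb_roc` object.
#' @param ... Unused.
#' @export
glance.mb_roc <- function(x, ...) {
  tibble(auc = attr(x, "auc"), n_pos = attr(x, "n_pos"),
         n_neg = attr(x, "n_neg"))
}

#' Operating points achieving sensitivity / specificity targets
#'
#' For each sensitivity target, selects the largest threshold whose
#' sensitivity reaches the target and reports the specificity there
#' (sensitivity is maximal at low thresholds, so the largest qualifying
#' threshold gives the best specificity). Symmetrically, for each
#' specificity target, the smallest threshold whose specificity reaches the
#' target, reporting its sensitivity. Unattainable targets are reported at
#' the nearest boundary with `attained = FALSE`.
#'
#' @inheritParams loss_mse
#' @param sen_targets,spe_targets Numeric vectors of targets in `[0, 1]`.
#'   Defaults are the conventional reporting grid
#'   (1.00, 0.95, 0.90, 0.85, 0.80, 0.767, 0.741 for sensitivity;
#'   1.00, 0.95, 0.90, 0.85, 0.80, 0.692, 0.60 for specificity).
#' @return Tibble with columns `target_metric` (`"sen"`/`"spe"`), `target`,
#'   `threshold`, `sen`, `spe`, `attained`.
#' @export
threshold_sweep <- function(scores, labels,
                            sen_targets = c(1, 0.95, 0.9, 0.85, 0.8, 0.767, 0.741),
                            spe_targets = c(1, 0.95, 0.9, 0.85, 0.8, 0.692, 0.6)) {
  roc <- roc_curve(scores, labels)
  row_for <- function(metric, target) {
    if (metric == "sen") {
      ok <- which(roc$sen >= target)       # thresholds descending: first hit = largest
      i <- if (length(ok)) ok[1] else nrow(roc)
      attained <- length(ok) > 0
    } else {
      ok <- which(roc$spe >= target)       # spe decreasing: last hit = smallest thr
      i <- if (length(ok)) ok[length(ok)] else 1L
      attained <- length(ok) > 0
    }
    thr <- roc$threshold[i]
    tibble(target_metric = metric, target = target,
           threshold = if (is.finite(thr)) thr else 1,
           sen = roc$sen[i], spe = roc$spe[i], attained = attained)
  }
  dplyr::bind_rows(
    purrr::map(sen_targets, ~ row_for("sen", .x)),
    purrr::map(spe_targets, ~ row_for("spe", .x)))
}

#' Balanced operating point
#'
#' Selects the decision threshold balancing sensitivity and specificity.
#' `"min_gap"` minimises `|SEN - SPE|` over all candidate thresholds, with
#' ties broken by larger `SEN + SPE`, then larger threshold; `"youden"`
#' maximises Youden's J = SEN + SPE - 1 (ties: larger threshold).
#'
#' @inheritParams loss_mse
#' @param criterion `"min_gap"` or `"youden"`.
#' @return One-row tibble with `criterion`, `threshold`, `sen`, `spe`.
#' @export
balanced_threshold <- function(scores, labels,
                               criterion = c("min_gap", "youden")) {
  criterion <- match.arg(criterion)
  roc <- roc_curve(scores, labels)
  thr <- ifelse(is.finite(roc$threshold), roc$threshold, 1)
  i <- if (criterion == "min_gap") {
    ord <- order(abs(roc$sen - roc$spe), -(roc$sen + roc$spe), -thr)
    ord[1]
  } else {
    ord <- order(-(roc$sen + roc$spe - 1), -thr)
    ord[1]
  }
  tibble(criterion = criterion, threshold = thr[i],
         sen = roc$sen[i], spe = roc$spe[i])
}

#' Load reader (clinician) operating points
#'
#' Reads a CSV of reader-study operating points with columns
#' `group, n, auc, sen, spe` (percentages, as such tables are printed) and
#' returns proportions. With no argument, loads the packaged summary of the
#' 157-dermatologist benchmark reader study.
#'
#' @param path CSV path; `NULL` for the packaged fixture.
#' @return Tibble with columns `group`, `n`, `auc`, `sen`, `spe`
#'   (proportions in `[0, 1]`).
#' @export
reader_points <- function(path = NULL) {
  path <- path %||% system.file("extdata", "dermatologist_readers.csv",
                                package = "melbalance", mustWork = TRUE)
  df <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("group", "n", "auc", "sen", "spe")
  if (!all(req %in% names(df))) {
    abort(sprintf("Reader CSV must have columns: %s.", paste(req, collapse = ", ")),
          class = "melbalance_invalid_input")
  }
  dplyr::mutate(df, dplyr::across(c("auc", "sen", "spe"),
                                  ~ ifelse(.x > 1, .x / 100, .x)))
}

#' Count readers outperformed by a model ROC curve
#'
#' A reader at `(1 - SPE, SEN)` is *outperformed* when the point lies
#' strictly below the model's ROC polyline (linear interpolation between
#' vertices); readers lying on the curve (within `tol`) are flagged
#' separately, not counted as outperformed.
#'
#' @param roc An `mb_roc` from [roc_curve()].
#' @param readers Data frame with columns `sen` and `spe` in `[0, 1]` (see
#'   [reader_points()]).
#' @param tol Geometric tolerance for "on the curve". Default `1e-9`.
#' @return The input `readers` tibble plus columns `fpr`, `model_sen` (the
#'   curve's sensitivity at the reader's false-positive rate) and `status`
#'   (`"below"`, `"on"`, `"above"`); attributes `n_outperformed` and
#'   `n_on_curve` hold the counts.
#' @export
readers_outperformed <- function(roc, readers, tol = 1e-9) {
  stopifnot(inherits(roc, "mb_roc"))
  if (!all(c("sen", "spe") %in% names(readers))) {
    abort("`readers` must have columns `sen` and `spe`.",
          class = "melbalance_invalid_input")
  }
  if (any(readers$sen < 0 | readers$sen > 1 | readers$spe < 0 | readers$spe > 1)) {
    abort("Reader `sen`/`spe` must lie in [0, 1].",
          class = "melbalance_invalid_input")
  }
  # upper envelope of the polyline as a function of fpr
  env <- dplyr::summarise(dplyr::group_by(tibble(fpr = roc$fpr, sen = roc$sen),
                                          .data$fpr),
                          lo = min(.data$sen), hi = max(.data$sen),
                          .groups = "drop")
  fpr_r <- 1 - readers$spe
  up <- approx(env$fpr, env$hi, xout = fpr_r, rule = 2)$y
  status <- character(nrow(readers))
  for (k in seq_along(status)) {
    if (abs(readers$sen[k] - up[k]) <= tol) {
      status[k] <- "on"
    } else if (readers$sen[k] < up[k]) {
      # interior of a vertical segment still lies on the curve
      j <- which(abs(env$fpr - fpr_r[k]) <= tol)
      on_vertical <- length(j) == 1 && readers$sen[k] >= env$lo[j] - tol &&
        readers$sen[k] <= env$hi[j] + tol
      status[k] <- if (on_vertical) "on" else "below"
    } else {
      status[k] <- "above"
    }
  }
  out <- dplyr::mutate(as_tibble(readers), fpr = fpr_r, model_sen = up,
                       status = status)
  structure(out, n_outperformed = sum(status == "below"),
            n_on_curve = sum(status == "on"))
}

#' Full evaluation report of a score set
#'
#' Bundles the fixed-threshold metrics, AUC, threshold sweep and balanced
#' operating points of one set of scores.
#'
#' @inheritParams loss_mse
#' @param threshold Reporting threshold. Default 0.5.
#' @return List with `metrics` (one-row tibble: auc, sen, spe, accuracy at
#'   `threshold`), `roc`, `sweep`, `balanced` (both criteria).
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  cc <- confusion_counts(scores, labels, threshold)
  roc <- roc_curve(scores, labels)
  list(
    metrics = tibble(threshold = threshold, auc = attr(roc, "auc"),
                     sen = sensitivity(cc), spe = specificity(cc),
                     accuracy = (cc$tp + cc$tn) / sum(cc[1, ])),
    roc = roc,
    sweep = threshold_sweep(scores, labels),
    balanced = dplyr::bind_rows(balanced_threshold(scores, labels, "min_gap"),
                                balanced_threshold(scores, labels, "youden")))
}
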