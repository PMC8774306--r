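# Decision rules and diagnostic statistics: inclusive-threshold spectrum
# classification, strict-majority patient aggregation, confusion counts,
# sensitivity/specificity, ROC and trapezoidal AUC. Cancer is the positive
# class throughout.

#' Classify spectra from cancer probabilities
#'
#' The threshold is inclusive: a probability exactly equal to the threshold
#' is called cancer.
#'
#' @param p_cancer Numeric vector of probabilities in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5).
#' @return Character vector of `"cancer"` / `"normal"` labels.
#' @export
classify_spectrum <- function(p_cancer, threshold = 0.5) {
  if (anyNA(p_cancer) || any(p_cancer < 0 | p_cancer > 1)) {
    abort("Probabilities must lie in [0, 1].", class = "fluordx_value_error")
  }
  ifelse(p_cancer >= threshold, "cancer", "normal")
}

#' Strict-majority case decision
#'
#' A case is counted correct if and only if strictly more than half of its
#' spectra carry the true label; ties on an even number of spectra are
#' incorrect. When incorrect, the case-level predicted label is the
#' opposite class.
#'
#' @param pred_labels Per-spectrum predicted labels for one case.
#' @param true_label The case's true label (`"normal"` or `"cancer"`).
#' @return A one-row tibble with `pred_label` and `correct`.
#' @export
case_majority <- function(pred_labels, true_label) {
  if (length(pred_labels) == 0) {
    abort("A case needs at least one spectrum.", class = "fluordx_value_error")
  }
  true_label <- match.arg(tolower(true_label), c("normal", "cancer"))
  correct <- sum(pred_labels == true_label) > length(pred_labels) / 2
  other <- if (true_label == "cancer") "normal" else "cancer"
  tibble(pred_label = if (correct) true_label else other, correct = correct)
}

#' Aggregate per-spectrum predictions to case-level predictions
#'
#' @param predictions A tibble with `case_id`, `label` and `p_cancer`
#'   columns (e.g. from [predict.dense_net_fit()]).
#' @param threshold Spectrum decision threshold passed to
#'   [classify_spectrum()].
#' @return A tibble with one row per case: `case_id`, `label`, `n_spectra`,
#'   `n_correct`, `correct`, `pred_label`.
#' @export
aggregate_cases <- function(predictions, threshold = 0.5) {
  stopifnot(all(c("case_id", "label", "p_cancer") %in% names(predictions)))
  predictions |>
    mutate(.spectrum_pred = classify_spectrum(.data$p_cancer, threshold)) |>
    group_by(.data$case_id, .data$label) |>
    summarise(
      n_spectra = n(),
      n_correct = sum(.data$.spectrum_pred == .data$label[1]),
      .groups = "drop"
    ) |>
    mutate(
      correct = .data$n_correct > .data$n_spectra / 2,
      pred_label = ifelse(.data$correct, .data$label,
                          ifelse(.data$label == "cancer", "normal", "cancer"))
    )
}

#' Confusion counts with cancer as the positive class
#'
#' @param case_predictions A tibble with `label` (truth) and `pred_label`
#'   columns, one row per unit (case or spectrum).
#' @return A one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(case_predictions) {
  stopifnot(all(c("label", "pred_label") %in% names(case_predictions)),
            nrow(case_predictions) >= 1)
  truth <- case_predictions$label
  pred <- case_predictions$pred_label
  tibble(
    tp = sum(truth == "cancer" & pred == "cancer"),
    fp = sum(truth == "normal" & pred == "cancer"),
    tn = sum(truth == "normal" & pred == "normal"),
    fn = sum(truth == "cancer" & pred == "normal")
  )
}

#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`. A zero
#' denominator yields `NA` with a warning rather than a silent 0.
#'
#' @param counts A one-row tibble or list with `tp`, `fp`, `tn`, `fn`.
#' @return A one-row tibble with `sensitivity` and `specificity`.
#' @export
diagnostic_rates <- function(counts) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  sens <- if (counts$tp + counts$fn == 0) {
    warn("Sensitivity undefined: no cancer cases (TP + FN = 0).")
    NA_real_
  } else counts$tp / (counts$tp + counts$fn)
  spec <- if (counts$tn + counts$fp == 0) {
    warn("Specificity undefined: no normal cases (TN + FP = 0).")
    NA_real_
  } else counts$tn / (counts$tn + counts$fp)
  tibble(sensitivity = sens, specificity = spec)
}

#' ROC curve over spectrum scores
#'
#' One operating point per distinct score threshold (prediction is positive
#' when `score >= threshold`), anchored at (0, 0) and (1, 1). Both
#' coordinates are monotone non-decreasing.
#'
#' @param scores Numeric cancer scores (higher = more cancer-like).
#' @param labels True labels, `"cancer"` positive.
#' @return A tibble of class `roc_tbl` with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == "cancer"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC needs at least one positive and one negative label.",
          class = "fluordx_value_error")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # cumulative counts at each distinct threshold (last index of each tie run)
  last <- which(!duplicated(s, fromLast = TRUE))
  tpr <- cumsum(p)[last] / n_pos
  fpr <- cumsum(!p)[last] / n_neg
  out <- tibble(
    threshold = c(Inf, s[last]),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  new_tibble(out, class = "roc_tbl")
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of a [roc_curve()]; equal to the Mann-Whitney
#' probability that a random cancer spectrum outscores a random normal one
#' (ties counting one half).
#'
#' @param roc A `roc_tbl` from [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(roc) {
  stopifnot(all(c("fpr", "tpr") %in% names(roc)))
  f <- roc$fpr
  t <- roc$tpr
  sum(diff(f) * (t[-1] + t[-length(t)]) / 2)
}
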