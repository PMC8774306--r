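# Repeated random-split protocol: case-level three-way partitions, one
# training run per split, Table-style order statistics over runs. The unit
# of splitting is the case, so all spectra of a case always travel together
# and no case appears in more than one partition.

#' Randomly partition cases into train / test / validation sets
#'
#' Draws a uniformly random, disjoint, exhaustive case-level partition.
#' The defaults are the published protocol: 229 training, 29 test (early
#' stopping) and 28 validation cases out of 286. A partition that leaves a
#' part of size two or more with only one class is re-drawn (bounded
#' retries) because single-class sets break both training and evaluation;
#' singleton parts are exempt.
#'
#' @param data A spectra tibble.
#' @param n_train,n_test,n_validation Case counts; must sum to the number
#'   of cases in `data`.
#' @param stratified Sample within each class proportionally instead of
#'   fully at random (off by default, matching the protocol).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param max_retries Redraw budget for degenerate partitions.
#' @return A tibble with one row per case: `case_id`, `label`, `part`
#'   (factor: train / test / validation).
#' @export
split_cases <- function(data, n_train = 229, n_test = 29, n_validation = 28,
                        stratified = FALSE, seed = NULL, max_retries = 100) {
  cases <- data |> distinct(.data$case_id, .data$label)
  sizes <- c(train = n_train, test = n_test, validation = n_validation)
  if (any(sizes < 0) || sum(sizes) != nrow(cases)) {
    abort(sprintf(
      "Split sizes (%d + %d + %d) must sum to the number of cases (%d).",
      n_train, n_test, n_validation, nrow(cases)),
      class = "fluordx_value_error")
  }
  if (!is.null(seed)) set.seed(seed)
  parts <- factor(rep(names(sizes), sizes),
                  levels = c("train", "test", "validation"))
  n_classes <- length(unique(cases$label))

  draw <- function() {
    ord <- sample(cases$case_id)
    tibble(case_id = ord, part = parts) |>
      left_join(cases, by = "case_id") |>
      select("case_id", "label", "part")
  }
  draw_stratified <- function() {
    shuffled <- cases[sample.int(nrow(cases)), ]
    assign <- rep(NA_character_, nrow(shuffled))
    for (cl in unique(shuffled$label)) {
      rows <- which(shuffled$label == cl)
      quota <- diff(round(cumsum(c(0, sizes / sum(sizes))) * length(rows)))
      assign[rows] <- rep(names(sizes), quota)
    }
    # quotas are proportional but rounding can misalign with the exact
    # sizes; repair by reassigning surplus cases at random
    for (p in names(sizes)) {
      excess <- sum(assign == p) - sizes[[p]]
      while (excess > 0) {
        short <- names(sizes)[vapply(names(sizes), function(q)
          sum(assign == q) < sizes[[q]], logical(1))][1]
        i <- sample(which(assign == p), 1)
        assign[i] <- short
        excess <- excess - 1
      }
    }
    tibble(case_id = shuffled$case_id, label = shuffled$label,
           part = factor(assign, levels = names(sizes)))
  }

  for (try in seq_len(max_retries)) {
    out <- if (stratified) draw_stratified() else draw()
    degenerate <- out |>
      group_by(.data$part) |>
      summarise(n = n(), k = dplyr::n_distinct(.data$label),
                .groups = "drop") |>
      filter(.data$n >= 2, .data$k < n_classes)
    if (nrow(degenerate) == 0 || n_classes == 1) {
      return(out)
    }
  }
  abort("Could not draw a partition with both classes in every part.",
        class = "fluordx_value_error")
}

derive_run_seed <- function(master_seed, run) {
  as.integer((as.numeric(master_seed) + 104729 * run) %% 2147483647)
}

#' Run one train/evaluate cross-validation experiment
#'
#' Splits the cases, trains the network on the training spectra with the
#' test spectra as the early-stopping monitor, then evaluates the
#' checkpointed model on the held-out validation cases: case-level
#' sensitivity and specificity through the strict-majority vote, spectrum-
#' level rates alongside, and the spectrum-level ROC AUC.
#'
#' @param data A spectra tibble.
#' @param n_train,n_test,n_validation Case-level split sizes.
#' @param net_spec A [network_spec()] or `NULL` (derived from the data).
#' @param config A [train_config()].
#' @param seed Seed for the whole experiment (split, init, training).
#' @param threshold Spectrum decision threshold.
#' @param detail If `TRUE`, attach the training history and ROC points as
#'   attributes `"history"` and `"roc"`.
#' @return A one-row tibble: confusion counts (`tp`, `fp`, `tn`, `fn`),
#'   `sensitivity`, `specificity`, spectrum-level rates, `auc`,
#'   `best_epoch`, `stopped_epoch`, `seed`.
#' @export
run_experiment <- function(data, n_train = 229, n_test = 29,
                           n_validation = 28, net_spec = NULL,
                           config = train_config("fast"), seed = NULL,
                           threshold = 0.5, detail = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  assignment <- split_cases(data, n_train, n_test, n_validation)
  part_of <- function(p) {
    ids <- assignment$case_id[assignment$part == p]
    filter(data, .data$case_id %in% ids)
  }
  fit <- fit_dense_net(part_of("train"), part_of("test"),
                       spec = net_spec, config = config)
  preds <- predict(fit, part_of("validation"), threshold = threshold)

  case_preds <- aggregate_cases(preds, threshold = threshold)
  counts <- confusion_counts(case_preds)
  rates <- diagnostic_rates(counts)
  spectrum_counts <- confusion_counts(
    preds |> select("label", "pred_label"))
  spectrum_rates <- diagnostic_rates(spectrum_counts)
  roc <- roc_curve(preds$p_cancer, preds$label)

  out <- dplyr::bind_cols(
    counts, rates,
    tibble(sensitivity_spectrum = spectrum_rates$sensitivity,
           specificity_spectrum = spectrum_rates$specificity,
           auc = auc(roc),
           best_epoch = fit$best_epoch,
           stopped_epoch = fit$stopped_epoch,
           seed = seed %||% NA_integer_)
  )
  if (detail) {
    attr(out, "history") <- fit$history
    attr(out, "roc") <- roc
  }
  out
}

#' Repeated random-split cross-validation
#'
#' Runs `n_runs` independent experiments (the published protocol uses 50),
#' each with its own seed derived from `master_seed` and a fresh case-level
#' split, so the whole procedure is reproducible from one integer.
#'
#' @inheritParams run_experiment
#' @param n_runs Number of independent experiments.
#' @param master_seed Integer seed from which per-run seeds are derived.
#' @param detail Keep each run's history and ROC (as attribute `"details"`,
#'   a list of lists).
#' @return A tibble of class `cv_runs`, one row per run (column `run`
#'   first), carrying `master_seed` as an attribute.
#' @export
cross_validate <- function(data, n_runs = 50, n_train = 229, n_test = 29,
                           n_validation = 28, net_spec = NULL,
                           config = train_config("fast"), master_seed = 1,
                           threshold = 0.5, detail = FALSE) {
  stopifnot(n_runs >= 1)
  details <- if (detail) vector("list", n_runs) else NULL
  rows <- purrr::map(seq_len(n_runs), function(i) {
    res <- run_experiment(
      data, n_train, n_test, n_validation, net_spec, config,
      seed = derive_run_seed(master_seed, i),
      threshold = threshold, detail = detail
    )
    if (detail) {
      details[[i]] <<- list(history = attr(res, "history"),
                            roc = attr(res, "roc"))
      attr(res, "history") <- NULL
      attr(res, "roc") <- NULL
    }
    mutate(res, run = i, .before = 1)
  })
  out <- new_tibble(bind_rows(rows), class = "cv_runs")
  attr(out, "master_seed") <- master_seed
  if (detail) attr(out, "details") <- details
  out
}

#' Order-statistic summary of cross-validation metrics
#'
#' For each metric reports N, Min, Max, Mean, Median, sample standard
#' deviation (n - 1) and the 25th/75th percentiles (linear interpolation
#' between order statistics).
#'
#' @param results A `cv_runs` tibble (or any tibble holding the metric
#'   columns).
#' @param metrics Metric columns to summarise; the default order matches
#'   the published summary table (specificity first).
#' @return A tibble with one row per metric and columns `metric`, `n`,
#'   `min`, `max`, `mean`, `median`, `sd`, `p25`, `p75`.
#' @export
summarize_runs <- function(results,
                           metrics = c("specificity", "sensitivity")) {
  if (nrow(results) == 0) {
    abort("No runs to summarise.", class = "fluordx_value_error")
  }
  missing <- setdiff(metrics, names(results))
  if (length(missing) > 0) {
    abort(paste0("Metric column(s) not found: ",
                 paste(missing, collapse = ", ")),
          class = "fluordx_value_error")
  }
  purrr::map_dfr(metrics, function(m) {
    v <- results[[m]]
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    tibble(
      metric = m, n = length(v),
      min = min(v), max = max(v),
      mean = mean(v), median = stats::median(v),
      sd = if (length(v) > 1) stats::sd(v) else 0,
      p25 = q[1], p75 = q[2]
    )
  })
}
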