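# broom-style accessors for fitted objects and cross-validation results.

#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Per-layer summary of a fitted dense network
#'
#' @param x A `dense_net_fit`.
#' @param ... Unused.
#' @return A tibble with one row per dense layer: `layer`, `input_dim`,
#'   `units`, `activation`, `dropout`, `n_parameters`.
#' @export
tidy.dense_net_fit <- function(x, ...) {
  spec <- x$spec
  d <- layer_dims(spec)
  tibble(
    layer = seq_along(d$fan_in),
    input_dim = d$fan_in,
    units = d$fan_out,
    activation = c(spec$hidden_activations, "softmax"),
    dropout = c(spec$dropout_rates, 0),
    n_parameters = d$fan_in * d$fan_out + d$fan_out
  )
}

#' One-row summary of a fitted dense network
#'
#' @param x A `dense_net_fit`.
#' @param ... Unused.
#' @return A one-row tibble: parameter count, epochs run, checkpointed
#'   epoch, and the monitor loss/accuracy at the checkpoint.
#' @export
glance.dense_net_fit <- function(x, ...) {
  tibble(
    n_parameters = n_parameters(x$spec),
    epochs_run = x$stopped_epoch,
    best_epoch = x$best_epoch,
    best_monitor_loss = x$history$monitor_loss[x$best_epoch],
    best_monitor_accuracy = x$history$monitor_accuracy[x$best_epoch]
  )
}

#' Order-statistic summary of cross-validation runs
#'
#' @param x A `cv_runs` tibble.
#' @param ... Passed to [summarize_runs()].
#' @return The [summarize_runs()] tibble.
#' @export
tidy.cv_runs <- function(x, ...) {
  summarize_runs(x, ...)
}

#' One-row summary of a cross-validation
#'
#' @param x A `cv_runs` tibble.
#' @param ... Unused.
#' @return A one-row tibble: run count, mean case-level sensitivity and
#'   specificity, mean spectrum-level AUC, master seed.
#' @export
glance.cv_runs <- function(x, ...) {
  tibble(
    n_runs = nrow(x),
    mean_sensitivity = mean(x$sensitivity, na.rm = TRUE),
    mean_specificity = mean(x$specificity, na.rm = TRUE),
    mean_auc = mean(x$auc, na.rm = TRUE),
    master_seed = attr(x, "master_seed") %||% NA_integer_
  )
}
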