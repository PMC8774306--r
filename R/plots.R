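# ggplot2 views of the three result types: training history, ROC curve,
# cross-validation metric distributions, plus a raw-spectra view.

#' @importFrom ggplot2 ggplot aes geom_line geom_step geom_abline
#'   geom_boxplot geom_jitter facet_wrap labs theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot training and monitor curves of a fitted network
#'
#' Loss and accuracy per epoch for the training set and the early-stopping
#' monitor set, with the checkpointed epoch marked.
#'
#' @param object A `dense_net_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dense_net_fit <- function(object, ...) {
  long <- object$history |>
    tidyr::pivot_longer(-"epoch", names_to = c("set", "measure"),
                        names_sep = "_", values_to = "value")
  ggplot(long, aes(x = .data$epoch, y = .data$value,
                   colour = .data$set)) +
    geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey40") +
    facet_wrap(~ .data$measure, scales = "free_y") +
    labs(x = "epoch", y = NULL, colour = NULL,
         title = "Training process",
         subtitle = sprintf("checkpoint at epoch %d", object$best_epoch)) +
    theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object A `roc_tbl` from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_tbl <- function(object, ...) {
  ggplot(object, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step(direction = "hv") +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                colour = "grey50") +
    labs(x = "false positive rate (1 - specificity)",
         y = "true positive rate (sensitivity)",
         title = sprintf("ROC curve (AUC = %.2f)", auc(object))) +
    theme_minimal()
}

#' Plot the distribution of cross-validation metrics
#'
#' @param object A `cv_runs` tibble from [cross_validate()].
#' @param metrics Metric columns to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_runs <- function(object,
                             metrics = c("sensitivity", "specificity", "auc"),
                             ...) {
  long <- as_tibble(object) |>
    select(dplyr::all_of(metrics)) |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$metric, y = .data$value)) +
    geom_boxplot(outlier.shape = NA, width = 0.5) +
    geom_jitter(width = 0.1, alpha = 0.5) +
    labs(x = NULL, y = NULL,
         title = sprintf("Validation metrics over %d runs", nrow(object))) +
    theme_minimal()
}

#' Plot class-mean emission spectra per excitation
#'
#' @param data A spectra tibble.
#' @return A ggplot object: mean intensity by emission wavelength,
#'   one panel per excitation, coloured by class.
#' @export
plot_spectra <- function(data) {
  data <- validate_spectra(data)
  long <- data |>
    tidyr::pivot_longer(dplyr::starts_with("em_"),
                        names_to = "emission_nm", values_to = "intensity") |>
    mutate(emission_nm = as.numeric(sub("^em_", "", .data$emission_nm))) |>
    group_by(.data$label, .data$excitation_nm, .data$emission_nm) |>
    summarise(intensity = mean(.data$intensity), .groups = "drop")
  ggplot(long, aes(x = .data$emission_nm, y = .data$intensity,
                   colour = .data$label)) +
    geom_line() +
    facet_wrap(~ .data$excitation_nm, labeller = ggplot2::label_both) +
    labs(x = "emission wavelength (nm)", y = "mean intensity (a.u.)",
         colour = NULL) +
    theme_minimal()
}
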