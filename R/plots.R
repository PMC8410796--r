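# ggplot2 displays for the main result types.

#' Plot an ROC curve, optionally against reader operating points
#'
#' @param object An `mb_roc` from [roc_curve()].
#' @param readers Optional data frame with `sen`/`spe` columns (see
#'   [reader_points()]) drawn as points in reader-study style.
#' @param ... Unused.
#' @return A ggplot object: SEN against 1 - SPE with the chance diagonal.
#' @export
autoplot.mb_roc <- function(object, readers = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$sen)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#4040c0", linewidth = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC curve (AUC = %.3f)", attr(object, "auc"))) +
    ggplot2::theme_minimal()
  if (!is.null(readers)) {
    rd <- dplyr::mutate(as_tibble(readers), fpr = 1 - .data$spe)
    p <- p + ggplot2::geom_point(data = rd, colour = "red", size = 1.8,
                                 ggplot2::aes(x = .data$fpr, y = .data$sen))
  }
  p
}

#' Plot training history of a scenario fit
#'
#' @param object An `imbalance_fit`.
#' @param ... Unused.
#' @return A ggplot with loss and SEN/SPE panels over epochs; the
#'   checkpoint epoch is marked.
#' @export
autoplot.imbalance_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              c("train_loss", "val_loss", "train_sen",
                                "train_spe", "val_sen", "val_spe"),
                              names_to = "metric", values_to = "value")
  long$panel <- ifelse(grepl("loss", long$metric), "loss", "SEN / SPE")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$checkpoint_epoch,
                        linetype = "dotted", colour = "grey40") +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Epoch", y = NULL,
                  title = sprintf("%s training history (checkpoint: epoch %d)",
                                  object$scenario$name,
                                  object$checkpoint_epoch)) +
    ggplot2::theme_minimal()
}

#' Side-by-side scenario performance plot
#'
#' Bar chart of AUC / SEN / SPE per scenario, the usual layout for
#' comparing the ORI / BON / BLF variants at a fixed threshold.
#'
#' @param comparison Tibble with columns `scenario`, `auc`, `sen`, `spe`
#'   (e.g. from [run_compare()]).
#' @return A ggplot object.
#' @export
plot_scenario_comparison <- function(comparison) {
  long <- tidyr::pivot_longer(comparison, c("auc", "sen", "spe"),
                              names_to = "metric", values_to = "value")
  long$metric <- toupper(long$metric)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     fill = .data$scenario)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Value", fill = "Scenario") +
    ggplot2::theme_minimal()
}
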