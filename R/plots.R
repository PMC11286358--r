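#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot out-of-fold predictions of an ensemble
#'
#' Observed versus predicted AUC, colored by fold, with the identity line.
#'
#' @param object A `vnn_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vnn_ensemble
#' @export
autoplot.vnn_ensemble <- function(object, ...) {
  ggplot2::ggplot(
    object$oof,
    ggplot2::aes(x = .data$observed, y = .data$predicted,
                 colour = factor(.data$fold))
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "observed AUC", y = "out-of-fold predicted AUC", colour = "fold"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-member assembly importances
#'
#' Mean importance per assembly with per-member points.
#'
#' @param object A `vnn_importance` (from [interpret_ensemble()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vnn_importance
#' @export
autoplot.vnn_importance <- function(object, ...) {
  df <- tibble::as_tibble(object)
  means <- summarize_importance(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$assembly, .data$rho, FUN = mean),
    y = .data$rho
  )) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(
      data = means,
      ggplot2::aes(x = .data$assembly, y = .data$mean_rho),
      colour = "red", size = 3, shape = 18
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "assembly importance (Spearman rho)") +
    ggplot2::theme_minimal()
}

#' Plot a training loss history
#'
#' @param fit A `vnn_fit` from [train_vnn()].
#' @return A ggplot of train and validation loss per epoch.
#' @export
plot_loss_history <- function(fit) {
  stopifnot(inherits(fit, "vnn_fit"))
  df <- fit$history |>
    tidyr::pivot_longer(
      c("train_loss", "val_loss"),
      names_to = "series", values_to = "loss"
    ) |>
    dplyr::filter(!is.na(.data$loss))
  ggplot2::ggplot(
    df, ggplot2::aes(x = .data$epoch, y = .data$loss, colour = .data$series)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss") +
    ggplot2::theme_minimal()
}
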