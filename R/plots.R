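#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_abline
#'   geom_point labs coord_flip theme_minimal scale_fill_manual
NULL

#' Bar chart of an evidence-propagation sensitivity profile
#'
#' One bar per non-evidence node showing the shift (in probability points)
#' of `P(high)` under the evidence, mirroring the paired low/high panels of
#' a standard sensitivity report.
#'
#' @param object A `bn_sensitivity` from [evidence_delta_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bn_sensitivity
#' @export
autoplot.bn_sensitivity <- function(object, ...) {
  ev <- attr(object, "evidence")
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    node = factor(.data$node, levels = rev(.data$node)),
    direction = ifelse(.data$delta >= 0, "increase", "decrease")
  )
  ggplot(df, aes(x = .data$node, y = .data$delta, fill = .data$direction)) +
    geom_col(show.legend = FALSE) +
    coord_flip() +
    scale_fill_manual(values = c(increase = "#b2182b", decrease = "#2166ac")) +
    labs(
      x = NULL, y = "Change in P(high), probability points",
      title = sprintf(
        "Evidence: %s",
        paste(sprintf("%s = %s", names(ev), ev), collapse = ", ")
      )
    ) +
    theme_minimal()
}

#' ROC curve plot
#'
#' @param object A `bn_roc` from [roc_and_auc()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bn_roc
#' @export
autoplot.bn_roc <- function(object, ...) {
  ggplot(object$points, aes(x = .data$fpr, y = .data$tpr)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line(colour = "#2166ac") +
    labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc)
    ) +
    theme_minimal()
}

#' Ranked arc-influence plot
#'
#' Dot-and-segment chart of the average (point) and maximum (segment end)
#' influence of each arc, ordered by average.
#'
#' @param object A `bn_influence` from [rank_arcs()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bn_influence
#' @export
autoplot.bn_influence <- function(object, ...) {
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    arc = factor(
      paste(.data$parent, "→", .data$child),
      levels = rev(paste(.data$parent, "→", .data$child))
    )
  )
  ggplot(df, aes(x = .data$arc)) +
    ggplot2::geom_segment(aes(xend = .data$arc, y = .data$average, yend = .data$maximum),
                          colour = "grey60") +
    geom_point(aes(y = .data$average), colour = "#b2182b", size = 2) +
    geom_point(aes(y = .data$maximum), colour = "grey40", shape = 1) +
    coord_flip() +
    labs(x = NULL, y = "Influence (average •, maximum ○)") +
    theme_minimal()
}
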