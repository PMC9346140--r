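#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Raster plot of a scanpath's situation-awareness development
#'
#' One row per AOI, one column per decision moment. Filled points mark
#' moments at which the AOI's information is known (awareness bit 1),
#' crosses mark unknown; red marks moments following a period in which the
#' AOI's information updated. Runs of consecutive crosses after a red mark
#' visualize the delay to notice an update.
#'
#' @param object An [sa_scanpath][simulate_scanpath()].
#' @param moments Range of decision moments to show (default: first 40).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sa_scanpath <- function(object, moments = NULL, ...) {
  spec <- attr(object, "spec")
  moments <- moments %||% 0:(min(nrow(object), 40L) - 1L)
  d <- object |>
    dplyr::filter(.data$moment %in% moments) |>
    dplyr::mutate(
      bits = strsplit(.data$state, ""),
      upd = strsplit(.data$update, "")
    ) |>
    tidyr::unnest_longer(c("bits", "upd")) |>
    dplyr::group_by(.data$moment) |>
    dplyr::mutate(aoi_row = spec$aoi[dplyr::row_number()]) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      known = .data$bits == "1",
      # an update during period t is flagged at the following moment
      updated = dplyr::lag(.data$upd == "1", n = n_aoi(spec), default = FALSE),
      aoi_row = factor(.data$aoi_row, levels = rev(spec$aoi))
    )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$moment, y = .data$aoi_row,
    shape = .data$known, colour = .data$updated
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 16, `FALSE` = 4),
      labels = c(`TRUE` = "known", `FALSE` = "unknown"), name = NULL
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "red", `FALSE` = "black"),
      labels = c(`TRUE` = "just updated", `FALSE` = "no update"), name = NULL
    ) +
    ggplot2::labs(
      x = "decision moment", y = NULL,
      title = paste0(
        "Situation-awareness development (", spec$name,
        ", seed ", attr(object, "seed"), ")"
      )
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of predicted versus observed proportions
#'
#' @param object An [sa_battery][run_battery()].
#' @param type `"fixation"` (default) or `"shift"`.
#' @param ... Unused.
#' @return A ggplot object with the identity line and the pooled Pearson r
#'   in the subtitle.
#' @export
autoplot.sa_battery <- function(object, type = c("fixation", "shift"), ...) {
  type <- match.arg(type)
  d <- object[[type]]
  r <- object$correlations |>
    dplyr::filter(.data$condition == "overall") |>
    dplyr::pull(paste0(type, "_r"))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$observed, y = .data$predicted, colour = .data$condition
  )) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = paste("observed", type, "probability"),
      y = paste("predicted", type, "probability"),
      subtitle = sprintf(
        "%s policy, %d points, pooled r = %.3f",
        object$policy, nrow(d), r
      )
    ) +
    ggplot2::theme_minimal()
}
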