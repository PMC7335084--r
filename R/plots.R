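#' Raster plot of a spike table
#'
#' One row per channel, one tick per spike; optionally overlays detected
#' bursts as translucent spans — the standard at-a-glance view of network
#' activity and coordinated bursting.
#'
#' @param object An [mea_spikes()] table.
#' @param bursts Optional burst tibble from [detect_bursts()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mea_spikes
#' @export
autoplot.mea_spikes <- function(object, bursts = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                        y = .data$channel_id)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = sprintf("device %s", device_id(object))) +
    ggplot2::theme_minimal()
  if (!is.null(bursts) && nrow(bursts)) {
    p <- p + ggplot2::geom_rect(
      data = tibble::as_tibble(bursts),
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = as.integer(factor(.data$channel_id,
                                            levels = sort(unique(df$channel_id)))) - 0.45,
                   ymax = as.integer(factor(.data$channel_id,
                                            levels = sort(unique(df$channel_id)))) + 0.45),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.25
    )
  }
  p
}

#' Heatmap of pairwise synchrony
#'
#' @param object An `mea_synchrony` object from [device_synchrony()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mea_synchrony
#' @export
autoplot.mea_synchrony <- function(object, ...) {
  stopifnot(inherits(object, "mea_synchrony"))
  pr <- object$pairs
  if (is.null(pr) || !nrow(pr)) stop("no pairs to plot", call. = FALSE)
  sym <- dplyr::bind_rows(
    pr[c("channel_x", "channel_y", "synchrony")],
    stats::setNames(pr[c("channel_y", "channel_x", "synchrony")],
                    c("channel_x", "channel_y", "synchrony"))
  )
  ggplot2::ggplot(sym, ggplot2::aes(.data$channel_x, .data$channel_y,
                                    fill = .data$synchrony)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(min(0, min(sym$synchrony)), 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("device %s synchrony (mean %.3f)",
                                  object$device_id,
                                  object$device_synchrony)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Device features over days in vitro
#'
#' Group mean with SEM error bars per DIV — the conventional longitudinal
#' summary figure for culture development.
#'
#' @param data A long table from [longitudinal_table()].
#' @param feature Feature to plot.
#' @return A ggplot object.
#' @export
plot_feature_over_div <- function(data, feature) {
  df <- data[data$feature == feature & !is.na(data$value), , drop = FALSE]
  agg <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(df), .data$group, .data$div),
    mean = mean(.data$value),
    sem = stats::sd(.data$value) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(agg, ggplot2::aes(.data$div, .data$mean,
                                    colour = .data$group,
                                    group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.4) +
    ggplot2::labs(x = "DIV", y = feature) +
    ggplot2::theme_minimal()
}
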