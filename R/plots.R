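#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of an attribution map
#'
#' Channels are ordered frontal (top) to occipital (bottom) following the
#' montage order; time runs along the x axis in ms post stimulus; fill is
#' the relative importance score in `[0, 1]`.
#'
#' @param object An `attribution_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.attribution_map <- function(object, ...) {
  chans <- object$channels %||% as.character(seq_len(nrow(object$importance)))
  tms <- object$times
  if (is.null(tms)) tms <- seq_len(ncol(object$importance))
  else tms <- tms * 1000
  df <- tidyr::expand_grid(channel = chans, time_ms = tms)
  df$importance <- as.vector(t(object$importance))
  df$channel <- factor(df$channel, levels = rev(chans))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$channel,
                                   fill = .data$importance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", limits = c(0, 1)) +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  fill = "relative\nimportance") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 4))
}

#' Per-run accuracy plot for an experiment report
#'
#' Shows each run's mean holdout accuracy, the run median, and the chance
#' level; cross-task accuracies are added when present.
#'
#' @param object An `experiment_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.experiment_report <- function(object, ...) {
  df <- tidy(object)
  df$condition <- "within-task"
  if (length(object$runs[[1]]$cross)) {
    cross <- purrr::map_dfr(seq_along(object$runs), function(i) {
      purrr::map_dfr(names(object$runs[[i]]$cross), function(tk) {
        ct <- object$runs[[i]]$cross[[tk]]
        tibble::tibble(run = i,
                       mean_accuracy = mean(ct$per_subject$accuracy),
                       condition = paste0("cross-task (", tk, ")"))
      })
    })
    df <- dplyr::bind_rows(df[, c("run", "mean_accuracy", "condition")],
                           cross)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = 100 * .data$mean_accuracy)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.3, linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = chance_level(object$k_classes),
                        linetype = "dashed") +
    ggplot2::labs(title = object$name, x = NULL, y = "accuracy (%)") +
    ggplot2::theme_minimal(base_size = 10)
}
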