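#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a stimulation pattern as a pulse raster over level frames
#'
#' Level frames are drawn as tiles (time x channel, fill = level) with the
#' scheduled pulse onsets overlaid as ticks, giving the standard view of a
#' continuous-interleaved-sampling pattern.
#'
#' @param object A `stim_pattern` from [encode()] or [schedule_pulses()].
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot stim_pattern
#' @export
autoplot.stim_pattern <- function(object, ...) {
  lv <- tidy(object$level_frames)
  p <- ggplot2::ggplot(lv, ggplot2::aes(x = .data$time_s, y = factor(.data$channel))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$level),
                       width = 1 / object$level_frames$frame_rate) +
    ggplot2::scale_fill_viridis_c(name = "level") +
    ggplot2::labs(x = "time (s)", y = "perceptual channel",
                  title = "Stimulation pattern",
                  subtitle = sprintf("%s, %d bps", format(object$config),
                                     bitrate(object$config)))
  if (nrow(object$pulses) > 0) {
    prim <- dplyr::filter(object$pulses, .data$phase == 1L)
    p <- p + ggplot2::geom_point(
      data = prim,
      ggplot2::aes(x = .data$onset_s, y = factor(.data$channel)),
      shape = "|", size = 2, colour = "white", alpha = 0.6
    )
  }
  p
}

#' Plot extracted envelopes per channel
#'
#' @param env An [extract_envelopes()] result.
#'
#' @return A ggplot object, one facet per channel.
#' @export
plot_envelopes <- function(env) {
  d <- tidy(env)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$envelope)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "envelope (a.u.)",
                  title = "Per-band amplitude envelopes")
}

#' Plot bitrate across configurations
#'
#' @param object A [capacity_report()] tibble.
#' @param ... Unused.
#'
#' @return A ggplot bar chart of bitrate per configuration.
#' @method autoplot capacity_report
#' @export
autoplot.capacity_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$config, .data$bitrate),
                                  y = .data$bitrate)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "bitrate (bps)",
                  title = "Interface information capacity")
}

#' Plot per-participant identification accuracy
#'
#' @param object An [analyze_identification()] result.
#' @param chance Chance level to draw as a dashed line (percent).
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot identification_analysis
#' @export
autoplot.identification_analysis <- function(object, chance = 100 / 3, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$participant, y = .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = .data$marker), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "% correct",
                  title = "Sound identification accuracy",
                  subtitle = "dashed line: chance (1/3)") +
    ggplot2::ylim(0, 100)
}

#' Plot discrimination performance by bitrate condition
#'
#' @param object An [analyze_discrimination()] result.
#' @param ... Unused.
#'
#' @return A ggplot object showing mean accuracy and mean d' per condition.
#' @method autoplot discrimination_analysis
#' @export
autoplot.discrimination_analysis <- function(object, ...) {
  d <- tidyr::pivot_longer(object$by_condition,
                           c("mean_accuracy", "mean_dprime"),
                           names_to = "measure", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(x = "bitrate condition", y = NULL,
                  title = "Same/different discrimination by bitrate")
}
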