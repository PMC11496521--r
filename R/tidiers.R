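#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for spinesound result objects
#'
#' Broom-style accessors: `tidy()` returns the per-unit table of a result
#' (per configuration, per participant, per trial-condition), `glance()` a
#' one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#'
#' @return A tibble.
#' @name spinesound-tidiers
NULL

#' @rdname spinesound-tidiers
#' @method tidy capacity_report
#' @export
tidy.capacity_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname spinesound-tidiers
#' @method tidy stim_pattern
#' @export
tidy.stim_pattern <- function(x, ...) {
  x$pulses
}

#' @rdname spinesound-tidiers
#' @method glance stim_pattern
#' @export
glance.stim_pattern <- function(x, ...) {
  tibble::tibble(
    n_channels = nrow(x$config$channels),
    frame_rate = x$config$frame_rate,
    n_frames = nrow(x$level_frames$levels),
    n_pulses = nrow(x$pulses) / 2,
    duration_s = nrow(x$level_frames$levels) / x$config$frame_rate,
    bitrate = bitrate(x$config)
  )
}

#' @rdname spinesound-tidiers
#' @method tidy level_frames
#' @export
tidy.level_frames <- function(x, ...) {
  lv <- x$levels
  tibble::tibble(
    frame = rep(seq_len(nrow(lv)), times = ncol(lv)),
    channel = rep(seq_len(ncol(lv)), each = nrow(lv)),
    time_s = (rep(seq_len(nrow(lv)), times = ncol(lv)) - 0.5) / x$frame_rate,
    level = as.integer(lv)
  )
}

#' @rdname spinesound-tidiers
#' @method tidy envelope_matrix
#' @export
tidy.envelope_matrix <- function(x, ...) {
  v <- x$values
  tibble::tibble(
    frame = rep(seq_len(nrow(v)), times = ncol(v)),
    channel = rep(seq_len(ncol(v)), each = nrow(v)),
    time_s = (rep(seq_len(nrow(v)), times = ncol(v)) - 0.5) / x$frame_rate,
    envelope = as.numeric(v)
  )
}

#' @rdname spinesound-tidiers
#' @method tidy sim_identification
#' @export
tidy.sim_identification <- function(x, ...) {
  x$log
}

#' @rdname spinesound-tidiers
#' @method glance sim_identification
#' @export
glance.sim_identification <- function(x, ...) {
  dplyr::select(x$result, -"by_category")
}

#' @rdname spinesound-tidiers
#' @method tidy sim_discrimination
#' @export
tidy.sim_discrimination <- function(x, ...) {
  x$log
}

#' @rdname spinesound-tidiers
#' @method glance sim_discrimination
#' @export
glance.sim_discrimination <- function(x, ...) {
  x$result
}

#' @rdname spinesound-tidiers
#' @method glance group_summary
#' @export
glance.group_summary <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname spinesound-tidiers
#' @method tidy discrimination_analysis
#' @export
tidy.discrimination_analysis <- function(x, ...) {
  x$by_condition
}

#' @rdname spinesound-tidiers
#' @method glance discrimination_analysis
#' @export
glance.discrimination_analysis <- function(x, ...) {
  x$t_test
}
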