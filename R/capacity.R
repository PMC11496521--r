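#' Information capacity of an interface configuration
#'
#' Each frame transmits one symbol from the joint alphabet of all channels:
#' with per-channel level counts \eqn{L_1, \dots, L_C} the alphabet has
#' \eqn{\prod_c L_c} states, carrying \eqn{\log_2 \prod_c L_c} bits per frame,
#' and the noiseless bitrate at frame rate \eqn{F} is
#' \eqn{\lfloor F \log_2 \prod_c L_c \rfloor} bits per second. The bitrate
#' truncates (floor) rather than rounds; bits per frame are reported rounded
#' half-up to one decimal. These two conventions jointly reproduce every
#' published session row (e.g. 4 channels x 3 levels at 20 fps: 6.3399 bits ->
#' "6.3" and 126.8 bps -> 126).
#'
#' @param config An [interface_config()].
#'
#' @return `n_states()` the integer joint alphabet size; `bits_per_frame()`
#'   the bits per frame rounded half-up to 1 decimal (set `raw = TRUE` for the
#'   unrounded value); `bitrate()` the integer bits per second.
#' @name capacity
#' @export
#' @examples
#' cfg <- make_config(c(3, 3), frame_rate = 20)
#' n_states(cfg)        # 9
#' bits_per_frame(cfg)  # 3.2
#' bitrate(cfg)         # 63
n_states <- function(config) {
  prod(config$channels$n_levels)
}

#' @rdname capacity
#' @param raw If `TRUE`, return the unrounded log2 value.
#' @export
bits_per_frame <- function(config, raw = FALSE) {
  b <- log2(n_states(config))
  if (raw) b else round_half_up(b, 1)
}

#' @rdname capacity
#' @export
bitrate <- function(config) {
  as.integer(floor_safe(config$frame_rate * bits_per_frame(config, raw = TRUE)))
}

#' Capacity report for one or more configurations
#'
#' Summarises configurations in the layout of the published session table:
#' channels, total levels, bits per frame (1 decimal), frame rate, and integer
#' bitrate. The raw (unrounded) bits-per-frame value is retained in
#' `bits_per_frame_raw`.
#'
#' @param configs An [interface_config()] or a list of them (optionally named).
#'
#' @return A tibble of class `capacity_report` with one row per configuration:
#'   `config`, `n_channels`, `total_levels`, `n_states`, `bits_per_frame_raw`,
#'   `bits_per_frame`, `frame_rate`, `bitrate`.
#' @export
#' @examples
#' capacity_report(list(
#'   baseline = make_config(c(3, 3, 3, 3), 20),
#'   reduced  = make_config(3, 10)
#' ))
capacity_report <- function(configs) {
  if (inherits(configs, "interface_config")) configs <- list(configs)
  nm <- names(configs) %||% paste0("config", seq_along(configs))
  nm[nm == ""] <- paste0("config", seq_along(configs))[nm == ""]
  out <- purrr::map2(configs, nm, function(cfg, name) {
    tibble::tibble(
      config = name,
      n_channels = nrow(cfg$channels),
      total_levels = sum(cfg$channels$n_levels),
      n_states = n_states(cfg),
      bits_per_frame_raw = bits_per_frame(cfg, raw = TRUE),
      bits_per_frame = bits_per_frame(cfg),
      frame_rate = cfg$frame_rate,
      bitrate = bitrate(cfg)
    )
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("capacity_report", class(out))
  out
}

#' Rebuild a configuration from a session-table row
#'
#' Session summaries record only (channels, total levels, frame rate); the
#' per-channel split is recovered with [allocate_levels()].
#'
#' @param n_channels Number of perceptual channels.
#' @param total_levels Total intensity levels summed over channels.
#' @param frame_rate Frames per second.
#' @param ... Passed to [perceptual_channel()] (pulse parameters, amplitudes).
#'
#' @return An [interface_config()].
#' @export
#' @examples
#' bitrate(config_from_summary(2, 7, 20))  # 71
config_from_summary <- function(n_channels, total_levels, frame_rate, ...) {
  make_config(allocate_levels(total_levels, n_channels), frame_rate = frame_rate, ...)
}
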