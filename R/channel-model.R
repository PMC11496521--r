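#' Describe one perceptual channel of a spinal interface
#'
#' A perceptual channel is a calibrated stimulus--sensation mapping: an
#' electrode configuration that evokes a reproducible paresthesia in a distinct
#' body region, together with a discrete alphabet of distinguishable intensity
#' levels. `n_levels` counts the whole alphabet *including* the "off" (no
#' stimulation) state, so a 3-level channel carries log2(3) bits per frame.
#' Levels 1..`n_levels - 1` map linearly onto the calibrated amplitude range
#' `[amp_min, amp_max]`.
#'
#' @param channel_id Small integer identifying the channel; channel order is
#'   frequency-band order, lowest band first.
#' @param n_levels Integer >= 1, size of the intensity alphabet including the
#'   off state.
#' @param amp_min,amp_max Calibrated amplitude bounds in mA (lowest perceptible
#'   and highest comfortable); `0 < amp_min <= amp_max`.
#' @param pulse_frequency Stimulation pulse rate in Hz.
#' @param pulse_width Single-phase pulse width in microseconds.
#' @param dermatome_label Optional free-text body-region label.
#'
#' @return A one-row tibble of class `perceptual_channel`.
#' @export
#' @examples
#' perceptual_channel(1, n_levels = 3)
perceptual_channel <- function(channel_id, n_levels, amp_min = 0.5,
                               amp_max = 2.0, pulse_frequency = 255,
                               pulse_width = 150, dermatome_label = NA_character_) {
  if (n_levels < 1) abort_invalid("`n_levels` must be >= 1")
  if (amp_min <= 0) abort_invalid("`amp_min` must be positive")
  if (amp_min > amp_max) abort_invalid("`amp_min` must not exceed `amp_max`")
  out <- tibble::tibble(
    channel_id = as.integer(channel_id),
    dermatome_label = as.character(dermatome_label),
    n_levels = as.integer(n_levels),
    amp_min = as.numeric(amp_min),
    amp_max = as.numeric(amp_max),
    pulse_frequency = as.numeric(pulse_frequency),
    pulse_width = as.numeric(pulse_width)
  )
  class(out) <- c("perceptual_channel", class(out))
  out
}

#' Assemble a spinal interface configuration
#'
#' An interface configuration is the participant-specific layout every other
#' function consumes: an ordered set of perceptual channels (band order,
#' lowest frequency band first) plus the frame rate at which the per-channel
#' intensity level is refreshed.
#'
#' @param channels A tibble of perceptual channels (rows in band order), e.g.
#'   built with [perceptual_channel()] and `dplyr::bind_rows()`, or a bare
#'   integer vector of per-channel level counts which is expanded with default
#'   pulse parameters.
#' @param frame_rate Frames per second (integer >= 1), e.g. 5, 10, 15 or 20.
#'
#' @return An object of class `interface_config`: a list with elements
#'   `channels` (tibble) and `frame_rate`.
#' @seealso [make_config()] for the common levels-vector shortcut,
#'   [validate_config()], [capacity_report()].
#' @export
#' @examples
#' cfg <- make_config(c(3, 3), frame_rate = 20)
#' bitrate(cfg)
interface_config <- function(channels, frame_rate) {
  if (is.numeric(channels)) {
    channels <- dplyr::bind_rows(
      purrr::imap(as.integer(channels), function(nl, i) perceptual_channel(i, nl))
    )
  }
  if (!is.data.frame(channels) || nrow(channels) < 1) {
    abort_invalid("an interface needs at least one channel")
  }
  frame_rate <- as.integer(frame_rate)
  if (is.na(frame_rate) || frame_rate < 1) abort_invalid("`frame_rate` must be >= 1")
  structure(
    list(channels = tibble::as_tibble(channels), frame_rate = frame_rate),
    class = "interface_config"
  )
}

#' @rdname interface_config
#' @param n_levels Integer vector of per-channel level counts (band order).
#' @param ... Passed on to [perceptual_channel()] for every channel.
#' @export
make_config <- function(n_levels, frame_rate = 20, ...) {
  channels <- dplyr::bind_rows(
    purrr::imap(as.integer(n_levels), function(nl, i) perceptual_channel(i, nl, ...))
  )
  interface_config(channels, frame_rate)
}

#' @export
print.interface_config <- function(x, ...) {
  cat(sprintf(
    "<interface_config> %d channel(s), levels [%s], %d fps, %d bps\n",
    nrow(x$channels), paste(x$channels$n_levels, collapse = ","),
    x$frame_rate, bitrate(x)
  ))
  invisible(x)
}

#' @export
format.interface_config <- function(x, ...) {
  sprintf("%dch/%dlvl/%dfps", nrow(x$channels), sum(x$channels$n_levels), x$frame_rate)
}

#' Stimulation-parameter safety envelope
#'
#' Default limits equal the established ranges for implantable spinal cord
#' neurostimulators used throughout: pulse frequency 120--450 Hz, pulse width
#' 70--450 microseconds, 6.0 mA per contact and 9.0 mA total amplitude.
#'
#' @param freq_range Length-2 numeric, allowed pulse frequency range in Hz.
#' @param width_range Length-2 numeric, allowed pulse width range in
#'   microseconds.
#' @param per_contact_amp_max Maximum single-contact amplitude in mA.
#' @param total_amp_max Maximum summed amplitude across simultaneously active
#'   channels in mA.
#'
#' @return A list of class `safety_limits`.
#' @export
safety_limits <- function(freq_range = c(120, 450), width_range = c(70, 450),
                          per_contact_amp_max = 6.0, total_amp_max = 9.0) {
  stopifnot(length(freq_range) == 2, length(width_range) == 2)
  structure(
    list(
      freq_range = as.numeric(freq_range),
      width_range = as.numeric(width_range),
      per_contact_amp_max = as.numeric(per_contact_amp_max),
      total_amp_max = as.numeric(total_amp_max)
    ),
    class = "safety_limits"
  )
}

#' Split a total level budget across channels
#'
#' Session settings are often summarised as (number of channels, total number
#' of intensity levels); the per-channel split is recovered here. Levels are
#' divided as equally as possible, with any surplus going to the
#' lowest-frequency channels first (speech and music energy concentrates at
#' low frequencies). The equal-as-possible split maximises the product of the
#' per-channel counts over all splits with the given sum, so it is the split
#' under which the joint per-frame alphabet -- and hence the bitrate -- is
#' largest.
#'
#' @param total_levels Total number of intensity levels across all channels.
#' @param n_channels Number of perceptual channels.
#'
#' @return Integer vector of length `n_channels`, each entry >= 1, summing to
#'   `total_levels`, non-increasing and differing by at most 1.
#' @export
#' @examples
#' allocate_levels(6, 2)   # 3 3
#' allocate_levels(7, 2)   # 4 3
#' allocate_levels(12, 4)  # 3 3 3 3
allocate_levels <- function(total_levels, n_channels) {
  total_levels <- as.integer(total_levels)
  n_channels <- as.integer(n_channels)
  if (n_channels < 1) abort_invalid("`n_channels` must be >= 1")
  if (total_levels < n_channels) {
    abort_invalid("`total_levels` must be at least `n_channels` (every channel needs >= 1 level)")
  }
  base <- total_levels %/% n_channels
  extra <- total_levels %% n_channels
  c(rep(base + 1L, extra), rep(base, n_channels - extra))
}

#' Validate an interface configuration against safety limits
#'
#' Produces a report rather than throwing: one row per violated invariant,
#' with a `severity` column distinguishing hard errors from calibration-target
#' warnings. The calibration target -- at least two perceptual channels with at
#' least three levels each -- is aspirational: single-channel sessions occur in
#' practice, so missing it warns but does not invalidate.
#'
#' @param config An [interface_config()].
#' @param limits A [safety_limits()] object.
#'
#' @return A tibble with columns `channel_id` (NA for interface-wide checks),
#'   `check`, `severity` ("error" or "warning") and `message`. A config is
#'   usable for encoding iff the report contains no `"error"` rows.
#' @export
validate_config <- function(config, limits = safety_limits()) {
  if (!inherits(config, "interface_config")) abort_invalid("`config` must be an interface_config")
  ch <- config$channels
  rows <- list()
  flag <- function(channel_id, check, severity, message) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      channel_id = as.integer(channel_id), check = check,
      severity = severity, message = message
    )
  }
  for (i in seq_len(nrow(ch))) {
    r <- ch[i, ]
    if (r$n_levels < 1) flag(r$channel_id, "n_levels", "error", "n_levels must be >= 1")
    if (r$amp_min <= 0) flag(r$channel_id, "amp_min", "error", "amp_min must be > 0 mA")
    if (r$amp_min > r$amp_max) flag(r$channel_id, "amp_order", "error", "amp_min exceeds amp_max")
    if (r$pulse_frequency < limits$freq_range[1] || r$pulse_frequency > limits$freq_range[2]) {
      flag(r$channel_id, "pulse_frequency", "error", sprintf(
        "pulse frequency %.0f Hz outside [%.0f, %.0f] Hz",
        r$pulse_frequency, limits$freq_range[1], limits$freq_range[2]
      ))
    }
    if (r$pulse_width < limits$width_range[1] || r$pulse_width > limits$width_range[2]) {
      flag(r$channel_id, "pulse_width", "error", sprintf(
        "pulse width %.0f us outside [%.0f, %.0f] us",
        r$pulse_width, limits$width_range[1], limits$width_range[2]
      ))
    }
    if (r$amp_max > limits$per_contact_amp_max) {
      flag(r$channel_id, "amp_max", "error", sprintf(
        "amp_max %.1f mA exceeds per-contact limit %.1f mA",
        r$amp_max, limits$per_contact_amp_max
      ))
    }
  }
  if (config$frame_rate < 1) flag(NA, "frame_rate", "error", "frame rate must be >= 1 fps")
  # calibration target: >= 2 channels with >= 3 levels each
  if (sum(ch$n_levels >= 3) < 2) {
    flag(NA, "calibration_target", "warning",
         "fewer than two channels with >= 3 intensity levels (calibration aim unmet)")
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      channel_id = integer(), check = character(),
      severity = character(), message = character()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Read and write interface configuration files
#'
#' Configurations serialise to a documented YAML or JSON schema with keys
#' `frame_rate` and `channels[]`, each channel carrying `n_levels`,
#' `amp_min_mA`, `amp_max_mA`, `pulse_frequency_hz`, `pulse_width_us` and an
#' optional `dermatome_label`. Channel order in the file is the frequency-band
#' order. Reading then writing (or vice versa) is lossless.
#'
#' @param path File path; format is chosen by extension (`.yml`/`.yaml` vs
#'   `.json`).
#' @param config An [interface_config()] to serialise.
#'
#' @return `read_config()` returns an [interface_config()]; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$frame_rate) || is.null(raw$channels) || length(raw$channels) == 0) {
    abort_invalid(sprintf("config file '%s' lacks frame_rate or channels", path))
  }
  channels <- dplyr::bind_rows(purrr::imap(raw$channels, function(chan, i) {
    perceptual_channel(
      channel_id = chan$channel_id %||% i,
      n_levels = chan$n_levels,
      amp_min = chan$amp_min_mA %||% 0.5,
      amp_max = chan$amp_max_mA %||% 2.0,
      pulse_frequency = chan$pulse_frequency_hz %||% 255,
      pulse_width = chan$pulse_width_us %||% 150,
      dermatome_label = chan$dermatome_label %||% NA_character_
    )
  }))
  interface_config(channels, raw$frame_rate)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  ch <- config$channels
  payload <- list(
    frame_rate = config$frame_rate,
    channels = purrr::map(seq_len(nrow(ch)), function(i) {
      r <- ch[i, ]
      out <- list(
        channel_id = r$channel_id,
        n_levels = r$n_levels,
        amp_min_mA = r$amp_min,
        amp_max_mA = r$amp_max,
        pulse_frequency_hz = r$pulse_frequency,
        pulse_width_us = r$pulse_width
      )
      if (!is.na(r$dermatome_label)) out$dermatome_label <- r$dermatome_label
      out
    })
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(payload, path)
  }
  invisible(path)
}
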