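#' Design the analysis filterbank
#'
#' Continuous interleaved sampling splits the audio into as many frequency
#' bands as the interface has perceptual channels. Bands are 4th-order
#' Butterworth band-passes with logarithmically spaced crossover frequencies
#' (the cochlear-implant convention): edges at
#' `f_low * (f_high/f_low)^(k/n_bands)` for `k = 0..n_bands`.
#'
#' @param n_bands Number of bands (= number of perceptual channels), >= 1.
#' @param f_low,f_high Analysis span in Hz; `f_low < f_high <= sample_rate/2`.
#' @param sample_rate Sampling rate of the audio the bank will filter, Hz.
#'
#' @return An object of class `filterbank`: tibble `bands` with columns
#'   `band`, `f_low`, `f_high`, plus attributes for the filter coefficients.
#' @export
#' @examples
#' design_filterbank(2, 100, 8000, 44100)$bands  # crossover at ~894 Hz
design_filterbank <- function(n_bands, f_low = 100, f_high = 8000, sample_rate) {
  if (n_bands < 1) abort_invalid("`n_bands` must be >= 1")
  if (f_low <= 0 || f_low >= f_high) abort_invalid("need 0 < f_low < f_high")
  if (f_high > sample_rate / 2) {
    abort_invalid(sprintf("f_high = %g Hz is above Nyquist (%g Hz)", f_high, sample_rate / 2))
  }
  edges <- f_low * (f_high / f_low)^(seq(0, n_bands) / n_bands)
  bands <- tibble::tibble(
    band = seq_len(n_bands),
    f_low = edges[-length(edges)],
    f_high = edges[-1]
  )
  # order-2 to butter() => 4th-order band-pass
  filters <- purrr::map2(bands$f_low, bands$f_high, function(lo, hi) {
    signal::butter(2, c(lo, hi) / (sample_rate / 2), type = "pass")
  })
  structure(
    list(bands = bands, filters = filters, order = 4L,
         design = "butterworth-log", sample_rate = sample_rate),
    class = "filterbank"
  )
}

#' @export
print.filterbank <- function(x, ...) {
  cat(sprintf("<filterbank> %d band(s), %s, order %d @ %g Hz\n",
              nrow(x$bands), x$design, x$order, x$sample_rate))
  print(x$bands)
  invisible(x)
}

#' Extract per-band amplitude envelopes at the frame rate
#'
#' Per band: band-pass filter, full-wave rectify, smooth with a 2nd-order
#' Butterworth low-pass at `min(frame_rate/2, 50)` Hz (at or below the frame
#' Nyquist so the frame sequence does not alias), then sample once per frame
#' at the frame centre. Frame count is `ceiling(duration * frame_rate)`; a
#' clip shorter than one frame yields a single frame.
#'
#' @param clip An [audio_clip()].
#' @param bank A [design_filterbank()] result with matching sample rate.
#' @param frame_rate Frames per second.
#'
#' @return An object of class `envelope_matrix`: list with `values`
#'   (frames x channels matrix of non-negative reals) and `frame_rate`.
#' @export
extract_envelopes <- function(clip, bank, frame_rate) {
  stopifnot(inherits(clip, "audio_clip"), inherits(bank, "filterbank"))
  if (!isTRUE(all.equal(clip$sample_rate, bank$sample_rate))) {
    abort_invalid("clip and filterbank sample rates differ")
  }
  sr <- clip$sample_rate
  n_frames <- max(1L, as.integer(ceiling(clip$duration * frame_rate)))
  lp_cut <- min(frame_rate / 2, 50)
  lp <- signal::butter(2, lp_cut / (sr / 2), type = "low")
  # frame centres, clamped into the sampled range
  centres <- pmin(length(clip$samples),
                  pmax(1L, as.integer(round((seq_len(n_frames) - 0.5) / frame_rate * sr))))
  vals <- vapply(bank$filters, function(flt) {
    sub <- signal::filter(flt, clip$samples)
    env <- signal::filter(lp, abs(sub))
    pmax(0, as.numeric(env)[centres])
  }, numeric(n_frames))
  vals <- matrix(vals, nrow = n_frames)
  structure(list(values = vals, frame_rate = as.integer(frame_rate)),
            class = "envelope_matrix")
}

#' Quantize envelopes to discrete intensity levels
#'
#' Envelopes are expressed in dB relative to the clip-wide envelope maximum
#' across *all* channels (a single reference per clip, so the relative energy
#' between bands is preserved -- normalising each channel to its own maximum
#' would make spectrally distinct stationary sounds indistinguishable).
#' Frames below the silence floor (default -40 dB) map to level 0 (off); the
#' remaining dynamic range is divided into `n_levels - 1` equal-width dB bins
#' mapping to levels `1..n_levels-1`, with values exactly on a bin edge
#' rounding up. Loudness is logarithmic, hence the dB scale; per-clip
#' normalisation mirrors the per-session presentation-level match. An
#' all-zero channel (or a 1-level channel, whose alphabet is just "off")
#' maps entirely to level 0.
#'
#' @param env An [extract_envelopes()] result.
#' @param config An [interface_config()] with as many channels as `env` has
#'   columns.
#' @param floor_db Silence gate in dB re the channel maximum (negative).
#'
#' @return An object of class `level_frames`: list with `levels` (frames x
#'   channels integer matrix, `0 <= level < n_levels`) and `frame_rate`.
#' @export
quantize_envelopes <- function(env, config, floor_db = -40) {
  stopifnot(inherits(env, "envelope_matrix"), inherits(config, "interface_config"))
  n_ch <- nrow(config$channels)
  if (ncol(env$values) != n_ch) {
    abort_invalid("envelope channel count does not match config channel count")
  }
  if (floor_db >= 0) abort_invalid("`floor_db` must be negative")
  lv <- matrix(0L, nrow = nrow(env$values), ncol = n_ch)
  ref <- max(env$values)
  for (ch in seq_len(n_ch)) {
    n_levels <- config$channels$n_levels[ch]
    if (ref <= 0 || n_levels < 2) next
    db <- ifelse(env$values[, ch] > 0, 20 * log10(env$values[, ch] / ref), -Inf)
    bin_w <- -floor_db / (n_levels - 1)
    lev <- integer(length(db))
    on <- db >= floor_db
    lev[on] <- pmin(n_levels - 1L, 1L + as.integer(floor((db[on] - floor_db) / bin_w)))
    lv[, ch] <- lev
  }
  structure(list(levels = lv, frame_rate = env$frame_rate), class = "level_frames")
}

#' Schedule interleaved charge-balanced pulses from level frames
#'
#' Per frame, every channel whose level is above 0 emits
#' `round(pulse_frequency / frame_rate)` biphasic pulses, evenly spaced
#' within the frame; channel k's train is phase-offset by
#' `(k-1) * slot / n_channels` (slot = frame span / pulses per frame) so that
#' pulses from different channels never overlap -- the interleaving that
#' prevents charge summation across electrodes. Each pulse is a primary phase
#' followed immediately by an equal-charge opposite-polarity recovery phase
#' (active charge balancing; net charge exactly zero). Amplitude is constant
#' within a frame and maps linearly over the calibrated range:
#' `amp_min + (level-1)/(n_levels-2) * (amp_max-amp_min)` for `n_levels >= 3`,
#' `amp_min` for the single on-level of a 2-level channel. Level 0 emits
#' nothing.
#'
#' @param frames A [quantize_envelopes()] result (`level_frames`).
#' @param config The matching [interface_config()].
#'
#' @return An object of class `stim_pattern`: list with `config`,
#'   `level_frames`, and `pulses`, a time-ordered tibble with one row per
#'   pulse phase: `onset_s`, `channel`, `pulse`, `phase` (1 primary / 2
#'   recovery), `amplitude_mA` (signed), `width_us`, `level`.
#' @export
schedule_pulses <- function(frames, config) {
  stopifnot(inherits(frames, "level_frames"), inherits(config, "interface_config"))
  ch <- config$channels
  n_ch <- nrow(ch)
  if (ncol(frames$levels) != n_ch) abort_invalid("level frame / config channel mismatch")
  fr <- frames$frame_rate
  # duty-cycle feasibility: total biphasic on-time per second across channels
  duty <- sum(ch$pulse_frequency * 2 * ch$pulse_width * 1e-6)
  if (duty > 1) {
    bad <- ch$channel_id[ch$pulse_frequency * 2 * ch$pulse_width * 1e-6 > 1 / n_ch]
    abort_invalid(sprintf(
      "infeasible duty cycle (%.2f s/s of pulse time requested); offending channel(s): %s",
      duty, paste(bad, collapse = ", ")
    ))
  }
  frame_span <- 1 / fr
  ppf <- as.integer(round_half_up(ch$pulse_frequency / fr))
  out <- vector("list", n_ch)
  for (k in seq_len(n_ch)) {
    active <- which(frames$levels[, k] > 0L)
    if (length(active) == 0 || ppf[k] == 0) next
    n_levels <- ch$n_levels[k]
    lev <- frames$levels[active, k]
    amp <- if (n_levels >= 3) {
      ch$amp_min[k] + (lev - 1) / (n_levels - 2) * (ch$amp_max[k] - ch$amp_min[k])
    } else {
      rep(ch$amp_min[k], length(lev))
    }
    slot <- frame_span / ppf[k]
    offset <- (k - 1) * slot / n_ch
    onsets <- rep((active - 1) * frame_span, each = ppf[k]) +
      rep((seq_len(ppf[k]) - 1) * slot, times = length(active)) + offset
    out[[k]] <- tibble::tibble(
      channel = ch$channel_id[k],
      pulse = seq_along(onsets),
      onset_s = onsets,
      amplitude_mA = rep(amp, each = ppf[k]),
      width_us = ch$pulse_width[k],
      level = rep(lev, each = ppf[k])
    )
  }
  pulses <- dplyr::bind_rows(out)
  if (nrow(pulses) == 0) {
    pulses <- tibble::tibble(
      onset_s = numeric(), channel = integer(), pulse = integer(),
      phase = integer(), amplitude_mA = numeric(), width_us = numeric(),
      level = integer()
    )
  } else {
    # expand each biphasic pulse into primary + opposite-polarity recovery phase
    w_s <- pulses$width_us * 1e-6
    pulses <- dplyr::bind_rows(
      dplyr::mutate(pulses, phase = 1L),
      dplyr::mutate(pulses, phase = 2L, onset_s = .data$onset_s + w_s,
                    amplitude_mA = -.data$amplitude_mA)
    )
    pulses <- dplyr::arrange(
      dplyr::select(pulses, "onset_s", "channel", "pulse", "phase",
                    "amplitude_mA", "width_us", "level"),
      .data$onset_s, .data$channel, .data$phase
    )
  }
  structure(list(config = config, level_frames = frames, pulses = pulses),
            class = "stim_pattern")
}

#' @export
print.stim_pattern <- function(x, ...) {
  cat(sprintf(
    "<stim_pattern> %s: %d frame(s), %d pulse(s)\n",
    format(x$config), nrow(x$level_frames$levels), nrow(x$pulses) / 2
  ))
  invisible(x)
}

#' Encode an audio clip for a spinal interface
#'
#' The full continuous-interleaved-sampling pipeline: band-split the clip
#' into one band per perceptual channel ([design_filterbank()]), extract
#' frame-rate envelopes ([extract_envelopes()]), quantize each channel's
#' envelope to its intensity-level alphabet ([quantize_envelopes()]), and
#' schedule interleaved charge-balanced biphasic pulses
#' ([schedule_pulses()]). Deterministic: identical inputs give bit-identical
#' patterns.
#'
#' @param clip An [audio_clip()].
#' @param config An [interface_config()].
#' @param f_low,f_high Analysis span in Hz; `f_high` is capped just below the
#'   clip's Nyquist frequency.
#' @param floor_db Silence gate passed to [quantize_envelopes()].
#'
#' @return A `stim_pattern` (see [schedule_pulses()]).
#' @export
#' @examples
#' clip <- make_double_tap(gap_ms = 200, seed = 1)
#' pat <- encode(clip, make_config(c(3, 3), 20))
#' pat
encode <- function(clip, config, f_low = 100, f_high = 8000, floor_db = -40) {
  stopifnot(inherits(clip, "audio_clip"), inherits(config, "interface_config"))
  f_high <- min(f_high, 0.45 * clip$sample_rate)
  bank <- design_filterbank(nrow(config$channels), f_low, f_high, clip$sample_rate)
  env <- extract_envelopes(clip, bank, config$frame_rate)
  frames <- quantize_envelopes(env, config, floor_db = floor_db)
  schedule_pulses(frames, config)
}

#' Check a stimulation pattern against the safety envelope
#'
#' Flags every pulse whose channel frequency, width or amplitude magnitude
#' falls outside the limits, and every frame whose summed active-channel
#' amplitude exceeds the total-amplitude limit. Encoder output under a valid
#' configuration always passes.
#'
#' @param pattern A `stim_pattern`.
#' @param limits A [safety_limits()] object.
#'
#' @return A tibble with columns `check`, `channel`, `frame`, `value`,
#'   `limit`, `message`; zero rows when the pattern is safe.
#' @export
check_safety <- function(pattern, limits = safety_limits()) {
  stopifnot(inherits(pattern, "stim_pattern"))
  ch <- pattern$config$channels
  rows <- list()
  flag <- function(check, channel, frame, value, limit, message) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      check = check, channel = as.integer(channel), frame = as.integer(frame),
      value = as.numeric(value), limit = as.numeric(limit), message = message
    )
  }
  for (k in seq_len(nrow(ch))) {
    if (ch$pulse_frequency[k] < limits$freq_range[1] || ch$pulse_frequency[k] > limits$freq_range[2]) {
      flag("pulse_frequency", ch$channel_id[k], NA, ch$pulse_frequency[k],
           limits$freq_range[2], "pulse frequency outside safe range")
    }
    if (ch$pulse_width[k] < limits$width_range[1] || ch$pulse_width[k] > limits$width_range[2]) {
      flag("pulse_width", ch$channel_id[k], NA, ch$pulse_width[k],
           limits$width_range[2], "pulse width outside safe range")
    }
  }
  p <- pattern$pulses
  if (nrow(p) > 0) {
    over <- dplyr::filter(p, abs(.data$amplitude_mA) > limits$per_contact_amp_max)
    for (i in seq_len(nrow(over))) {
      flag("per_contact_amplitude", over$channel[i], NA, abs(over$amplitude_mA[i]),
           limits$per_contact_amp_max, "pulse amplitude exceeds per-contact limit")
    }
  }
  # per-frame sum of active-channel amplitudes vs total limit
  lv <- pattern$level_frames$levels
  for (f in seq_len(nrow(lv))) {
    amps <- vapply(seq_len(ncol(lv)), function(k) {
      l <- lv[f, k]
      if (l == 0L) return(0)
      nl <- ch$n_levels[k]
      if (nl >= 3) ch$amp_min[k] + (l - 1) / (nl - 2) * (ch$amp_max[k] - ch$amp_min[k])
      else ch$amp_min[k]
    }, numeric(1))
    if (sum(amps) > limits$total_amp_max) {
      flag("total_amplitude", NA, f, sum(amps), limits$total_amp_max,
           "summed active-channel amplitude exceeds total limit")
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(check = character(), channel = integer(), frame = integer(),
                          value = numeric(), limit = numeric(), message = character()))
  }
  dplyr::bind_rows(rows)
}

#' Export or import a stimulation pattern
#'
#' `write_pattern()` serialises a pattern to a JSON container holding the
#' interface configuration, the level frames, and the pulse schedule;
#' `write_schedule_csv()` writes just the pulse schedule as CSV with columns
#' `onset_s, channel, amplitude_mA, width_us, phase`. `read_pattern()`
#' restores the JSON container losslessly.
#'
#' @param pattern A `stim_pattern`.
#' @param path Output path.
#' @return The path, invisibly (`read_pattern()` returns the pattern).
#' @export
write_pattern <- function(pattern, path) {
  payload <- list(
    config = list(
      frame_rate = pattern$config$frame_rate,
      channels = purrr::transpose(as.list(pattern$config$channels))
    ),
    level_frames = list(
      frame_rate = pattern$level_frames$frame_rate,
      levels = unclass(as.data.frame(pattern$level_frames$levels))
    ),
    pulses = as.list(pattern$pulses)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  channels <- tibble::as_tibble(raw$config$channels)
  channels$dermatome_label <- as.character(channels$dermatome_label)
  cfg <- interface_config(channels, raw$config$frame_rate)
  lv <- as.matrix(as.data.frame(raw$level_frames$levels))
  dimnames(lv) <- NULL
  storage.mode(lv) <- "integer"
  frames <- structure(
    list(levels = lv, frame_rate = as.integer(raw$level_frames$frame_rate)),
    class = "level_frames"
  )
  pulses <- tibble::as_tibble(raw$pulses)
  structure(list(config = cfg, level_frames = frames, pulses = pulses),
            class = "stim_pattern")
}

#' @rdname write_pattern
#' @export
write_schedule_csv <- function(pattern, path) {
  utils::write.csv(
    pattern$pulses[, c("onset_s", "channel", "amplitude_mA", "width_us", "phase")],
    path, row.names = FALSE
  )
  invisible(path)
}
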