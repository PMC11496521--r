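# Synthetic stimulus generators. The identification experiment used everyday
# recordings grouped into seven categories; these generators emulate the
# *structure* of each category (temporal gaps, spectral alternation, note
# sequences, noise bands, vowel-like formants), not the original recordings,
# so the whole encode/simulate pipeline is testable from code alone.

FIXTURE_SR <- 16000

fade <- function(x, sr, ms = 5) {
  n <- min(length(x), max(1L, as.integer(sr * ms / 1000)))
  ramp <- seq(0, 1, length.out = n)
  x[seq_len(n)] <- x[seq_len(n)] * ramp
  x[seq(length(x) - n + 1, length(x))] <- x[seq(length(x) - n + 1, length(x))] * rev(ramp)
  x
}

normalize_full_scale <- function(x) {
  m <- max(abs(x))
  if (m > 0) x / m * 0.95 else x
}

#' Synthesize a "double tap" stimulus
#'
#' Two identical short broadband bursts separated by a silent gap -- the
#' category used in the same/different discrimination experiment, where the
#' discriminating cue is the gap duration. Deterministic given `seed`.
#'
#' @param gap_ms Silent gap between the taps, ms (> 0).
#' @param tap_duration_ms Duration of each burst, ms.
#' @param seed Integer seed for the burst noise.
#' @param sample_rate Sampling rate, Hz.
#'
#' @return An [audio_clip()], full-scale normalised, with 100 ms of leading
#'   and trailing padding.
#' @export
#' @examples
#' make_double_tap(gap_ms = 200, seed = 1)
make_double_tap <- function(gap_ms, tap_duration_ms = 50, seed = 1,
                            sample_rate = FIXTURE_SR) {
  if (gap_ms <= 0 || tap_duration_ms <= 0) abort_invalid("durations must be positive")
  sr <- sample_rate
  tap_n <- as.integer(sr * tap_duration_ms / 1000)
  gap_n <- as.integer(sr * gap_ms / 1000)
  pad_n <- as.integer(sr * 0.1)
  tap <- with_seed(seed, stats::rnorm(tap_n))
  tap <- fade(tap * exp(-seq_len(tap_n) / (0.4 * tap_n)), sr, 2)
  x <- c(rep(0, pad_n), tap, rep(0, gap_n), tap, rep(0, pad_n))
  audio_clip(normalize_full_scale(x), sr)
}

#' Synthesize an "alternating" stimulus
#'
#' A square alternation between two pure tones: `f1_hz` for one half-period,
#' then `f2_hz`, repeating for `duration_s`. With a two-band interface the
#' envelope dominance alternates between the channels.
#'
#' @param f1_hz,f2_hz Distinct tone frequencies, Hz, below Nyquist.
#' @param period_ms Full alternation period, ms.
#' @param duration_s Total duration, s.
#' @param sample_rate Sampling rate, Hz.
#'
#' @return An [audio_clip()].
#' @export
make_alternating <- function(f1_hz, f2_hz, period_ms = 500, duration_s = 2,
                             sample_rate = FIXTURE_SR) {
  if (f1_hz == f2_hz) abort_invalid("`f1_hz` and `f2_hz` must differ")
  if (max(f1_hz, f2_hz) >= sample_rate / 2) abort_invalid("tone frequency above Nyquist")
  sr <- sample_rate
  t <- seq_len(as.integer(sr * duration_s)) / sr
  half <- period_ms / 2000  # seconds
  in_first <- (t %% (2 * half)) < half
  x <- ifelse(in_first, sin(2 * pi * f1_hz * t), sin(2 * pi * f2_hz * t))
  audio_clip(normalize_full_scale(fade(x, sr)), sr)
}

#' Synthesize a note sequence (piano / "elise" surrogates)
#'
#' Concatenated decaying harmonic tones at the given MIDI pitches -- a
#' surrogate for short melodic excerpts. The default pitch list of
#' [make_elise()] is the familiar eight-note opening figure
#' (E5 D#5 E5 D#5 E5 B4 D5 C5).
#'
#' @param midi_notes Non-empty integer vector of MIDI note numbers.
#' @param note_ms Duration per note, ms.
#' @param waveform `"harmonic"` (decaying 4-partial tone) or `"sine"`.
#' @param sample_rate Sampling rate, Hz.
#'
#' @return An [audio_clip()].
#' @export
make_note_sequence <- function(midi_notes, note_ms = 250, waveform = "harmonic",
                               sample_rate = FIXTURE_SR) {
  if (length(midi_notes) == 0) abort_invalid("`midi_notes` must be non-empty")
  waveform <- match.arg(waveform, c("harmonic", "sine"))
  sr <- sample_rate
  note_n <- as.integer(sr * note_ms / 1000)
  t <- seq_len(note_n) / sr
  x <- unlist(lapply(midi_notes, function(m) {
    f0 <- 440 * 2^((m - 69) / 12)
    tone <- if (waveform == "harmonic") {
      h <- 0
      for (p in 1:4) if (p * f0 < sr / 2) h <- h + sin(2 * pi * p * f0 * t) / p
      h
    } else {
      sin(2 * pi * f0 * t)
    }
    fade(tone * exp(-3 * t / max(t)), sr, 3)
  }))
  audio_clip(normalize_full_scale(x), sr)
}

#' @rdname make_note_sequence
#' @export
make_elise <- function(note_ms = 250, sample_rate = FIXTURE_SR) {
  make_note_sequence(c(76, 75, 76, 75, 76, 71, 74, 72), note_ms = note_ms,
                     sample_rate = sample_rate)
}

#' Synthesize a band-limited noise burst ("noisy" surrogate)
#'
#' White noise band-pass filtered to `band_hz`; deterministic given `seed`.
#'
#' @param band_hz Length-2 numeric, pass band in Hz (below Nyquist).
#' @param duration_s Duration, s.
#' @param seed Integer seed.
#' @param sample_rate Sampling rate, Hz.
#'
#' @return An [audio_clip()].
#' @export
make_noise_burst <- function(band_hz, duration_s = 1, seed = 1,
                             sample_rate = FIXTURE_SR) {
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[1] >= band_hz[2]) {
    abort_invalid("`band_hz` must be an increasing positive pair")
  }
  if (band_hz[2] >= sample_rate / 2) abort_invalid("band edge above Nyquist")
  sr <- sample_rate
  x <- with_seed(seed, stats::rnorm(as.integer(sr * duration_s)))
  flt <- signal::butter(2, band_hz / (sr / 2), type = "pass")
  x <- as.numeric(signal::filter(flt, x))
  audio_clip(normalize_full_scale(fade(x, sr)), sr)
}

#' Synthesize a vowel-like formant word (numbers / voices surrogates)
#'
#' A harmonic glottal-like source (100 Hz fundamental, gently sloped
#' spectrum) shaped by two-pole resonances at the given formant frequencies.
#' Genuine speech is out of scope; these surrogates carry speech-like
#' spectral envelopes so the categories exercise distinct channels.
#'
#' @param formants_hz Numeric vector of formant centre frequencies, Hz.
#' @param duration_s Duration, s.
#' @param f0_hz Fundamental (voice pitch), Hz.
#' @param seed Integer seed (adds slight aspiration noise).
#' @param sample_rate Sampling rate, Hz.
#'
#' @return An [audio_clip()].
#' @export
make_formant_word <- function(formants_hz, duration_s = 0.8, f0_hz = 100,
                              seed = 1, sample_rate = FIXTURE_SR) {
  if (length(formants_hz) == 0 || any(formants_hz <= 0)) {
    abort_invalid("`formants_hz` must be positive frequencies")
  }
  if (max(formants_hz) >= sample_rate / 2) abort_invalid("formant above Nyquist")
  sr <- sample_rate
  n <- as.integer(sr * duration_s)
  t <- seq_len(n) / sr
  f0 <- f0_hz
  src <- 0
  for (p in seq_len(floor(min(4000, sr / 2 - 1) / f0))) {
    src <- src + sin(2 * pi * p * f0 * t) / p
  }
  src <- src + 0.05 * with_seed(seed, stats::rnorm(n))
  x <- src
  for (f in formants_hz) {
    r <- exp(-pi * 120 / sr)  # ~120 Hz formant bandwidth
    a <- c(1, -2 * r * cos(2 * pi * f / sr), r^2)
    x <- as.numeric(signal::filter(signal::Arma(b = 1 - r, a = a), x))
  }
  audio_clip(normalize_full_scale(fade(x, sr)), sr)
}

#' Deterministic fixture catalog: seven categories, three items each
#'
#' Mirrors the blocked design of the identification experiment, where each
#' test block mixed three items from one category. Categories: `double_tap`,
#' `alternating`, `piano`, `elise`, `noisy`, `numbers`, `voices`. The third
#' `elise` item and the first `piano` item share the same underlying note
#' list (one item was shared between those two categories in the study).
#'
#' @param seed Integer seed; the same seed always yields the same catalog.
#'
#' @return A tibble with one row per item: `category`, `item_id`, `params`
#'   (list-column), and `clip` (list-column of [audio_clip()]s).
#' @export
#' @examples
#' cat21 <- fixture_catalog(seed = 1)
#' nrow(cat21)  # 21
fixture_catalog <- function(seed = 1) {
  specs <- list(
    double_tap = list(
      list(gap_ms = 150), list(gap_ms = 300), list(gap_ms = 450)
    ),
    alternating = list(
      list(f1_hz = 300, f2_hz = 2000, period_ms = 400),
      list(f1_hz = 500, f2_hz = 3000, period_ms = 800),
      list(f1_hz = 250, f2_hz = 1200, period_ms = 250)
    ),
    piano = list(
      list(midi_notes = c(76, 75, 76, 75, 76, 71, 74, 72)),  # shared item
      list(midi_notes = c(60, 64, 67, 72)),
      list(midi_notes = c(72, 67, 64, 60, 64, 67))
    ),
    elise = list(
      list(midi_notes = c(64, 66, 68, 69, 71, 73, 75, 76)),
      list(midi_notes = c(69, 69, 71, 69, 74, 73)),
      list(midi_notes = c(76, 75, 76, 75, 76, 71, 74, 72))   # shared item
    ),
    noisy = list(
      list(band_hz = c(200, 800)),
      list(band_hz = c(1000, 3000)),
      list(band_hz = c(3000, 7000))
    ),
    numbers = list(
      list(formants_hz = c(700, 1200), duration_s = 0.6),
      list(formants_hz = c(300, 2300), duration_s = 0.8),
      list(formants_hz = c(400, 800), duration_s = 1.0)
    ),
    voices = list(
      list(formants_hz = c(500, 1500, 2500), duration_s = 0.9, f0_hz = 95),
      list(formants_hz = c(250, 2100, 3000), duration_s = 0.7, f0_hz = 160),
      list(formants_hz = c(600, 900, 2600), duration_s = 1.1, f0_hz = 220)
    )
  )
  rows <- purrr::imap(specs, function(items, category) {
    purrr::imap(items, function(params, i) {
      item_seed <- (seed * 100 + match(category, names(specs)) * 10 + i) %% .Machine$integer.max
      clip <- switch(category,
        double_tap = do.call(make_double_tap, c(params, list(seed = item_seed))),
        alternating = do.call(make_alternating, params),
        piano = do.call(make_note_sequence, params),
        elise = do.call(make_note_sequence, params),
        noisy = do.call(make_noise_burst, c(params, list(seed = item_seed))),
        numbers = do.call(make_formant_word, c(params, list(seed = item_seed))),
        voices = do.call(make_formant_word, c(params, list(seed = item_seed)))
      )
      tibble::tibble(
        category = category,
        item_id = sprintf("%s_%d", category, i),
        params = list(params),
        clip = list(clip)
      )
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}

#' Write a fixture catalog to WAV files with a manifest
#'
#' @param catalog A [fixture_catalog()] tibble.
#' @param outdir Output directory (created if needed).
#'
#' @return Invisibly, the manifest path. Writes one WAV per item plus
#'   `manifest.json` mapping `item_id` to category and parameters.
#' @export
write_fixtures <- function(catalog, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(catalog))) {
    write_wav(catalog$clip[[i]], file.path(outdir, paste0(catalog$item_id[i], ".wav")))
  }
  manifest <- purrr::map(seq_len(nrow(catalog)), function(i) {
    list(item_id = catalog$item_id[i], category = catalog$category[i],
         file = paste0(catalog$item_id[i], ".wav"),
         params = catalog$params[[i]])
  })
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
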