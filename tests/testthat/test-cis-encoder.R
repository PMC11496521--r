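test_that("filterbank edges are log-spaced between the span bounds", {
  fb2 <- design_filterbank(2, 100, 8000, 44100)
  expect_equal(fb2$bands$f_high[1], sqrt(100 * 8000), tolerance = 1e-10)

  fb1 <- design_filterbank(1, 100, 8000, 44100)
  expect_equal(unlist(fb1$bands[, c("f_low", "f_high")]), c(100, 8000),
               ignore_attr = TRUE)

  fb4 <- design_filterbank(4, 100, 8000, 44100)
  expect_equal(c(fb4$bands$f_low, 8000), 100 * 80^(0:4 / 4), tolerance = 1e-10)

  expect_error(design_filterbank(2, 100, 9000, 16000), class = "spinesound_invalid")
})

test_that("envelope extraction is silent for silence, band-selective, and linear", {
  sr <- 16000
  bank <- design_filterbank(2, 100, 7200, sr)

  silence <- audio_clip(rep(0, sr), sr)
  env0 <- extract_envelopes(silence, bank, 20)
  expect_true(all(env0$values == 0))
  expect_equal(nrow(env0$values), 20)

  # crossover is sqrt(100*7200) = 849 Hz: a 2 kHz tone must dominate band 2
  t <- seq_len(sr) / sr
  tone <- audio_clip(0.8 * sin(2 * pi * 2000 * t), sr)
  env <- extract_envelopes(tone, bank, 20)
  steady <- 10:18  # skip onset transient
  expect_true(all(env$values[steady, 2] > env$values[steady, 1]))

  # linearity: doubling the waveform doubles the envelope
  half <- audio_clip(0.4 * sin(2 * pi * 2000 * t), sr)
  env_half <- extract_envelopes(half, bank, 20)
  expect_equal(env$values, 2 * env_half$values, tolerance = 1e-8)

  # a clip shorter than one frame still yields one frame
  tiny <- audio_clip(rep(0.1, 100), sr)
  expect_equal(nrow(extract_envelopes(tiny, bank, 20)$values), 1)
})

test_that("quantization gates silence, fills the top bin, and bins in equal dB steps", {
  fake_env <- function(vals) {
    structure(list(values = vals, frame_rate = 20L), class = "envelope_matrix")
  }
  cfg3 <- make_config(3, 20)

  expect_true(all(quantize_envelopes(fake_env(matrix(0, 5, 1)), cfg3)$levels == 0))

  # -50, -25, -5 dB re max with a -40 dB floor and two 20-dB bins -> 0, 1, 2
  env <- fake_env(matrix(10^(c(-50, -25, -5, 0) / 20), ncol = 1))
  expect_equal(as.integer(quantize_envelopes(env, cfg3)$levels), c(0L, 1L, 2L, 2L))

  # the globally loudest frame lands in the top bin
  expect_equal(max(quantize_envelopes(env, cfg3)$levels), cfg3$channels$n_levels - 1L)

  # bin-edge ties round up: exactly -20 dB goes to level 2 of 3
  env_edge <- fake_env(matrix(c(10^(-20 / 20), 1), ncol = 1))
  expect_equal(as.integer(quantize_envelopes(env_edge, cfg3)$levels), c(2L, 2L))

  # a 1-level channel maps entirely to "off"
  cfg1 <- make_config(1, 20)
  expect_true(all(quantize_envelopes(fake_env(matrix(1, 4, 1)), cfg1)$levels == 0))

  expect_error(quantize_envelopes(fake_env(matrix(1, 2, 2)), cfg3),
               class = "spinesound_invalid")
})

test_that("pulse scheduling emits the per-frame pulse count with interleaving and zero net charge", {
  lf <- function(m, fr) structure(list(levels = m, frame_rate = fr), class = "level_frames")

  # all-zero frames -> empty schedule
  cfg <- make_config(c(3, 3), 20)
  empty <- schedule_pulses(lf(matrix(0L, 4, 2), 20L), cfg)
  expect_equal(nrow(empty$pulses), 0)

  # 1 channel at 250 Hz, 20 fps, one frame at top level -> round(12.5) = 13 pulses
  cfg250 <- make_config(3, 20, pulse_frequency = 250)
  pat <- schedule_pulses(lf(matrix(2L, 1, 1), 20L), cfg250)
  expect_equal(nrow(pat$pulses) / 2, 13)
  expect_true(all(pat$pulses$onset_s < 1 / 20 + 1e-12))
  # top level of a 3-level channel maps to amp_max
  expect_equal(max(pat$pulses$amplitude_mA), cfg250$channels$amp_max)

  # amplitude interpolation: mid level of a 4-level channel
  cfg4 <- make_config(4, 20, amp_min = 1, amp_max = 3)
  mid <- schedule_pulses(lf(matrix(2L, 1, 1), 20L), cfg4)
  expect_equal(unique(abs(mid$pulses$amplitude_mA)), 2)  # 1 + (2-1)/2 * 2

  # 2-level channel: its single on-level stimulates at amp_min
  cfg2 <- make_config(2, 20, amp_min = 0.9, amp_max = 1.8)
  two <- schedule_pulses(lf(matrix(1L, 1, 1), 20L), cfg2)
  expect_equal(unique(abs(two$pulses$amplitude_mA)), 0.9)

  # duty-cycle infeasibility: 3 channels x 450 Hz x 900 us biphasic = 1.2 s/s
  hot <- make_config(c(3, 3, 3), 20, pulse_frequency = 450, pulse_width = 450)
  expect_error(schedule_pulses(lf(matrix(1L, 1, 3), 20L), hot), "duty cycle")
})

test_that("every biphasic pulse carries zero net charge", {
  pat <- encode(make_double_tap(200, seed = 4), baseline_config())
  charge <- dplyr::summarise(
    dplyr::group_by(pat$pulses, channel, pulse),
    q = sum(amplitude_mA * width_us), n_phases = dplyr::n(), .groups = "drop"
  )
  expect_true(all(charge$n_phases == 2))
  expect_true(all(abs(charge$q) < 1e-12))
})

test_that("encoded patterns never overlap pulses across channels", {
  cat21 <- test_catalog()
  some <- cat21[cat21$category %in% c("double_tap", "alternating", "voices"), ]
  for (i in seq_len(nrow(some))) {
    pat <- encode(some$clip[[i]], rich_config())
    prim <- dplyr::arrange(dplyr::filter(pat$pulses, phase == 1), onset_s)
    if (nrow(prim) < 2) next
    ends <- prim$onset_s + 2 * prim$width_us * 1e-6
    expect_true(all(ends[-length(ends)] <= prim$onset_s[-1] + 1e-12),
                info = some$item_id[i])
  }
})

test_that("encode composes the stages deterministically", {
  clip <- make_double_tap(200, seed = 2)

  silence <- audio_clip(rep(0, 16000), 16000)
  expect_equal(nrow(encode(silence, baseline_config())$pulses), 0)

  pat20 <- encode(clip, make_config(c(3, 3), 20))
  pat10 <- encode(clip, make_config(c(3, 3), 10))
  expect_equal(nrow(pat10$level_frames$levels),
               ceiling(nrow(pat20$level_frames$levels) / 2))

  again <- encode(clip, make_config(c(3, 3), 20))
  expect_identical(pat20$level_frames$levels, again$level_frames$levels)
  expect_identical(pat20$pulses, again$pulses)
})

test_that("a full-scale chirp visits every level of every channel", {
  sr <- 16000
  t <- seq_len(3 * sr) / sr
  # exponential sweep through the analysis span with a rising amplitude ramp
  f0 <- 100; f1 <- 7000
  phase <- 2 * pi * f0 * (exp(t / max(t) * log(f1 / f0)) - 1) / (log(f1 / f0) / max(t))
  chirp <- audio_clip(sin(phase) * seq(0.02, 1, length.out = length(t)), sr)
  pat <- encode(chirp, make_config(c(3, 3), 20))
  for (ch in 1:2) {
    expect_setequal(unique(pat$level_frames$levels[, ch]), 0:2)
  }
})

test_that("encoder output from valid configs passes the safety check", {
  pat <- encode(make_alternating(300, 2000), rich_config())
  expect_equal(nrow(check_safety(pat)), 0)
})

test_that("check_safety flags out-of-range hand-built patterns", {
  lf <- structure(list(levels = matrix(1L, 1, 1), frame_rate = 20L),
                  class = "level_frames")
  # amplitude over the 6 mA per-contact limit (bypass validation deliberately)
  cfg_hot <- make_config(2, 20, amp_min = 7, amp_max = 7)
  pat <- schedule_pulses(lf, cfg_hot)
  expect_true("per_contact_amplitude" %in% check_safety(pat)$check)

  cfg_slow <- make_config(2, 20, pulse_frequency = 100)
  pat2 <- schedule_pulses(lf, cfg_slow)
  expect_true("pulse_frequency" %in% check_safety(pat2)$check)

  # frame amplitude sum over the 9 mA total limit
  cfg_sum <- make_config(c(2, 2), 20, amp_min = 5, amp_max = 5)
  lf2 <- structure(list(levels = matrix(1L, 1, 2), frame_rate = 20L),
                   class = "level_frames")
  pat3 <- schedule_pulses(lf2, cfg_sum)
  expect_true("total_amplitude" %in% check_safety(pat3)$check)
})

test_that("patterns round-trip through the JSON container and CSV schedule", {
  pat <- encode(make_double_tap(150, seed = 3), baseline_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_pattern(pat, path)
  back <- read_pattern(path)
  expect_identical(back$level_frames$levels, pat$level_frames$levels)
  expect_equal(back$pulses$onset_s, pat$pulses$onset_s)
  expect_equal(back$pulses$amplitude_mA, pat$pulses$amplitude_mA)
  expect_equal(bitrate(back$config), bitrate(pat$config))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_schedule_csv(pat, csv)
  sched <- utils::read.csv(csv)
  expect_equal(nrow(sched), nrow(pat$pulses))
  expect_named(sched, c("onset_s", "channel", "amplitude_mA", "width_us", "phase"))
})

test_that("WAV files round-trip at 16-bit precision", {
  clip <- make_alternating(300, 2000, duration_s = 0.3)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate, clip$sample_rate)
  expect_equal(length(back$samples), length(clip$samples))
  expect_lt(max(abs(back$samples - clip$samples)), 2 / 32768)
  expect_error(audio_clip(1:10 / 10, 4000), class = "spinesound_invalid")
})
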