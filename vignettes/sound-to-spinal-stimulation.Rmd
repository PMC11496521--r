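---
title: "Encoding sound as spinal cord stimulation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding sound as spinal cord stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinesound)
```

## The interface model

A spinal cord stimulation implant, calibrated so that distinct electrode
configurations evoke reproducible paresthesias in distinct body regions,
behaves as a set of *perceptual channels*. Each channel carries a discrete
intensity alphabet: an "off" state plus one or more perceptible amplitude
steps between the lowest perceptible (`amp_min`, mA) and highest
comfortable (`amp_max`, mA) calibrated bounds. The whole interface is
described by an `interface_config`: an ordered list of channels (frequency
band order, lowest band first) and a frame rate `F` (frames per second) at
which every channel's level is refreshed.

Treating each frame as one symbol from the joint alphabet of all channels
gives the capacity accounting implemented in `n_states()`,
`bits_per_frame()` and `bitrate()`:

* joint states per frame: \(S = \prod_c L_c\) (product of per-channel level
  counts),
* bits per frame: \(\log_2 S\),
* bitrate: \(\lfloor F \log_2 S \rfloor\) bits/s.

Two conventions matter and were fixed by cross-checking all 23 published
session rows. **The off state counts as a level**: a single-channel,
3-level session reports \(\log_2 3 = 1.6\) bits per frame, so silence is
inside the alphabet, not in addition to it. **The bitrate truncates**:
rounding would report 127 bps for the 4-channel/12-level/20-fps session
(\(20 \times 6.3399 = 126.8\)), while every published row matches the
floored value (126). Bits per frame are displayed rounded half-up to one
decimal (3.1699 → 3.2); R's default banker's rounding would not reproduce
the published table either.

Session summaries record only the *total* level count. `allocate_levels()`
recovers the per-channel split as the equal-as-possible partition, which
uniquely maximises \(\prod_c L_c\) for a fixed sum — the only split
consistent with the published bits-per-frame values (e.g. 7 levels over 2
channels must be 4 × 3 = 12 states to give 3.6 bits and 71 bps). When the
split is uneven the surplus goes to the lower-frequency channels, since
speech and music concentrate energy at low frequencies; capacity itself is
split-order-invariant, so this choice affects only the encoding.

## The encoding pipeline

`encode()` implements continuous interleaved sampling in four stages.

**Filterbank** (`design_filterbank()`). One 4th-order Butterworth band-pass
per perceptual channel, crossovers log-spaced over the analysis span
(default 100–8000 Hz, capped below the clip's Nyquist frequency). Log
spacing is the cochlear-implant convention; the band count always equals
the channel count.

**Envelopes** (`extract_envelopes()`). Per band: full-wave rectification,
then a 2nd-order Butterworth low-pass at `min(F/2, 50)` Hz, sampled once
per frame at the frame centre. Cutting at the frame Nyquist prevents
envelope fluctuations from aliasing into the frame sequence. Frame count is
`ceiling(duration × F)`; a clip shorter than one frame yields one frame.

**Quantization** (`quantize_envelopes()`). Envelopes are expressed in dB
relative to the clip-wide envelope maximum across *all* channels. A silence
gate maps frames below −40 dB to level 0; the remaining 40 dB are split
into `n_levels − 1` equal bins for levels 1 … `n_levels − 1`, bin-edge ties
rounding up. Two choices deserve comment. The dB scale follows loudness
perception; −40 dB is a conventional dynamic-range floor for envelope
coding, and with typical 3-level channels it yields two perceptually wide
20-dB bins. The *global* (all-channel) reference is deliberate: an earlier
per-channel normalisation made every spectrally stationary stimulus
identical on every channel — each channel saturated at its own maximum, so
a low noise band and a high noise band quantized to the same pattern.
A single reference preserves relative band energy, which is exactly the
spectral contrast the interface is supposed to convey; the cost is that a
weak channel may never reach its top level on a given clip.

**Scheduling** (`schedule_pulses()`). Per frame, a channel at level > 0
emits `round(pulse_frequency / F)` biphasic pulses (half-up, so 255 Hz at
20 fps gives 13), evenly spaced within the frame; channel *k*'s train is
phase-offset by `(k−1)/n_channels` of the inter-pulse slot, which
interleaves the channels so no two pulses ever coincide — preventing charge
summation across electrodes. Every pulse is a primary phase followed
immediately by an equal-magnitude opposite-polarity recovery phase of the
same width (active charge balancing: net charge is exactly zero).
Amplitude is constant within a frame and linear in level between the
calibrated bounds (`amp_min` at level 1, `amp_max` at the top level; a
2-level channel stimulates at `amp_min`). Linearity is justified because
calibration already chose perceptually spaced endpoints. A feasibility
check rejects configurations whose summed biphasic duty cycle exceeds one
second per second, naming the offending channels.

Safety is audited separately (`check_safety()`) against the implant
envelope: pulse frequency 120–450 Hz, width 70–450 µs, ≤ 6.0 mA per
contact, and ≤ 9.0 mA summed over the channels active in a frame. The
default synthetic amplitude range (0.5–2.0 mA per channel) keeps even a
fully active 4-channel frame under the total limit; real calibrated
configurations supply their own bounds.

Whether the source study held amplitude constant between frame updates, and
how its per-channel stimulation rate related to the frame rate, is not
documented; constant-per-frame amplitude and the `round(f/F)` pulse-count
rule are one consistent reading of a 5–20 fps update-rate design.
Which frequency band was routed to which dermatome is likewise unknown;
the package uses list order.

## Synthetic stimuli

`fixture_catalog()` builds seven categories × three items, mirroring the
blocked three-alternative design of the identification experiment: double
taps (two broadband bursts, gaps 150/300/450 ms — the gap is the
discriminative cue, and these items also drive the discrimination
simulation), alternating two-tone squares, two note-sequence categories
(one item deliberately shared between them, as in the study's stimulus
collection), band-limited noise bursts, and formant-shaped harmonic
"words" standing in for spoken numbers and voices (different durations and
fundamentals per item; genuine speech is out of scope). All items are
deterministic given the seed, mono, ≤ 5 s, 16 kHz, full-scale normalised.

The catalog emulates the *structure* of the experimental categories, not
the original recordings — durations, pitches and exact spectra of those
recordings were never published. Consequently, passing tests demonstrate
that the pipeline separates structurally distinct sounds under realistic
interface configurations; they say nothing about absolute human
recognition rates for everyday sounds.

## Statistics

All statistics of the study's analysis plan operate on summary tables or
trial logs:

* `binomial_test_vs_chance()` — exact upper tail \(P(X \ge k)\) under
  Binomial(n, 1/3); per-participant test against chance.
* `wilcoxon_signed_rank_one_sided()` — exact permutation p-value for the
  group-level test. The null distribution of the positive-rank sum is built
  by a generating-function convolution, which equals full \(2^n\) sign
  enumeration (the test suite verifies this against brute force up to
  n = 12) while handling ties via average ranks; zero differences are
  dropped. With eight uniformly positive differences this gives exactly
  1/256 = 0.0039.
* `dprime()` — \(\Phi^{-1}(\mathrm{hit}) - \Phi^{-1}(\mathrm{fa})\) with
  "different" as the signal class; observed rates of exactly 0 or 1 are
  replaced by \(1/2N\) and \(1 - 1/2N\). The 1/(2N) rule is the standard
  correction in the signal-detection literature; the study names none, and
  its d′ values cannot be recomputed from percent correct alone, so no
  exact-match test is keyed to them.
* `paired_t_one_tailed()` — t on paired differences (reduced − baseline),
  lower-tail p, for the d′ drop.
* `group_summary()` — mean, sample SD, t-based 95 % CI.

Group means over published tables first recover integer correct-trial
counts from the printed 1-decimal percentages
(`counts_from_percent()`); averaging exact fractions reproduces the
published 88.3 % where naive averaging of rounded percentages gives 88.4.
The bundled `session_settings()`, `experiment1_results()` and
`experiment2_results()` tables transcribe the study's summary tables and
are the inputs to these reproductions.

## The observer simulation

`run_experiment1()` and `run_experiment2()` simulate both experiments with
an ideal observer that sees only noisy level frames — deliberately less
information than human participants, who may also use dermatome location
and timing cues; the simulator demonstrates the *direction* of the
bitrate–performance relationship and its chance-level anchors, and is not
a model of human accuracy.

Noise acts in level space, after quantization: each frame/channel entry is
redrawn from a discretized Gaussian centred on the true level (standard
deviation `sigma`, in level units), truncated and renormalised over the
channel's alphabet. Truncation, rather than boundary clipping, keeps the
large-noise limit uniform over the alphabet instead of piling mass onto
the extreme levels. Level space is the right place for perceptual
confusion noise because the calibration procedure equates discriminable
intensity *steps* across participants. A `lapse` probability mixes in
uniformly random responses.

The identification observer (`identify_3afc()`) picks the template with
the smallest mean absolute level difference (sequences zero-padded to a
common length; ties to the lowest index — levels are ordinal by
construction, so an L1 distance is natural). The discrimination observer
(`same_different()`) thresholds the same distance; its default criterion
assumes the observer knows the noise statistics, sitting midway between
the expected distances of noisy same pairs and noisy different pairs
(estimated from a short seeded calibration run per condition). Pairs
follow the study's balanced design: every stimulus and every pair used
equally often, 50-50 same/different, order shuffled, condition order
counterbalanced.

`reduce_bitrate()` derives the reduced condition in the two styles present
in the published sessions: halving the frame rate (63 → 31 bps; requires
an even frame rate) or collapsing to one 3-level channel at 10 fps
(63 → 15 bps; requires ≥ 30 bps to start from). Both guarantee the
reduced bitrate is at most half the baseline, and a minimal configuration
(e.g. one 3-level channel at 5 fps) is rejected by both modes.

The default noise level for the discrimination demonstration is
`sigma = 0.66`, calibrated once so that simulated baseline accuracy for
the standard 63 bps → 15 bps comparison sits near the high-baseline
regime of the study (≈ 88 % correct), and left fixed thereafter. Under
that noise the reduced condition is reliably harder across seeds, which is
the qualitative claim the simulation is meant to exhibit.

## Problem sizes and runtime choices

The test-suite simulations use sizes chosen to keep Monte-Carlo error
small relative to the effects under test while remaining comfortable to
run interactively: 48 pairs per condition (the modal published session
size) over 20 seeded replicates for the directional d′ comparison, ~1000
trials for the chance-level anchor, and 30 trials per category across a
5-point noise grid for the monotonicity check. Encoder invariants are
asserted over the full 21-item catalog under every distinct published
configuration.

## Limitations

* The encoder is offline and deterministic; real-time streaming, wireless
  transport and hardware control are out of scope.
* The human calibration loop that produces an interface configuration
  (verbal reports, dermatome mapping) is modelled only as a supplied
  configuration file.
* Trial-level mixed-effects modelling (logistic GLMM) is not implemented:
  the study's trial-level data are unavailable, and the fit itself is
  standard off-the-shelf methodology.
* The observer's noise model is not fitted to human data; simulated
  accuracies are not predictions of human performance.
* WAV support covers PCM 16/24-bit and float-32 mono/stereo files, which
  is sufficient for the package's fixtures and typical laboratory stimuli.
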