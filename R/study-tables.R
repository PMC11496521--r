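#' Published session settings of the spinal-interface feasibility study
#'
#' The interface settings used in the different experiment sessions of the
#' 13-participant clinical feasibility study this package models: one row per
#' (participant, session-set) combination with the number of perceptual
#' channels, the total number of intensity levels across channels, the
#' reported bits per frame, the frame (update) rate, and the reported bitrate.
#' The `bits_per_frame` and `bitrate_bps` columns are as published and can be
#' reproduced exactly from the first three quantities via
#' [config_from_summary()] and [capacity_report()].
#'
#' @return A 23-row tibble with columns `participant`, `session`,
#'   `n_channels`, `total_levels`, `bits_per_frame`, `frame_rate`,
#'   `bitrate_bps`.
#' @seealso [experiment1_results()], [experiment2_results()]
#' @export
#' @examples
#' s <- session_settings()
#' all(purrr::pmap_int(
#'   s[, c("n_channels", "total_levels", "frame_rate")],
#'   function(n_channels, total_levels, frame_rate)
#'     bitrate(config_from_summary(n_channels, total_levels, frame_rate))
#' ) == s$bitrate_bps)
session_settings <- function() {
  tibble::tribble(
    ~participant, ~session,  ~n_channels, ~total_levels, ~bits_per_frame, ~frame_rate, ~bitrate_bps,
    "p1",  "1, 2",    2L,  6L, 3.2, 20L,  63L,
    "p1",  "2",       2L, 10L, 4.6, 20L,  92L,
    "p2",  "1, 2, 4", 2L,  6L, 3.2, 20L,  63L,
    "p2",  "3",       2L,  7L, 3.6, 20L,  71L,
    "p3",  "1",       2L,  6L, 3.2, 15L,  47L,
    "p4",  "1",       2L, 12L, 5.2, 20L, 103L,
    "p5",  "1, 2",    3L,  9L, 4.8, 20L,  95L,
    "p6",  "1, 2, 3", 3L,  9L, 4.8, 20L,  95L,
    "p7",  "1",       2L,  6L, 3.2, 20L,  63L,
    "p8",  "1, 2",    4L, 12L, 6.3, 20L, 126L,
    "p9",  "1, 2",    1L,  3L, 1.6, 10L,  15L,
    "p9",  "1, 2",    2L,  6L, 3.2, 20L,  63L,
    "p10", "1",       2L,  6L, 3.2, 20L,  63L,
    "p10", "2",       2L,  6L, 3.2, 10L,  31L,
    "p11", "1",       1L,  3L, 1.6, 10L,  15L,
    "p11", "2",       2L,  6L, 3.2, 20L,  63L,
    "p12", "1",       1L,  3L, 1.6,  5L,   7L,
    "p12", "1, 2",    2L,  6L, 3.2, 20L,  63L,
    "p12", "2",       1L,  3L, 1.6, 10L,  15L,
    "p13", "1, 2",    1L,  3L, 1.6, 10L,  15L,
    "p13", "1, 2",    2L,  6L, 3.2, 10L,  31L,
    "p13", "1, 2",    1L,  3L, 1.6, 20L,  31L,
    "p13", "1, 2",    2L,  6L, 3.2, 20L,  63L
  )
}

#' Published identification-experiment results
#'
#' Per-participant summary of the sound-identification experiment (3
#' alternatives per block, chance 1/3): training time, sound categories
#' tested, number of test trials, and the reported percentage of correct
#' responses (1 decimal). The underlying correct-trial counts are integers;
#' [counts_from_percent()] recovers them exactly from (`percent_correct`,
#' `n_trials`).
#'
#' @return An 8-row tibble with columns `participant`, `training_min`,
#'   `categories`, `n_trials`, `percent_correct`.
#' @export
experiment1_results <- function() {
  tibble::tribble(
    ~participant, ~training_min, ~categories, ~n_trials, ~percent_correct,
    "p1", 2.3, "alternating, numbers, voices",                      70L, 42.9,
    "p2", 2.3, "alternating, noisy, numbers, piano, voices",        79L, 69.6,
    "p3", 3.5, "alternating, double tap, elise",                    35L, 71.4,
    "p4", 1.8, "noisy, voices",                                     20L, 75.0,
    "p5", 5.0, "alternating, double tap, elise, voices",            46L, 69.6,
    "p6", 5.6, "double tap, numbers, piano, voices",                66L, 87.9,
    "p7", 6.3, "alternating, double tap, piano",                    30L, 73.3,
    "p8", 5.2, "alternating, double tap, numbers, piano, voices",   70L, 92.9
  )
}

#' Published discrimination-experiment results
#'
#' Per-participant, per-bitrate-condition summary of the same/different
#' discrimination experiment: number of stimulus pairs, reported percentage
#' correct, and the reported d' sensitivity index. The reduced-bitrate
#' condition carried at most half the baseline bitrate.
#'
#' @return A 10-row tibble with columns `participant`, `condition`
#'   (`"baseline"`/`"reduced"`), `n_pairs`, `percent_correct`, `dprime`.
#' @export
experiment2_results <- function() {
  tibble::tribble(
    ~participant, ~condition, ~n_pairs, ~percent_correct, ~dprime,
    "p9",  "baseline", 48L, 87.5,  2.20,
    "p9",  "reduced",  48L, 72.9,  1.18,
    "p10", "baseline", 24L, 79.2,  1.48,
    "p10", "reduced",  21L, 66.7,  0.79,
    "p11", "baseline", 24L, 91.7,  2.64,
    "p11", "reduced",  24L, 75.0,  1.27,
    "p12", "baseline", 48L, 89.6,  2.47,
    "p12", "reduced",  48L, 41.7, -0.41,
    "p13", "baseline", 48L, 93.8,  2.84,
    "p13", "reduced",  48L, 85.4,  2.05
  )
}
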