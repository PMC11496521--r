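#' Perceptual noise model for the ideal observer
#'
#' Noise acts in level space, after quantization: each frame/channel level is
#' independently displaced by a rounded Gaussian step of standard deviation
#' `sigma` and clipped to the channel's alphabet. This models confusion
#' between adjacent calibrated intensity steps -- the quantity the
#' calibration procedure equates across participants. `lapse` is the
#' probability of an entirely random response regardless of the percept.
#'
#' @param sigma Standard deviation of the level perturbation, >= 0.
#' @param lapse Probability of a uniformly random response, in \[0, 1\].
#'
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(sigma = 0, lapse = 0) {
  if (sigma < 0) abort_invalid("`sigma` must be >= 0")
  if (lapse < 0 || lapse > 1) abort_invalid("`lapse` must be in [0, 1]")
  structure(list(sigma = sigma, lapse = lapse), class = "noise_model")
}

#' Perturb level frames with discretized Gaussian noise
#'
#' Each entry moves to level `v` with probability proportional to the
#' Gaussian mass of the rounding cell `[v - l - 0.5, v - l + 0.5]` around the
#' true level `l`, truncated and renormalised over the channel's alphabet
#' `0..n_levels - 1` (so levels never leave the alphabet, and as
#' `sigma -> Inf` the perturbed entries approach a uniform distribution over
#' the alphabet rather than piling up on the boundary levels).
#'
#' @param frames A `level_frames` object.
#' @param noise A [noise_model()].
#' @param n_levels Integer vector of per-channel alphabet sizes (one per
#'   column of `frames$levels`).
#'
#' @return A `level_frames` object of the same shape; `sigma = 0` returns
#'   the input unchanged. Uses the current RNG state.
#' @export
perturb <- function(frames, noise, n_levels) {
  stopifnot(inherits(frames, "level_frames"), inherits(noise, "noise_model"))
  if (noise$sigma == 0) return(frames)
  lv <- frames$levels
  for (ch in seq_len(ncol(lv))) {
    L <- n_levels[ch]
    if (L < 2) next
    # transition kernel: rows = current level, cols = perturbed level
    kernel <- t(vapply(0:(L - 1), function(l) {
      p <- stats::pnorm(0:(L - 1) - l + 0.5, sd = noise$sigma) -
        stats::pnorm(0:(L - 1) - l - 0.5, sd = noise$sigma)
      p / sum(p)
    }, numeric(L)))
    col <- lv[, ch]
    u <- stats::runif(length(col))
    cum <- kernel[col + 1L, , drop = FALSE]
    cum <- t(apply(cum, 1, cumsum))
    lv[, ch] <- pmin(L - 1L, as.integer(rowSums(u > cum)))  # inverse-CDF draw
  }
  structure(list(levels = lv, frame_rate = frames$frame_rate), class = "level_frames")
}

# mean absolute level distance after padding the shorter sequence with level 0
level_distance <- function(a, b) {
  na <- nrow(a$levels); nb <- nrow(b$levels)
  n <- max(na, nb)
  pad <- function(m, n) {
    if (nrow(m) < n) rbind(m, matrix(0L, n - nrow(m), ncol(m))) else m
  }
  mean(abs(pad(a$levels, n) - pad(b$levels, n)))
}

#' Identify the closest of three templates (3AFC observer)
#'
#' Template-matching decision rule for the three-alternative identification
#' task: returns the index of the template with the smallest mean absolute
#' level-index distance to the observed frames (sequences padded with level
#' 0 to a common length). Ties break toward the lowest index.
#'
#' @param observed A `level_frames` object (typically a perturbed template).
#' @param templates A list of `level_frames` templates.
#'
#' @return The chosen template index.
#' @export
identify_3afc <- function(observed, templates) {
  if (length(templates) == 0) abort_invalid("`templates` must be non-empty")
  d <- vapply(templates, function(tmp) level_distance(observed, tmp), numeric(1))
  which.min(d)  # which.min breaks ties toward the lowest index
}

#' Same/different decision on two level-frame sequences
#'
#' Responds `"different"` iff the mean absolute level distance (after
#' padding to a common length) exceeds `criterion`.
#'
#' @param a,b `level_frames` objects.
#' @param criterion Non-negative decision threshold on the mean level
#'   distance.
#'
#' @return `"same"` or `"different"`.
#' @export
same_different <- function(a, b, criterion) {
  if (criterion < 0) abort_invalid("`criterion` must be >= 0")
  if (level_distance(a, b) > criterion) "different" else "same"
}

#' Simulate the sound-identification experiment
#'
#' For each category in the catalog, the three items are encoded into
#' level-frame templates under `config`. Each trial presents one template
#' through the noisy channel ([perturb()]); the observer responds with
#' [identify_3afc()], or uniformly at random with probability `lapse`.
#'
#' @param catalog A [fixture_catalog()] tibble (or subset of its
#'   categories).
#' @param config An [interface_config()].
#' @param noise A [noise_model()].
#' @param n_trials_per_category Trials per category block (>= 10 in the
#'   study design).
#' @param seed Integer seed; runs are exactly reproducible.
#'
#' @return A list of class `sim_identification` with elements `result`
#'   (tibble: participant = "sim", n_trials, n_correct, percent_correct,
#'   by-category breakdown) and `log` (trial-level tibble: block, category,
#'   stimulus, response, correct), plus attributes recording seed and noise.
#' @export
#' @examples
#' run_experiment1(fixture_catalog(1), make_config(c(3, 3), 20),
#'                 noise_model(0.5), n_trials_per_category = 10, seed = 1)
run_experiment1 <- function(catalog, config, noise,
                            n_trials_per_category = 10, seed = 1) {
  if (nrow(catalog) == 0) abort_invalid("`catalog` must be non-empty")
  categories <- unique(catalog$category)
  n_lv <- config$channels$n_levels
  templates <- purrr::map(seq_len(nrow(catalog)), function(i) {
    encode(catalog$clip[[i]], config)$level_frames
  })
  names(templates) <- catalog$item_id
  log <- with_seed(seed, {
    rows <- purrr::map(categories, function(cat) {
      idx <- which(catalog$category == cat)
      tmpl <- templates[idx]
      stim <- sample.int(length(tmpl), n_trials_per_category, replace = TRUE)
      purrr::map(seq_len(n_trials_per_category), function(tr) {
        s <- stim[tr]
        resp <- if (stats::runif(1) < noise$lapse) {
          sample.int(length(tmpl), 1)
        } else {
          identify_3afc(perturb(tmpl[[s]], noise, n_lv), tmpl)
        }
        tibble::tibble(
          block = cat, category = cat,
          stimulus = names(tmpl)[s], response = names(tmpl)[resp],
          correct = resp == s
        )
      })
    })
    dplyr::bind_rows(purrr::flatten(rows))
  })
  by_cat <- dplyr::summarise(dplyr::group_by(log, .data$category),
                             n_trials = dplyr::n(), n_correct = sum(.data$correct),
                             .groups = "drop")
  result <- tibble::tibble(
    participant = "sim",
    n_trials = nrow(log),
    n_correct = sum(log$correct),
    percent_correct = percent_correct(sum(log$correct), nrow(log)),
    by_category = list(by_cat)
  )
  structure(list(result = result, log = log),
            class = "sim_identification", seed = seed, noise = noise)
}

#' Simulate the same/different discrimination experiment
#'
#' Presents 50-50 same/different pairs built from the double-tap fixture
#' items under a baseline and a reduced-bitrate configuration (condition
#' order counterbalanced across pair indices). Both presentations of a pair
#' pass independently through the noisy channel; the observer applies
#' [same_different()]. The default criterion mimics an observer who knows
#' the noise statistics: per condition it is the midpoint between the mean
#' distance of noise-perturbed same pairs and of noise-perturbed different
#' pairs, estimated from a short seeded calibration run (deterministic
#' given `seed`). Per condition the confusion counts
#' (hits/misses/false alarms/correct rejections, "different" = signal) and
#' d' are returned.
#'
#' @param config_baseline,config_reduced Interface configurations; the
#'   reduced bitrate must be at most half the baseline bitrate.
#' @param noise A [noise_model()].
#' @param n_pairs Even number of pairs per condition.
#' @param seed Integer seed.
#' @param catalog Optionally a [fixture_catalog()]; its `double_tap` items
#'   are used.
#' @param criterion Optional fixed decision criterion (otherwise derived per
#'   condition as above).
#'
#' @return A list of class `sim_discrimination` with element `result`: a
#'   two-row tibble (condition, n_pairs, hits, misses, false_alarms,
#'   correct_rejections, percent_correct, dprime) plus a `log` tibble.
#' @export
run_experiment2 <- function(config_baseline, config_reduced, noise,
                            n_pairs = 48, seed = 1, catalog = NULL,
                            criterion = NULL) {
  if (bitrate(config_reduced) > bitrate(config_baseline) / 2) {
    abort_invalid("reduced bitrate must be at most half the baseline bitrate")
  }
  if (n_pairs %% 2 != 0) abort_invalid("`n_pairs` must be even (50-50 same/different)")
  if (is.null(catalog)) catalog <- fixture_catalog(seed)
  items <- dplyr::filter(catalog, .data$category == "double_tap")
  if (nrow(items) < 2) abort_invalid("need at least two double-tap items")
  conds <- list(baseline = config_baseline, reduced = config_reduced)
  out <- purrr::imap(conds, function(cfg, cond) {
    n_lv <- cfg$channels$n_levels
    tmpl <- purrr::map(items$clip, function(cl) encode(cl, cfg)$level_frames)
    # condition-specific but seed-reproducible stream
    cond_seed <- (seed + match(cond, names(conds)) * 7919L) %% .Machine$integer.max
    crit <- criterion
    if (is.null(crit)) {
      # observer criterion from the known noise statistics: midpoint between
      # the expected same-pair and different-pair distances under the noise
      crit <- with_seed(cond_seed + 1L, {
        pairs <- utils::combn(length(tmpl), 2)
        d_diff <- replicate(8, mean(apply(pairs, 2, function(ij) {
          level_distance(perturb(tmpl[[ij[1]]], noise, n_lv),
                         perturb(tmpl[[ij[2]]], noise, n_lv))
        })))
        d_same <- replicate(8, mean(vapply(seq_along(tmpl), function(i) {
          level_distance(perturb(tmpl[[i]], noise, n_lv),
                         perturb(tmpl[[i]], noise, n_lv))
        }, numeric(1))))
        (mean(d_same) + mean(d_diff)) / 2
      })
    }
    log <- with_seed(cond_seed, {
      # balanced design: every stimulus and stimulus pair used equally often
      # (up to remainder), trial order shuffled
      same_pool <- rep_len(seq_along(tmpl), n_pairs / 2)
      diff_combos <- utils::combn(length(tmpl), 2)
      diff_pool <- rep_len(seq_len(ncol(diff_combos)), n_pairs / 2)
      pair_a <- c(same_pool, diff_combos[1, diff_pool])
      pair_b <- c(same_pool, diff_combos[2, diff_pool])
      ord <- sample.int(n_pairs)
      pair_a <- pair_a[ord]; pair_b <- pair_b[ord]
      is_same <- pair_a == pair_b
      purrr::map(seq_len(n_pairs), function(i) {
        a <- pair_a[i]
        b <- pair_b[i]
        resp <- same_different(perturb(tmpl[[a]], noise, n_lv),
                               perturb(tmpl[[b]], noise, n_lv), crit)
        tibble::tibble(
          condition = cond, pair = i, stimulus_a = items$item_id[a],
          stimulus_b = items$item_id[b], truth = if (is_same[i]) "same" else "different",
          response = resp, correct = resp == (if (is_same[i]) "same" else "different")
        )
      })
    })
    dplyr::bind_rows(log)
  })
  log <- dplyr::bind_rows(out)
  result <- dplyr::summarise(
    dplyr::group_by(log, .data$condition),
    n_pairs = dplyr::n(),
    hits = sum(.data$truth == "different" & .data$response == "different"),
    misses = sum(.data$truth == "different" & .data$response == "same"),
    false_alarms = sum(.data$truth == "same" & .data$response == "different"),
    correct_rejections = sum(.data$truth == "same" & .data$response == "same"),
    .groups = "drop"
  )
  result$percent_correct <- percent_correct(
    result$hits + result$correct_rejections, result$n_pairs
  )
  result$dprime <- purrr::pmap_dbl(
    result[, c("hits", "misses", "false_alarms", "correct_rejections")], dprime
  )
  # baseline first, as in the summary tables
  result <- result[order(match(result$condition, c("baseline", "reduced"))), ]
  structure(list(result = result, log = log),
            class = "sim_discrimination", seed = seed, noise = noise)
}

#' Derive a reduced-bitrate configuration
#'
#' The discrimination experiment compared each participant's baseline
#' configuration against a reduced one carrying at most half the bitrate.
#' Two reduction modes were used in the study sessions: halving the frame
#' rate (e.g. 63 -> 31 bps), or collapsing to a single 3-level channel at
#' 10 fps (e.g. 63 -> 15 bps).
#'
#' @param config An [interface_config()].
#' @param mode `"halve_rate"` or `"collapse"`.
#'
#' @return A new [interface_config()] whose bitrate is at most half of the
#'   input's. Errors when the configuration is already minimal for the
#'   requested mode (odd frame rate for `halve_rate`; bitrate below 30 bps
#'   for `collapse`).
#' @export
#' @examples
#' bitrate(reduce_bitrate(make_config(c(3, 3), 20), "halve_rate"))  # 31
#' bitrate(reduce_bitrate(make_config(c(3, 3), 20), "collapse"))    # 15
reduce_bitrate <- function(config, mode = c("halve_rate", "collapse")) {
  mode <- match.arg(mode)
  if (mode == "halve_rate") {
    if (config$frame_rate %% 2 != 0 || config$frame_rate < 2) {
      abort_invalid("frame rate cannot be halved; configuration already minimal")
    }
    out <- interface_config(config$channels, config$frame_rate %/% 2)
  } else {
    if (bitrate(config) < 30) {
      abort_invalid("bitrate below 30 bps cannot be collapsed to the 15 bps floor")
    }
    ch1 <- config$channels[1, ]
    ch1$n_levels <- 3L
    out <- interface_config(ch1, 10)
  }
  stopifnot(bitrate(out) <= bitrate(config) / 2)
  out
}
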