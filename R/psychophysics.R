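#' Percentage of correct trials
#'
#' @param n_correct,n_trials Integer counts, `0 <= n_correct <= n_trials`,
#'   `n_trials > 0`.
#'
#' @return Percentage correct, rounded half-up to 1 decimal.
#' @export
#' @examples
#' percent_correct(30, 70)  # 42.9
percent_correct <- function(n_correct, n_trials) {
  if (any(n_trials <= 0)) abort_invalid("`n_trials` must be positive")
  if (any(n_correct < 0 | n_correct > n_trials)) {
    abort_invalid("`n_correct` must lie in [0, n_trials]")
  }
  round_half_up(100 * n_correct / n_trials, 1)
}

#' Recover integer correct-trial counts from a printed percentage
#'
#' Published summaries report percent correct to 1 decimal; since the
#' underlying counts are integers, `round(pct/100 * n)` recovers them
#' exactly. Group statistics computed from these exact fractions avoid the
#' accumulation of 1-decimal rounding error.
#'
#' @param percent Reported percentage (vectorised).
#' @param n_trials Number of trials (vectorised).
#'
#' @return Integer vector of correct-trial counts.
#' @export
#' @examples
#' counts_from_percent(42.9, 70)  # 30
counts_from_percent <- function(percent, n_trials) {
  as.integer(round_half_up(percent / 100 * n_trials))
}

#' One-sided exact binomial test against chance
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, chance)`: the
#' p-value for the null hypothesis that per-trial accuracy does not exceed
#' chance (1/3 for three-alternative identification).
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param chance Null success probability, in (0, 1).
#'
#' @return The exact one-sided p-value.
#' @export
#' @examples
#' binomial_test_vs_chance(30, 70)  # 0.061
binomial_test_vs_chance <- function(k, n, chance = 1 / 3) {
  if (k < 0 || k > n) abort_invalid("`k` must lie in [0, n]")
  if (chance <= 0 || chance >= 1) abort_invalid("`chance` must be in (0, 1)")
  stats::pbinom(k - 1, n, chance, lower.tail = FALSE)
}

#' One-sided exact Wilcoxon signed-rank test
#'
#' Tests whether `values` exceed `mu` (alternative: greater) with the exact
#' permutation null: exact zero differences are dropped, absolute differences
#' are ranked with average ranks for ties, and the null distribution of the
#' positive-rank sum is built by exact enumeration over all 2^n sign
#' assignments (implemented as a rank-sum generating function, which equals
#' brute-force enumeration). No normal approximation is used, so small-sample
#' p-values such as 1/2^8 = 0.0039 for eight uniformly positive differences
#' are exact.
#'
#' @param values Numeric vector of observations.
#' @param mu Null location.
#'
#' @return The exact one-sided p-value `P(W >= w_obs)`.
#' @export
#' @examples
#' wilcoxon_signed_rank_one_sided(experiment1_results()$percent_correct, 100 / 3)
wilcoxon_signed_rank_one_sided <- function(values, mu = 0) {
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort_invalid("all values equal `mu`; test undefined")
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  # integerise (average ranks give .5 steps)
  r2 <- as.integer(round(2 * r))
  w2 <- round(2 * w_obs)
  # generating function over subset rank sums: counts[s+1] = #subsets with sum s
  counts <- rep(0, sum(r2) + 1)
  counts[1] <- 1
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(length(counts) - ri)])
    counts <- counts + shifted
  }
  sum(counts[seq(w2 + 1, length(counts))]) / 2^n
}

#' d-prime sensitivity for same/different discrimination
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)`, with "different" as the
#' signal class. Extreme observed rates of exactly 0 or 1 are replaced by
#' `1/(2N)` and `1 - 1/(2N)` respectively (N = number of trials of that
#' class) so the inverse normal stays finite. Negative values occur when
#' false alarms outnumber hits (response confusion).
#'
#' @param hits,misses Counts on "different" pairs (signal).
#' @param false_alarms,correct_rejections Counts on "same" pairs (noise).
#'
#' @return The d' value.
#' @export
#' @examples
#' dprime(42, 6, 6, 42)  # 2.30
dprime <- function(hits, misses, false_alarms, correct_rejections) {
  n_diff <- hits + misses
  n_same <- false_alarms + correct_rejections
  if (n_diff <= 0 || n_same <= 0) abort_invalid("need trials of both pair types")
  clamp <- function(rate, n) {
    if (rate <= 0) 1 / (2 * n) else if (rate >= 1) 1 - 1 / (2 * n) else rate
  }
  hr <- clamp(hits / n_diff, n_diff)
  fa <- clamp(false_alarms / n_same, n_same)
  stats::qnorm(hr) - stats::qnorm(fa)
}

#' One-tailed paired Student's t-test
#'
#' Tests whether `y` is lower than `x` on paired data: t is computed on the
#' differences `y - x` with `df = n - 1`, and the one-tailed p-value is the
#' lower-tail probability. Used for the drop in d' from the baseline to the
#' reduced bitrate condition.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#'
#' @return A tibble with columns `t`, `df`, `p`.
#' @export
#' @examples
#' e2 <- experiment2_results()
#' paired_t_one_tailed(
#'   e2$dprime[e2$condition == "baseline"],
#'   e2$dprime[e2$condition == "reduced"]
#' )  # t(4) = -3.4, p = 0.014
paired_t_one_tailed <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort_invalid("`x` and `y` must be paired vectors of length >= 2")
  }
  d <- y - x
  if (stats::sd(d) == 0) abort_invalid("zero difference variance; t undefined")
  n <- length(d)
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  tibble::tibble(t = t_stat, df = n - 1, p = stats::pt(t_stat, n - 1))
}

#' Group mean with sample SD and t-based 95% confidence interval
#'
#' @param values Numeric vector, length >= 2.
#' @param conf_level Confidence level for the interval.
#'
#' @return An object of class `group_summary`: a one-row tibble with `mean`,
#'   `sd`, `ci_low`, `ci_high`, `n`.
#' @export
#' @examples
#' e1 <- experiment1_results()
#' acc <- 100 * counts_from_percent(e1$percent_correct, e1$n_trials) / e1$n_trials
#' group_summary(acc)  # mean 72.8, CI [60, 85]
group_summary <- function(values, conf_level = 0.95) {
  n <- length(values)
  if (n < 2) abort_invalid("need n >= 2 for a confidence interval")
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(1 - (1 - conf_level) / 2, n - 1) * s / sqrt(n)
  out <- tibble::tibble(mean = m, sd = s, ci_low = m - half, ci_high = m + half, n = n)
  class(out) <- c("group_summary", class(out))
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#'
#' @return The correlation coefficient rho.
#' @export
#' @examples
#' spearman_rho(1:4, c(1, 3, 2, 4))  # 0.8
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort_invalid("`x` and `y` must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_invalid("constant input; rank correlation undefined")
  }
  stats::cor(x, y, method = "spearman")
}

#' Significance marker at conventional thresholds
#'
#' `***` for p < 0.001, `**` < 0.01, `*` < 0.05, `.` < 0.1, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of markers.
#' @export
significance_marker <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*", p < 0.1 ~ ".",
    .default = ""
  )
}

#' Analyse an identification-experiment summary table
#'
#' Takes a per-participant summary (columns `participant`, `n_trials`,
#' `percent_correct`, as in [experiment1_results()]), recovers exact
#' correct-trial fractions, and computes the per-participant exact binomial
#' p-value against chance plus its significance marker.
#'
#' @param tbl A data frame with columns `participant`, `n_trials`,
#'   `percent_correct` (or `n_correct` directly).
#' @param chance Chance success probability.
#'
#' @return A tibble of class `identification_analysis`: the input plus
#'   `n_correct`, `accuracy` (exact, percent), `p_binomial`, `marker`.
#' @seealso [identification_group_stats()] for the group-level statistics.
#' @export
#' @examples
#' analyze_identification(experiment1_results())
analyze_identification <- function(tbl, chance = 1 / 3) {
  tbl <- tibble::as_tibble(tbl)
  if (!"n_correct" %in% names(tbl)) {
    tbl$n_correct <- counts_from_percent(tbl$percent_correct, tbl$n_trials)
  }
  out <- dplyr::mutate(
    tbl,
    accuracy = 100 * .data$n_correct / .data$n_trials,
    p_binomial = purrr::map2_dbl(.data$n_correct, .data$n_trials,
                                 binomial_test_vs_chance, chance = chance),
    marker = significance_marker(.data$p_binomial)
  )
  class(out) <- c("identification_analysis", class(out))
  out
}

#' Group-level statistics for the identification experiment
#'
#' Mean accuracy over participants (computed from exact fractions), the
#' t-based 95% confidence interval, and the one-sided exact Wilcoxon
#' signed-rank p-value against chance.
#'
#' @param tbl As in [analyze_identification()].
#' @param chance Chance success probability.
#'
#' @return A one-row tibble: `mean`, `sd`, `ci_low`, `ci_high`, `n`,
#'   `p_wilcoxon`.
#' @export
#' @examples
#' identification_group_stats(experiment1_results())
#' # mean 72.8 [60, 85], p 0.004
identification_group_stats <- function(tbl, chance = 1 / 3) {
  a <- analyze_identification(tbl, chance = chance)
  gs <- group_summary(a$accuracy)
  gs$p_wilcoxon <- wilcoxon_signed_rank_one_sided(a$accuracy, 100 * chance)
  gs
}

#' Analyse a discrimination-experiment summary table
#'
#' Takes a per-participant, per-condition summary (columns `participant`,
#' `condition`, `n_pairs`, `percent_correct`, optionally `dprime`, as in
#' [experiment2_results()]) and computes condition means from exact
#' fractions, mean d' per condition, and the one-tailed paired t-test on the
#' per-participant d' drop from baseline to reduced.
#'
#' @param tbl A data frame as above; `condition` must contain `"baseline"`
#'   and `"reduced"`.
#'
#' @return A list of class `discrimination_analysis` with elements
#'   `by_condition` (tibble: condition, mean accuracy, sd, mean d', sd d',
#'   n) and `t_test` (tibble: t, df, p), printed together.
#' @export
#' @examples
#' analyze_discrimination(experiment2_results())
analyze_discrimination <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  tbl$n_correct <- counts_from_percent(tbl$percent_correct, tbl$n_pairs)
  tbl$accuracy <- 100 * tbl$n_correct / tbl$n_pairs
  by_cond <- dplyr::summarise(
    dplyr::group_by(tbl, .data$condition),
    mean_accuracy = mean(.data$accuracy),
    sd_accuracy = stats::sd(.data$accuracy),
    mean_dprime = if ("dprime" %in% names(tbl)) mean(.data$dprime) else NA_real_,
    sd_dprime = if ("dprime" %in% names(tbl)) stats::sd(.data$dprime) else NA_real_,
    n = dplyr::n(),
    .groups = "drop"
  )
  t_test <- NULL
  if ("dprime" %in% names(tbl)) {
    wide <- tidyr::pivot_wider(tbl[, c("participant", "condition", "dprime")],
                               names_from = "condition", values_from = "dprime")
    if (all(c("baseline", "reduced") %in% names(wide))) {
      t_test <- paired_t_one_tailed(wide$baseline, wide$reduced)
    }
  }
  structure(list(by_condition = by_cond, t_test = t_test),
            class = "discrimination_analysis")
}

#' @export
print.discrimination_analysis <- function(x, ...) {
  cat("Discrimination performance by bitrate condition:\n")
  print(x$by_condition)
  if (!is.null(x$t_test)) {
    cat(sprintf("\nPaired one-tailed t on d' (reduced - baseline): t(%d) = %.1f, p = %.3f\n",
                x$t_test$df, x$t_test$t, x$t_test$p))
  }
  invisible(x)
}

#' Read and write trial logs
#'
#' Trial logs are JSON Lines: one trial per line with fields `participant`,
#' `block`, `category`, `stimulus`, `response`, `correct` (logical) and
#' optional `condition`.
#'
#' @param path Path to a `.jsonl` file.
#' @param log A data frame of trials.
#'
#' @return `read_trial_log()` returns a tibble; `write_trial_log()` returns
#'   `path` invisibly.
#' @export
read_trial_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  dplyr::bind_rows(purrr::map(lines, function(l) {
    tibble::as_tibble(jsonlite::fromJSON(l))
  }))
}

#' @rdname read_trial_log
#' @export
write_trial_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Summarise a trial log into identification counts
#'
#' @param log A trial-log tibble with `participant`, `category`, `correct`.
#'
#' @return A tibble with one row per participant (`n_trials`, `n_correct`,
#'   `percent_correct`) carrying a `by_category` list-column.
#' @export
summarize_trial_log <- function(log) {
  by_cat <- dplyr::summarise(
    dplyr::group_by(log, .data$participant, .data$category),
    n_trials = dplyr::n(), n_correct = sum(.data$correct), .groups = "drop"
  )
  out <- dplyr::summarise(
    dplyr::group_by(log, .data$participant),
    n_trials = dplyr::n(), n_correct = sum(.data$correct), .groups = "drop"
  )
  out$percent_correct <- percent_correct(out$n_correct, out$n_trials)
  out$by_category <- purrr::map(out$participant, function(p) {
    dplyr::filter(by_cat, .data$participant == p)
  })
  out
}
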