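test_that("percent correct rounds half-up to one decimal", {
  expect_equal(percent_correct(30, 70), 42.9)
  expect_equal(percent_correct(65, 70), 92.9)
  expect_equal(percent_correct(0, 10), 0)
  expect_equal(percent_correct(1, 16), 6.3)  # 6.25 rounds up, not to even
  expect_error(percent_correct(1, 0), class = "spinesound_invalid")
  expect_error(percent_correct(5, 3), class = "spinesound_invalid")
})

test_that("counts are recovered exactly from printed percentages", {
  e1 <- experiment1_results()
  counts <- counts_from_percent(e1$percent_correct, e1$n_trials)
  expect_equal(counts, c(30L, 55L, 25L, 15L, 32L, 58L, 22L, 65L))
  # re-rounding the exact fractions reproduces the printed values
  expect_equal(percent_correct(counts, e1$n_trials), e1$percent_correct)
})

test_that("the exact binomial upper tail matches closed forms", {
  expect_equal(round(binomial_test_vs_chance(30, 70, 1 / 3), 3), 0.061)
  expect_equal(binomial_test_vs_chance(3, 3, 1 / 3), (1 / 3)^3)
  expect_lt(binomial_test_vs_chance(65, 70, 1 / 3), 0.001)
  expect_equal(binomial_test_vs_chance(0, 10, 1 / 3), 1)
  # agreement with stats::binom.test
  expect_equal(binomial_test_vs_chance(30, 70, 1 / 3),
               stats::binom.test(30, 70, 1 / 3, alternative = "greater")$p.value)
})

test_that("binomial p at the mean count stays large", {
  for (n in c(10, 30, 60, 90)) {
    k <- ceiling(n / 3)
    expect_gte(binomial_test_vs_chance(k, n, 1 / 3), 0.4)
  }
})

test_that("exact Wilcoxon enumeration matches hand-checkable cases", {
  # eight uniformly positive differences: 1 of 256 sign patterns as extreme
  e1 <- experiment1_results()
  acc <- 100 * counts_from_percent(e1$percent_correct, e1$n_trials) / e1$n_trials
  expect_equal(wilcoxon_signed_rank_one_sided(acc, 100 / 3), 1 / 256)
  expect_equal(round(wilcoxon_signed_rank_one_sided(acc, 100 / 3), 3), 0.004)

  expect_equal(wilcoxon_signed_rank_one_sided(5, 0), 0.5)
  expect_equal(wilcoxon_signed_rank_one_sided(c(1, -1), 0), 0.75)
  expect_error(wilcoxon_signed_rank_one_sided(c(3, 3), 3),
               class = "spinesound_invalid")
})

test_that("exact Wilcoxon equals the 2^n brute-force oracle for n <= 12", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(1:12, 1)
    x <- round(stats::rnorm(n, 0.3), sample(0:1, 1))  # ties likely at 0 decimals
    x <- x[x != 0]
    if (length(x) == 0) next
    expect_equal(wilcoxon_signed_rank_one_sided(x, 0),
                 wilcoxon_brute_force(x, 0),
                 info = paste(x, collapse = ","))
  }
  # tie-free cases also agree with the reference implementation in stats
  for (rep in 1:10) {
    x <- stats::rnorm(sample(3:10, 1))
    expect_equal(wilcoxon_signed_rank_one_sided(x, 0),
                 stats::wilcox.test(x, alternative = "greater", exact = TRUE)$p.value)
  }
})

test_that("dprime handles interior, extreme, and inverted rates", {
  expect_equal(dprime(12, 12, 12, 12), 0)  # hit = fa = 0.5
  expect_equal(dprime(42, 6, 6, 42), 2 * stats::qnorm(0.875))  # 2.30
  expect_lt(dprime(10, 14, 20, 4), 0)  # fa > hit -> negative

  # extreme-rate correction: perfect separation with N = 24 per class
  ceiling24 <- stats::qnorm(1 - 1 / 48) - stats::qnorm(1 / 48)
  expect_equal(dprime(24, 0, 0, 24), ceiling24)

  # antisymmetry under swapping hits and false alarms
  for (h in c(20, 15, 8)) {
    expect_equal(dprime(h, 24 - h, 5, 19), -dprime(5, 19, h, 24 - h))
  }
})

test_that("the paired one-tailed t-test reproduces textbook behaviour", {
  x <- c(1, 2, 3, 4)
  res <- paired_t_one_tailed(x, x - c(1, 2, 1, 2))
  ref <- stats::t.test(x - c(1, 2, 1, 2), x, paired = TRUE, alternative = "less")
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)

  same <- paired_t_one_tailed(c(1, 2, 3), c(2, 1, 3))
  expect_equal(same$p, stats::pt(same$t, 2))

  expect_error(paired_t_one_tailed(c(1, 2, 3), c(0, 1, 2)),
               class = "spinesound_invalid")  # constant differences
  expect_error(paired_t_one_tailed(1, 2), class = "spinesound_invalid")
})

test_that("group_summary gives a t-interval that contains the mean and shrinks with n", {
  g <- group_summary(c(5, 5, 5))
  expect_equal(g$sd, 0)
  expect_equal(g$ci_low, g$mean)
  expect_equal(g$ci_high, g$mean)

  set.seed(9)
  x <- stats::rnorm(64, 50, 10)
  g_small <- group_summary(x[1:16])
  g_big <- group_summary(x)
  expect_true(g_small$ci_low <= g_small$mean && g_small$mean <= g_small$ci_high)
  expect_lt(g_big$ci_high - g_big$ci_low, g_small$ci_high - g_small$ci_low)
  expect_error(group_summary(1), class = "spinesound_invalid")
})

test_that("spearman_rho matches the rank-difference formula", {
  expect_equal(spearman_rho(1:5, 2 * (1:5) + 3), 1)
  expect_equal(spearman_rho(1:5, rev(1:5)), -1)
  expect_equal(spearman_rho(1:4, c(1, 3, 2, 4)), 0.8)  # 1 - 6*2/(4*15)
  expect_error(spearman_rho(rep(1, 4), 1:4), class = "spinesound_invalid")
})

test_that("identification analysis flags participants against chance", {
  a <- analyze_identification(experiment1_results())
  expect_equal(a$marker, c(".", rep("***", 7)))
  expect_equal(round(a$p_binomial[1], 3), 0.061)
  expect_true(all(a$p_binomial[-1] < 0.001))

  g <- identification_group_stats(experiment1_results())
  expect_equal(round(g$mean, 1), 72.8)
  expect_equal(round(g$ci_low), 60)
  expect_equal(round(g$ci_high), 85)
  expect_equal(round(g$p_wilcoxon, 3), 0.004)
  expect_equal(round(g$sd), 15)
})

test_that("discrimination analysis recovers condition means and the d-prime drop", {
  d <- analyze_discrimination(experiment2_results())
  bc <- d$by_condition
  expect_equal(round(bc$mean_accuracy[bc$condition == "baseline"], 1), 88.3)
  expect_equal(round(bc$mean_accuracy[bc$condition == "reduced"], 1), 68.3)
  expect_equal(round(bc$mean_dprime[bc$condition == "baseline"], 2), 2.33)
  expect_equal(round(bc$mean_dprime[bc$condition == "reduced"], 2), 0.98)
  expect_equal(round(d$t_test$t, 1), -3.4)
  expect_equal(d$t_test$df, 4)
  expect_equal(round(d$t_test$p, 3), 0.014)
})

test_that("trial logs round-trip through JSONL and summarise correctly", {
  log <- tibble::tibble(
    participant = "p1", block = rep(c("a", "b"), each = 3),
    category = rep(c("piano", "noisy"), each = 3),
    stimulus = paste0("s", 1:6), response = paste0("s", c(1, 2, 2, 4, 5, 5)),
    correct = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  )
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_trial_log(log, path)
  back <- read_trial_log(path)
  expect_equal(back$correct, log$correct)
  expect_equal(back$stimulus, log$stimulus)

  s <- summarize_trial_log(back)
  expect_equal(s$n_trials, 6L)
  expect_equal(s$n_correct, 3L)
  expect_equal(s$percent_correct, 50)
  expect_equal(nrow(s$by_category[[1]]), 2)
})
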