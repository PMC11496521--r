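make_lf <- function(m, fr = 20L) {
  structure(list(levels = m, frame_rate = fr), class = "level_frames")
}

test_that("perturb is identity at sigma 0 and stays inside the alphabet", {
  lf <- make_lf(matrix(c(0L, 1L, 2L, 2L), 2, 2))
  expect_identical(perturb(lf, noise_model(0), c(3, 3)), lf)

  set.seed(1)
  for (i in 1:20) {
    p <- perturb(lf, noise_model(2), c(3, 3))
    expect_true(all(p$levels >= 0 & p$levels <= 2))
  }

  # zero floor: level 0 never goes negative even under huge noise
  zeros <- make_lf(matrix(0L, 10, 1))
  p <- perturb(zeros, noise_model(10), 3)
  expect_true(all(p$levels >= 0))
})

test_that("heavy level noise approaches a uniform alphabet distribution", {
  lf <- make_lf(matrix(1L, 3000, 1))
  set.seed(2)
  p <- perturb(lf, noise_model(50), 3)
  freq <- table(factor(p$levels, levels = 0:2)) / length(p$levels)
  expect_true(all(abs(freq - 1 / 3) < 0.05))
})

test_that("the 3AFC observer picks the nearest template with low-index ties", {
  t1 <- make_lf(matrix(c(0L, 0L, 2L, 2L), 2, 2))
  t2 <- make_lf(matrix(c(2L, 2L, 0L, 0L), 2, 2))
  t3 <- make_lf(matrix(1L, 2, 2))
  expect_equal(identify_3afc(t2, list(t1, t2, t3)), 2)
  expect_equal(identify_3afc(t1, list(t1, t1, t1)), 1)  # tie -> lowest index
  expect_error(identify_3afc(t1, list()), class = "spinesound_invalid")

  # shorter observed sequences are padded with level 0
  short <- make_lf(matrix(c(0L, 2L), 1, 2))
  expect_equal(identify_3afc(short, list(t1, t2, t3)), 1)
})

test_that("same_different thresholds the mean level distance monotonically", {
  a <- make_lf(matrix(0L, 4, 1))
  b <- make_lf(matrix(c(0L, 1L, 0L, 1L), 4, 1))
  expect_equal(same_different(a, a, 0.1), "same")
  expect_equal(same_different(a, b, 0.1), "different")  # distance 0.5
  expect_equal(same_different(a, b, 0.6), "same")
  expect_error(same_different(a, b, -1), class = "spinesound_invalid")

  # rising criterion can only reduce the "different" rate: threshold a common
  # set of noisy presentations at each criterion
  set.seed(3)
  pairs <- replicate(80, list(pa = perturb(a, noise_model(0.7), 3),
                              pb = perturb(b, noise_model(0.7), 3)),
                     simplify = FALSE)
  crits <- c(0, 0.2, 0.4, 0.8)
  rates <- vapply(crits, function(cr) {
    mean(vapply(pairs, function(p) {
      same_different(p$pa, p$pb, cr) == "different"
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rates) <= 0))
  expect_gt(rates[1], 0.9)  # criterion 0 with noise: almost always "different"
})

test_that("identification simulation is perfect without noise and reproducible", {
  cat21 <- test_catalog()
  sim0 <- run_experiment1(cat21, rich_config(), noise_model(0),
                          n_trials_per_category = 4, seed = 5)
  expect_equal(sim0$result$percent_correct, 100)
  expect_equal(sim0$result$n_trials, 7 * 4)

  s1 <- run_experiment1(cat21, baseline_config(), noise_model(0.5), 6, seed = 11)
  s2 <- run_experiment1(cat21, baseline_config(), noise_model(0.5), 6, seed = 11)
  expect_identical(s1$log, s2$log)
  expect_s3_class(tidy(s1), "tbl_df")
  expect_named(glance(s1), c("participant", "n_trials", "n_correct", "percent_correct"))
})

test_that("full lapsing drives identification to chance", {
  cat21 <- test_catalog()
  sim <- run_experiment1(cat21[cat21$category == "double_tap", ],
                         baseline_config(), noise_model(0, lapse = 1),
                         n_trials_per_category = 600, seed = 13)
  # 3 alternatives: accuracy within 4 binomial SEs of 1/3
  se <- sqrt(1 / 3 * 2 / 3 / 600) * 100
  expect_lt(abs(sim$result$percent_correct - 100 / 3), 4 * se)
})

test_that("discrimination simulation respects design constraints and reproducibility", {
  base <- baseline_config()
  red <- reduce_bitrate(base, "collapse")
  expect_error(run_experiment2(base, base, noise_model(0.5), 24, seed = 1),
               class = "spinesound_invalid")  # not a halved bitrate
  expect_error(run_experiment2(base, red, noise_model(0.5), 25, seed = 1),
               class = "spinesound_invalid")  # odd pair count

  cat21 <- test_catalog()
  s1 <- run_experiment2(base, red, noise_model(0.6), 24, seed = 2, catalog = cat21)
  s2 <- run_experiment2(base, red, noise_model(0.6), 24, seed = 2, catalog = cat21)
  expect_identical(s1$result, s2$result)

  r <- s1$result
  expect_equal(r$condition, c("baseline", "reduced"))
  expect_equal(r$hits + r$misses, c(12L, 12L))              # 50-50 split
  expect_equal(r$false_alarms + r$correct_rejections, c(12L, 12L))

  # noiseless observer separates items perfectly: d' at the corrected ceiling
  s0 <- run_experiment2(base, red, noise_model(0), 24, seed = 3, catalog = cat21)
  ceiling12 <- stats::qnorm(1 - 1 / 24) - stats::qnorm(1 / 24)
  expect_equal(s0$result$dprime, rep(ceiling12, 2))
})

test_that("reduce_bitrate reproduces the published reduction styles", {
  base <- make_config(c(3, 3), 20)
  halved <- reduce_bitrate(base, "halve_rate")
  expect_equal(halved$frame_rate, 10L)
  expect_equal(bitrate(halved), 31L)

  collapsed <- reduce_bitrate(base, "collapse")
  expect_equal(nrow(collapsed$channels), 1)
  expect_equal(bitrate(collapsed), 15L)

  minimal <- make_config(3, 5)
  expect_error(reduce_bitrate(minimal, "halve_rate"), class = "spinesound_invalid")
  expect_error(reduce_bitrate(minimal, "collapse"), class = "spinesound_invalid")
})
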