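# Shared objects for the test suite. Everything is generated in code; the
# catalog and configs are small enough to build once per test run.

baseline_config <- function() make_config(c(3, 3), frame_rate = 20)
rich_config <- function() config_from_summary(4, 12, 20)
reduced_config <- function() make_config(3, frame_rate = 10)

# cached fixture catalog (encoding 21 clips repeatedly would dominate runtime)
test_catalog <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fixture_catalog(seed = 1)
    cache
  }
})

# brute-force oracle: enumerate all 2^n sign patterns of the rank sums
wilcoxon_brute_force <- function(values, mu = 0) {
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  w_all <- apply(signs, 1, function(s) sum(r[as.logical(s)]))
  mean(w_all >= w_obs - 1e-12)
}

# oracle: best split of total levels over channels by enumerating compositions
allocate_levels_oracle <- function(total, k) {
  if (k == 1) return(total)
  best <- NULL
  best_prod <- -Inf
  recurse <- function(prefix, remaining, slots) {
    if (slots == 1) {
      split <- c(prefix, remaining)
      if (remaining >= 1 && all(diff(split) <= 0)) {
        p <- prod(split)
        if (p > best_prod) {
          best_prod <<- p
          best <<- split
        }
      }
      return()
    }
    for (v in seq_len(remaining - slots + 1)) {
      if (length(prefix) == 0 || v <= prefix[length(prefix)]) {
        recurse(c(prefix, v), remaining - v, slots - 1)
      }
    }
  }
  recurse(integer(0), total, k)
  best
}
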