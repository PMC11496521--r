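# Internal numeric helpers shared across modules.

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# floor with a tiny guard so exact powers of two survive log2 round-trips
floor_safe <- function(x, eps = 1e-9) floor(x + eps)

# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

abort_invalid <- function(msg) rlang::abort(msg, class = "spinesound_invalid")

`%||%` <- rlang::`%||%`
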