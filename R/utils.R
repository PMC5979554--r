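# small shared helpers

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# round-half-away-from-zero (base round() is banker's rounding)
round_half_away <- function(x) trunc(x + 0.5 * sign(x))

# wrap angles into (-pi, pi]; the boundary maps to +pi
wrap_angle <- function(x) {
  w <- x - 2 * pi * floor(x / (2 * pi)) # [0, 2*pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
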