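# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic package operations route through this so that a seed given
# once makes the whole call reproducible bit-for-bit.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic 31-ary string hash onto [0, .Machine$integer.max), used to
# derive independent per-tile seeds from a master seed and design coordinates.
# Plain integer arithmetic in double precision; stable across platforms.
stable_hash <- function(master_seed, ...) {
  key <- paste(c(master_seed, ...), collapse = "/")
  h <- 0
  m <- 2147483647
  for (b in utf8ToInt(key)) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %s.", name, lower))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %s.", name, lower))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %s.", name, upper))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort(sprintf("`%s` must be a whole number.", name))
  }
  invisible(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
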