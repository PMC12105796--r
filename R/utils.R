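# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Derive a per-call seed from a master seed by a fixed offset.  Kept below
## 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(master, offset) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  as.integer((as.double(master) * 1009 + offset) %% 2147483647)
}

## Evaluate `expr` with the RNG temporarily seeded; restores (or removes)
## .Random.seed afterwards so generators never disturb the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

## Centred moving average of window `k` (odd) with circular wrap.
moving_average_circular <- function(x, k = 11L) {
  stopifnot(k %% 2L == 1L, k >= 1L)
  n <- length(x)
  h <- (k - 1L) %/% 2L
  xx <- c(x[(n - h + 1L):n], x, x[1L:h])
  out <- stats::filter(xx, rep(1 / k, k), sides = 2)
  as.numeric(out[(h + 1L):(h + n)])
}

## Centred rolling maximum over window `k` (odd); edges use the shrunken
## window that fits inside the vector.
rolling_max <- function(x, k = 11L) {
  stopifnot(k %% 2L == 1L, k >= 1L)
  n <- length(x)
  h <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    max(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

## Shortest (circular) distance between hours a and b on a cycle of `period`.
circular_diff <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

## Wilson score interval for a binomial proportion.
wilson_ci <- function(x, n, level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

## Parse "HH:MM" (or "HH:MM:SS") to minutes after midnight.
parse_clock_minutes <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) < 2L || anyNA(suppressWarnings(as.numeric(parts))))
    stop("clock time must be 'HH:MM' or 'HH:MM:SS', got: ", x)
  as.numeric(parts[1]) * 60 + as.numeric(parts[2]) +
    if (length(parts) >= 3L) as.numeric(parts[3]) / 60 else 0
}
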