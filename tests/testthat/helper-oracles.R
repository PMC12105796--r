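# Independent oracles used to cross-check the package implementations.
# These deliberately use naive algorithms, not the package's code paths.

## Sleep scoring oracle: explicit minute-by-minute scan for runs of >=
## `min_bout` consecutive zero-count minutes.
sleep_oracle <- function(counts, min_bout = 5L) {
  n <- length(counts)
  asleep <- rep(FALSE, n)
  i <- 1L
  while (i <= n) {
    if (counts[i] == 0L) {
      j <- i
      while (j < n && counts[j + 1L] == 0L) j <- j + 1L
      if (j - i + 1L >= min_bout) asleep[i:j] <- TRUE
      i <- j + 1L
    } else i <- i + 1L
  }
  asleep
}

## Jonckheere-Terpstra statistic by brute force over all index pairs.
jt_stat_oracle <- function(x, g) {
  n <- length(x)
  s <- 0L
  for (a in seq_len(n - 1L)) for (b in seq.int(a + 1L, n)) {
    if (g[a] < g[b] && x[a] < x[b]) s <- s + 1L
    if (g[b] < g[a] && x[b] < x[a]) s <- s + 1L
  }
  s
}

## Permutation null sample of the JT statistic for a fixed grouping:
## draws `B` random permutations of tie-free scores and evaluates the
## statistic with vectorized pair comparisons.
jt_perm_null <- function(g, B = 10000L) {
  n <- length(g)
  pairs <- which(outer(g, g, "<"), arr.ind = TRUE)
  P <- t(replicate(B, sample.int(n)))
  stat <- integer(B)
  for (k in seq_len(nrow(pairs)))
    stat <- stat + (P[, pairs[k, 1]] < P[, pairs[k, 2]])
  stat
}

## Running mean by brute force (circular), for the profile smoother.
moving_avg_oracle <- function(x, k) {
  n <- length(x)
  h <- (k - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    idx <- ((i - h - 1L):(i + h - 1L)) %% n + 1L
    mean(x[idx])
  }, numeric(1))
}

## All permutations of 1:n as rows (tiny n only).
combinat_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- combinat_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

## Simple helpers for building fixtures.
make_series <- function(counts, start = "2024-01-01 08:00:00",
                        fly = "f1", channel = 1L) {
  beam_count_series(fly, "M1", channel,
                    as.POSIXct(start, tz = "UTC"), counts)
}
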