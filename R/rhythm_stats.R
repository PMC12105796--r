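# Rhythmicity statistics: Lomb-Scargle periodograms with an analytic
# false-alarm threshold, a JTK-style nonparametric cycling test built on the
# Jonckheere-Terpstra statistic, and the group-comparison decision tree
# (Shapiro/Levene gate -> t-test or Wilcoxon; Kruskal-Wallis + pairwise
# Wilcoxon with a compact letter display).

## Cache of Lomb-Scargle trigonometric bases keyed by the (regular) time
## grid and the frequency grid, to keep cohort-scale scans fast.
.ls_cache <- new.env(parent = emptyenv())

ls_basis <- function(t_h, freq) {
  key <- sprintf("n%d_t0%.6f_dt%.6f_f%.8f_%.8f_%d",
                 length(t_h), t_h[1], if (length(t_h) > 1) t_h[2] - t_h[1] else 0,
                 freq[1], freq[length(freq)], length(freq))
  hit <- .ls_cache[[key]]
  if (!is.null(hit)) return(hit)
  omega <- 2 * pi * freq
  basis <- lapply(seq_along(omega), function(j) {
    w <- omega[j]
    tau <- atan2(sum(sin(2 * w * t_h)), sum(cos(2 * w * t_h))) / (2 * w)
    arg <- w * (t_h - tau)
    co <- cos(arg); si <- sin(arg)
    list(co = co, si = si, cc = sum(co^2), ss = sum(si^2))
  })
  if (length(ls(.ls_cache)) > 8L) rm(list = ls(.ls_cache), envir = .ls_cache)
  .ls_cache[[key]] <- basis
  basis
}

#' Lomb-Scargle periodogram rhythmicity test
#'
#' Computes the variance-normalized Lomb-Scargle periodogram of a
#' constant-darkness activity segment over a grid of candidate periods
#' (default 14--34 h in 0.1 h steps), after binning the per-minute counts
#' into 10-min bins.  The rhythmicity criterion is the analytic
#' false-alarm probability of the band maximum in the aliasing-free
#' approximation of Baluev (2008, MNRAS 385, 1279):
#' `FAP(z) = 1 - (1 - exp(-z)) * exp(-tau(z))` with
#' `tau(z) = W exp(-z) sqrt(z)` and effective bandwidth
#' `W = delta_f * sqrt(4 pi var(t))`.  A fly is called rhythmic iff the
#' maximal power exceeds the power threshold solving `FAP(z) = alpha`
#' (simply counting independent Fourier frequencies under-estimates the
#' trials made by maximizing over an oversampled grid and mis-calibrates
#' the test).
#'
#' @param series A [beam_count_series()]: the DD segment (typically the
#'   first 9 DD days from [split_ld_dd()]).  At least 3 complete days.
#' @param period_range Period grid limits in hours.
#' @param period_step Grid step (h).
#' @param alpha Significance level of the false-alarm threshold.
#' @param bin_minutes Width of the pre-analysis bins (default 10).
#' @return An object of class `periodogram`: list with `periods`, `power`,
#'   `alpha`, `threshold`, `best_period`, `peak_power`, `p_value`,
#'   `rhythmic`, `bandwidth_w`.
#' @references Baluev, R. V. (2008) Assessing the statistical significance
#'   of periodogram peaks. MNRAS 385, 1279--1285.
#' @export
lomb_scargle <- function(series, period_range = c(14, 34), period_step = 0.1,
                         alpha = 0.05, bin_minutes = 10L) {
  stopifnot(inherits(series, "beam_count_series"))
  n_min <- length(series$counts)
  if (n_min < 3 * 1440L) stop("DD segment shorter than 3 days: refusing")
  n_bins <- n_min %/% bin_minutes
  x <- as.numeric(tapply(series$counts[seq_len(n_bins * bin_minutes)],
                         rep(seq_len(n_bins), each = bin_minutes), sum))
  t_h <- (seq_len(n_bins) - 0.5) * bin_minutes / 60

  periods <- seq(period_range[1], period_range[2], by = period_step)
  freq <- 1 / periods
  ## Baluev effective bandwidth of the scanned band
  w_eff <- (max(freq) - min(freq)) * sqrt(4 * pi * stats::var(t_h) *
                                            (n_bins - 1) / n_bins)
  fap <- function(z) 1 - (1 - exp(-z)) * exp(-w_eff * exp(-z) * sqrt(z))
  threshold <- stats::uniroot(function(z) fap(z) - alpha, c(1, 60),
                              tol = 1e-10)$root

  if (stats::var(x) == 0) {
    warning("constant (e.g. all-zero) series: classified arrhythmic")
    return(structure(list(periods = periods, power = rep(0, length(periods)),
                          alpha = alpha, threshold = threshold,
                          best_period = NA_real_, peak_power = 0,
                          p_value = 1, rhythmic = FALSE,
                          bandwidth_w = w_eff),
                     class = "periodogram"))
  }

  xc <- x - mean(x)
  basis <- ls_basis(t_h, freq)
  power <- vapply(basis, function(b) {
    (sum(xc * b$co)^2 / b$cc + sum(xc * b$si)^2 / b$ss) /
      (2 * stats::var(x))
  }, numeric(1))

  peak <- which.max(power)
  pmax_ <- power[peak]
  structure(list(periods = periods, power = power, alpha = alpha,
                 threshold = threshold, best_period = periods[peak],
                 peak_power = pmax_, p_value = min(1, fap(pmax_)),
                 rhythmic = pmax_ >= threshold, bandwidth_w = w_eff),
            class = "periodogram")}

#' @export
print.periodogram <- function(x, ...) {
  cat(sprintf("Lomb-Scargle periodogram: best period %s h, power %.2f (threshold %.2f at alpha %.2g) -> %s\n",
              fmt_or_na(x$best_period), x$peak_power, x$threshold, x$alpha,
              if (x$rhythmic) "rhythmic" else "arrhythmic"))
  invisible(x)
}

#' @export
plot.periodogram <- function(x, ...) {
  graphics::plot(x$periods, x$power, type = "l", xlab = "period (h)",
                 ylab = "normalized power", ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Percentage of rhythmic flies with a Wilson confidence interval
#'
#' @param flags Logical vector of per-fly rhythmic calls, or a list of
#'   [lomb_scargle()] results.
#' @param level Confidence level (default 0.95).
#' @return List with `n`, `n_rhythmic`, `fraction`, `percent`, `ci`
#'   (Wilson interval on the fraction).
#' @export
percent_rhythmic <- function(flags, level = 0.95) {
  if (is.list(flags))
    flags <- vapply(flags, function(p) isTRUE(p$rhythmic), logical(1))
  if (length(flags) == 0L) stop("empty cohort")
  k <- sum(flags)
  n <- length(flags)
  list(n = n, n_rhythmic = k, fraction = k / n, percent = 100 * k / n,
       ci = wilson_ci(k, n, level))
}

#' Average raw ROI intensities per brain
#'
#' JTK-style cycling analysis is run on per-brain means: raw per-cell ROI
#' values are averaged within each (brain, cluster, timepoint) group.
#'
#' @param rois Data frame with columns `brain_id`, `cluster`,
#'   `timepoint_h`, `value` (extra columns such as `cell_id` are ignored).
#' @return Data frame with one row per (brain, cluster, timepoint) and the
#'   arithmetic mean in `value`.
#' @export
per_brain_average <- function(rois) {
  stopifnot(all(c("brain_id", "cluster", "timepoint_h", "value") %in%
                  names(rois)))
  agg <- stats::aggregate(value ~ brain_id + cluster + timepoint_h,
                          data = rois, FUN = mean)
  agg[order(agg$cluster, agg$timepoint_h, agg$brain_id), , drop = FALSE]
}

## ---- Jonckheere-Terpstra machinery ------------------------------------

## Exact convolution of two coefficient vectors (no FFT, so tiny tail
## probabilities stay exact to floating rounding).
poly_conv <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  out
}

## Coefficients of the Gaussian binomial [m+n choose n]_q, i.e. the number
## of arrangements giving each value u = 0..m*n of the Mann-Whitney U
## statistic between groups of sizes m and n (no ties).
mwu_counts <- function(m, n) {
  p <- 1
  for (i in seq_len(n)) {
    ## multiply by (1 - q^(m+i)) ...
    a <- c(p, numeric(m + i))
    idx <- (m + i + 1L):length(a)
    a[idx] <- a[idx] - p
    ## ... and divide by (1 - q^i)
    for (k in seq.int(i + 1L, length(a))) a[k] <- a[k] + a[k - i]
    p <- a[seq_len(length(a) - i)]
  }
  p
}

.jt_cache <- new.env(parent = emptyenv())

## Exact null pmf of the JT statistic for ordered groups of sizes `sizes`
## under exchangeability of continuous data: the JT statistic is the sum of
## the Mann-Whitney U statistics of each group against all earlier ones,
## whose null distributions convolve.  Memoized: the null depends only on
## the group sizes, which repeat across lags and series.
jt_null_pmf <- function(sizes) {
  key <- paste(sizes, collapse = ",")
  hit <- .jt_cache[[key]]
  if (!is.null(hit)) return(hit)
  pmf <- 1
  m <- 0L
  for (n in sizes) {
    if (m > 0L) {
      u <- mwu_counts(m, n)
      pmf <- poly_conv(pmf, u / sum(u))
    }
    m <- m + n
  }
  if (length(ls(.jt_cache)) > 32L) rm(list = ls(.jt_cache), envir = .jt_cache)
  .jt_cache[[key]] <- pmf
  pmf
}

## Upper-tail P(JT >= stat) from the exact null pmf.
jt_null_tail <- function(sizes, stat) {
  pmf <- jt_null_pmf(sizes)
  sum(pmf[seq.int(stat + 1L, length(pmf))])
}

## Observed JT statistic: number of strictly concordant cross-group pairs,
## groups ordered by increasing reference value.
jt_statistic <- function(x, g) {
  lev <- sort(unique(g))
  stat <- 0
  for (i in seq_along(lev)[-length(lev)]) {
    xi <- x[g == lev[i]]
    for (j in seq.int(i + 1L, length(lev))) {
      xj <- x[g == lev[j]]
      stat <- stat + sum(outer(xi, xj, "<"))
    }
  }
  stat
}

## Normal approximation with tie correction (Kendall 1970 form), upper
## tail with continuity correction.
jt_normal_tail <- function(x, g, stat) {
  n <- length(x)
  ni <- as.numeric(table(g))
  tj <- as.numeric(table(x))    # ties in the data
  mu <- (n^2 - sum(ni^2)) / 4
  v1 <- n * (n - 1) * (2 * n + 5) - sum(ni * (ni - 1) * (2 * ni + 5)) -
    sum(tj * (tj - 1) * (2 * tj + 5))
  v2 <- sum(ni * (ni - 1) * (ni - 2)) * sum(tj * (tj - 1) * (tj - 2)) /
    (9 * n * (n - 1) * (n - 2))
  v3 <- sum(ni * (ni - 1)) * sum(tj * (tj - 1)) / (2 * n * (n - 1))
  sigma2 <- v1 / 72 + v2 + v3
  if (sigma2 <= 0) return(1)
  stats::pnorm((stat - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
}

#' JTK-style nonparametric cycling test
#'
#' Tests a per-brain-averaged staining time series for cycling at a given
#' reference period (24 h or 12 h in practice).  For every phase lag on the
#' sampling grid, the data are compared with a cosine reference of that
#' period via the Jonckheere-Terpstra statistic on groups ordered by the
#' reference value (the rank-correlation reading of Kendall's tau); the
#' one-sided upper-tail null probability is computed exactly by
#' dynamic-programming convolution when the data are tie-free and not too
#' long (`n <= exact_max_n`), otherwise by a tie-corrected normal
#' approximation.  The reported p-value is the minimum over lags,
#' Bonferroni-adjusted for the number of lags.
#'
#' @param samples Data frame of per-brain samples with columns
#'   `timepoint_h` and `value` (see [per_brain_average()]); at least 4
#'   distinct timepoints.
#' @param period Reference period (h), e.g. 24 or 12.
#' @param sampling_interval Lag grid step (h); defaults to the sampling
#'   interval of the data.
#' @param exact_max_n Largest tie-free sample size for which the exact
#'   null is used (default 40).
#' @return An object of class `jtk_result`: list with `period_tested`,
#'   `best_lag`, `tau` (Kendall correlation with the winning reference),
#'   `p_value` (Bonferroni-adjusted), `p_per_lag`, `n_lags`, `method`.
#' @export
jtk_cycle <- function(samples, period = 24, sampling_interval = NULL,
                      exact_max_n = 40L) {
  stopifnot(all(c("timepoint_h", "value") %in% names(samples)))
  x <- samples$value
  tp <- samples$timepoint_h
  utp <- sort(unique(tp))
  if (length(utp) < 4L) stop("need at least 4 distinct timepoints")
  if (is.null(sampling_interval)) sampling_interval <- min(diff(utp))
  lags <- seq(0, period - sampling_interval, by = sampling_interval)

  if (length(unique(x)) == 1L) {
    return(structure(list(period_tested = period, best_lag = NA_real_,
                          tau = NA_real_, p_value = 1,
                          p_per_lag = rep(1, length(lags)),
                          n_lags = length(lags), method = "degenerate"),
                     class = "jtk_result"))
  }

  has_ties <- anyDuplicated(x) > 0L
  n <- length(x)
  res <- lapply(lags, function(lag) {
    ref <- cos(2 * pi * (tp - lag) / period)
    g <- match(round(ref, 9), sort(unique(round(ref, 9))))  # ordered groups
    if (length(unique(g)) < 2L) return(list(p = 1, stat = NA, g = g))
    stat <- jt_statistic(x, g)
    p <- if (!has_ties && n <= exact_max_n)
      jt_null_tail(as.integer(table(g)), stat)
    else jt_normal_tail(x, g, stat)
    list(p = p, stat = stat, g = g,
         tau = suppressWarnings(stats::cor(x, ref, method = "kendall")))
  })
  p_per_lag <- vapply(res, `[[`, numeric(1), "p")
  best <- which.min(p_per_lag)
  structure(list(period_tested = period, best_lag = lags[best],
                 tau = res[[best]]$tau,
                 p_value = min(1, length(lags) * p_per_lag[best]),
                 p_per_lag = p_per_lag, n_lags = length(lags),
                 statistic = res[[best]]$stat,
                 groups = res[[best]]$g,
                 method = if (!has_ties && n <= exact_max_n) "exact"
                 else "normal-approximation"),
            class = "jtk_result")
}

#' @export
print.jtk_result <- function(x, ...) {
  cat(sprintf("JTK-style cycling test (period %g h): p = %.3g, tau = %s, best lag %s h [%s]\n",
              x$period_tested, x$p_value, fmt_or_na(x$tau),
              fmt_or_na(x$best_lag), x$method))
  invisible(x)
}

## ---- Group comparisons -------------------------------------------------

## Levene/Brown-Forsythe test of variance homogeneity (median-centred).
levene_test <- function(values, groups) {
  groups <- factor(groups)
  centres <- tapply(values, groups, stats::median)
  z <- abs(values - centres[groups])
  out <- stats::oneway.test(z ~ groups, var.equal = TRUE)
  list(statistic = unname(out$statistic), p_value = unname(out$p.value))
}

## Compact letter display from a logical "significantly different" matrix,
## by the insert-and-absorb algorithm.
compact_letters <- function(sig) {
  k <- nrow(sig)
  groups <- list(seq_len(k))  # start: everyone shares letter "a"
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    if (!sig[i, j]) next
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      if (i %in% g && j %in% g) {
        groups[[gi]] <- setdiff(g, j)
        gnew <- setdiff(g, i)
        dup <- any(vapply(groups, function(h) all(gnew %in% h), logical(1)))
        if (!dup) groups[[length(groups) + 1L]] <- gnew
      }
    }
    ## absorb letter-sets contained in others
    keep <- !vapply(seq_along(groups), function(a) {
      any(vapply(seq_along(groups), function(b)
        a != b && all(groups[[a]] %in% groups[[b]]), logical(1)))
    }, logical(1))
    groups <- groups[keep]
  }
  letters_out <- character(k)
  for (gi in seq_along(groups))
    for (m in groups[[gi]])
      letters_out[m] <- paste0(letters_out[m], letters[gi])
  letters_out
}

#' Group comparison following the parametric/nonparametric decision tree
#'
#' For two groups: each group is tested for normality (Shapiro-Wilk) and
#' the pair for variance homogeneity (Levene, median-centred); if all
#' three p-values are >= 0.05 a two-sample t-test (equal variances) is
#' used, otherwise the Wilcoxon rank-sum test.  For more than two groups:
#' a Kruskal-Wallis omnibus test followed by pairwise Wilcoxon tests with
#' Holm adjustment and a compact letter display at the 0.05 level.
#' Degenerate (constant) groups fall to the nonparametric branch with a
#' warning.
#'
#' @param groups Named list of numeric vectors (>= 2 groups of >= 3
#'   values each).
#' @param paired Two-group case only: paired samples.
#' @param alpha Gate and letter-display level (default 0.05).
#' @return An object of class `group_comparison`: list with `test_used`,
#'   `statistic`, `p_value`, and for the omnibus branch `pairwise`
#'   (Holm-adjusted p matrix) and `letters`.
#' @export
compare_groups <- function(groups, paired = FALSE, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) < 3L)) stop("each group needs >= 3 values")
  k <- length(groups)

  if (k == 2L) {
    degenerate <- vapply(groups, function(g) stats::var(g) == 0, logical(1))
    if (any(degenerate)) {
      warning("constant group: falling back to the nonparametric branch")
      normal_ok <- FALSE
    } else {
      sh <- vapply(groups, function(g) stats::shapiro.test(g)$p.value,
                   numeric(1))
      lev <- levene_test(unlist(groups),
                         rep(names(groups), lengths(groups)))$p_value
      normal_ok <- all(sh >= alpha) && lev >= alpha
    }
    if (normal_ok) {
      tt <- stats::t.test(groups[[1]], groups[[2]], paired = paired,
                          var.equal = !paired)
      out <- list(test_used = if (paired) "paired t-test" else "t-test",
                  statistic = unname(tt$statistic),
                  p_value = tt$p.value, pairwise = NULL, letters = NULL)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]],
                                                paired = paired))
      out <- list(test_used = if (paired) "Wilcoxon signed-rank"
                  else "Wilcoxon rank-sum",
                  statistic = unname(wt$statistic),
                  p_value = wt$p.value, pairwise = NULL, letters = NULL)
    }
  } else {
    values <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(names(groups), lengths(groups)),
                  levels = names(groups))
    kw <- stats::kruskal.test(values, fac)
    pw <- suppressWarnings(stats::pairwise.wilcox.test(
      values, fac, p.adjust.method = "holm"))$p.value
    full <- matrix(NA_real_, k, k, dimnames = list(names(groups),
                                                   names(groups)))
    for (a in rownames(pw)) for (b in colnames(pw))
      if (!is.na(pw[a, b])) full[a, b] <- full[b, a] <- pw[a, b]
    sig <- !is.na(full) & full < alpha
    lets <- compact_letters(sig)
    names(lets) <- names(groups)
    out <- list(test_used = "Kruskal-Wallis + pairwise Wilcoxon (Holm)",
                statistic = unname(kw$statistic), p_value = kw$p.value,
                pairwise = full, letters = lets)
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison [%s]: statistic %.3f, p = %.3g\n",
              x$test_used, x$statistic, x$p_value))
  if (!is.null(x$letters))
    cat("  letters:", paste(names(x$letters), x$letters, sep = "=",
                            collapse = ", "), "\n")
  invisible(x)
}
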