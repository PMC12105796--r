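test_that("a single tone is recovered by the periodogram", {
  set.seed(55)
  t_min <- seq_len(9 * 1440) - 1
  lam <- 2 * (1 + 0.8 * cos(2 * pi * t_min / 60 / 24.5))
  s <- make_series(rpois(length(lam), lam))
  pg <- lomb_scargle(s)
  expect_true(pg$rhythmic)
  expect_lt(abs(pg$best_period - 24.5), 0.5)
  expect_lt(pg$p_value, 0.001)
})

test_that("periodogram contracts: constant series, short segments, power law", {
  expect_warning(pg <- lomb_scargle(make_series(rep(0L, 4 * 1440L))),
                 "arrhythmic")
  expect_false(pg$rhythmic)
  expect_equal(pg$p_value, 1)
  expect_error(lomb_scargle(make_series(rep(1L, 2 * 1440L))), "3 days")
  # power at the true frequency grows with amplitude on noiseless input
  t_min <- seq_len(5 * 1440) - 1
  pow_at <- function(a) {
    x <- round(1000 * (1 + a * cos(2 * pi * t_min / 60 / 24)))
    pg <- lomb_scargle(make_series(x))
    pg$power[which.min(abs(pg$periods - 24))]
  }
  p1 <- pow_at(0.2); p2 <- pow_at(0.5); p3 <- pow_at(0.9)
  expect_true(p1 < p2 && p2 < p3)
})

test_that("percent_rhythmic counts flags with a Wilson interval", {
  expect_equal(percent_rhythmic(rep(FALSE, 30))$percent, 0)
  pr <- percent_rhythmic(rep(c(TRUE, FALSE), 15))
  expect_equal(pr$percent, 50)
  # Wilson interval cross-check against the closed form
  z <- qnorm(0.975)
  expect_equal(unname(pr$ci["upper"]),
               (0.5 + z^2 / 60 + z * sqrt(0.25 / 30 + z^2 / 3600)) /
                 (1 + z^2 / 30))
  expect_error(percent_rhythmic(logical(0)), "empty")
  # permutation equivariance
  set.seed(1); flags <- runif(40) < 0.4
  expect_equal(percent_rhythmic(flags)$fraction,
               percent_rhythmic(sample(flags))$fraction)
})

test_that("per-brain averaging equals a group-by-mean oracle", {
  expect_equal(per_brain_average(data.frame(
    brain_id = "b1", cluster = "LNd", timepoint_h = 0,
    value = c(10, 20)))$value, 15)
  set.seed(77)
  tab <- data.frame(brain_id = sample(paste0("b", 1:4), 60, TRUE),
                    cluster = sample(c("LNd", "DN1"), 60, TRUE),
                    timepoint_h = sample(seq(0, 21, 3), 60, TRUE),
                    value = rnorm(60))
  avg <- per_brain_average(tab)
  key <- paste(tab$brain_id, tab$cluster, tab$timepoint_h)
  oracle <- tapply(tab$value, key, mean)
  expect_equal(avg$value[match(names(oracle),
                               paste(avg$brain_id, avg$cluster,
                                     avg$timepoint_h))],
               as.numeric(oracle), ignore_attr = TRUE)
})

test_that("exact JT null matches brute-force enumeration at small n", {
  # full enumeration over all 6!/(2!2!2!) label-to-value assignments
  sizes <- c(2, 2, 2)
  g <- rep(1:3, times = sizes)
  perms <- combinat_perms(6)
  stats_all <- apply(perms, 1, function(ix) jt_stat_oracle(ix, g))
  pmf_enum <- tabulate(stats_all + 1, nbins = max(stats_all) + 1) /
    length(stats_all)
  pmf_dp <- chronocline:::jt_null_pmf(sizes)
  expect_equal(pmf_dp[seq_along(pmf_enum)], pmf_enum, tolerance = 1e-12)
})

test_that("jtk_cycle finds the phase of a noiseless cosine at minimal p", {
  tp <- seq(0, 21, 3)
  d <- gen_staining_series(cosinor_params(amp24 = 20, sigma = 0,
                                          phase24 = 6, n_brains = 3,
                                          timepoints = tp, seed = 2))
  res <- jtk_cycle(per_brain_average(d), period = 24)
  expect_equal(res$best_lag, 6)
  # perfect concordance: the statistic attains the cross-group maximum
  sizes <- as.integer(table(res$groups))
  expect_equal(res$statistic, (sum(sizes)^2 - sum(sizes^2)) / 2)
  expect_lt(res$p_value, 1e-6)
})

test_that("jtk_cycle degenerate and invariance contracts hold", {
  tp <- seq(0, 21, 3)
  const <- data.frame(timepoint_h = rep(tp, each = 3), value = 5)
  expect_equal(jtk_cycle(const, period = 24)$p_value, 1)
  expect_error(jtk_cycle(data.frame(timepoint_h = c(0, 6, 12), value = 1:3),
                         period = 24), "4 distinct")
  # rank invariance: any strictly increasing transform leaves p unchanged
  set.seed(9)
  d <- data.frame(timepoint_h = rep(tp, each = 3), value = rnorm(24))
  p1 <- jtk_cycle(d, period = 24)$p_value
  d2 <- d; d2$value <- exp(3 * d$value) - 1
  expect_identical(jtk_cycle(d2, period = 24)$p_value, p1)
})

test_that("null jtk p-values are (super-)uniform", {
  set.seed(31)
  tp <- seq(0, 21, 3)
  pvals <- replicate(400, {
    d <- data.frame(timepoint_h = rep(tp, each = 3), value = rnorm(24))
    jtk_cycle(d, period = 24)$p_value
  })
  # super-uniform: P(p <= a) <= a (one-sided check at a few levels)
  for (a in c(0.05, 0.1, 0.25))
    expect_lte(mean(pvals <= a), a + 3 * sqrt(a * (1 - a) / 400))
})

test_that("two-group comparison takes the gated parametric path", {
  set.seed(5)
  g1 <- rnorm(20); g2 <- rnorm(20, mean = 5)
  res <- compare_groups(list(a = g1, b = g2))
  expect_match(res$test_used, "t-test")
  expect_lt(res$p_value, 0.001)
  # skewed data falls to Wilcoxon
  set.seed(6)
  s1 <- exp(rnorm(25, sd = 1.5)); s2 <- exp(rnorm(25, sd = 1.5)) + 1
  res2 <- compare_groups(list(a = s1, b = s2))
  expect_match(res2$test_used, "Wilcoxon")
  # constant group falls to the nonparametric branch with a warning
  expect_warning(res3 <- compare_groups(list(a = rep(1, 5), b = rnorm(5))),
                 "nonparametric")
  expect_match(res3$test_used, "Wilcoxon")
})

test_that("multi-group comparison yields letters consistent with the shifts", {
  set.seed(8)
  gr <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15, mean = 4))
  res <- compare_groups(gr)
  expect_match(res$test_used, "Kruskal")
  expect_lt(res$p_value, 0.01)
  expect_equal(dim(res$pairwise), c(3, 3))
  # the shifted group gets its own letter; the null pair shares one
  expect_identical(res$letters[["a"]], res$letters[["b"]])
  expect_false(res$letters[["c"]] %in% res$letters[c("a", "b")])
  # Holm-adjusted pairwise p agrees with the reference implementation
  vals <- unlist(gr); fac <- factor(rep(names(gr), lengths(gr)),
                                    levels = names(gr))
  ref <- suppressWarnings(pairwise.wilcox.test(vals, fac, "holm"))$p.value
  expect_equal(res$pairwise["b", "a"], ref["b", "a"])
  # identical groups: omnibus p near 1 and a single shared letter
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  res_same <- suppressWarnings(compare_groups(same))
  expect_gt(res_same$p_value, 0.9)
  expect_length(unique(unlist(res_same$letters)), 1)
})
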