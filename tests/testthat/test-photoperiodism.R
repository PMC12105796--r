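noiseless_panel <- function(d, b, e, nl = seq(4, 18, 2), n = 1000) {
  data.frame(night_length = nl,
             n_diapause = n * d / (1 + exp(-b * (nl - e))),
             n_total = n)
}

test_that("noiseless response curves are recovered to 3 decimals", {
  fit <- suppressWarnings(fit_pprc(noiseless_panel(1, 2, 9)))
  expect_equal(unname(coef(fit)), c(1, 2, 9), tolerance = 1e-4)
  expect_equal(fit$cnl, 9, tolerance = 1e-3)
  # with d = 1 the CNL coincides with the ED50 exactly
  expect_equal(fit$cnl, unname(coef(fit)["ed50"]), tolerance = 1e-6)
  # free asymptote is recovered too
  fit2 <- suppressWarnings(fit_pprc(noiseless_panel(0.8, 2, 9)))
  expect_equal(unname(coef(fit2)), c(0.8, 2, 9), tolerance = 1e-3)
})

test_that("CNL is the absolute 50% crossing, checked against closed form", {
  fit <- suppressWarnings(fit_pprc(noiseless_panel(0.8, 2, 9)))
  cf <- coef(fit)
  closed <- unname(cf["ed50"] - log(2 * cf["asymptote"] - 1) / cf["slope"])
  expect_equal(fit$cnl, closed, tolerance = 1e-6)   # root-finder vs algebra
  expect_gt(fit$cnl, cf["ed50"])                    # d < 1 pushes CNL later
  # asymptote below one half: no crossing, CNL undefined
  fit04 <- suppressWarnings(fit_pprc(noiseless_panel(0.4, 2, 9)))
  expect_true(is.na(fit04$cnl))
  # all-zero responses: separation flagged, CNL undefined
  all0 <- data.frame(night_length = seq(4, 18, 2), n_diapause = 0,
                     n_total = 30)
  fit0 <- suppressWarnings(fit_pprc(all0))
  expect_true(fit0$separation)
  expect_true(is.na(fit0$cnl))
})

test_that("shift equivariance: translating night lengths translates the CNL", {
  set.seed(12)
  p <- strain_sim_params(cnl_true = 8, seed = 13)
  pan <- gen_diapause_panel(p, seq(3, 17, 2), n_per_point = 40)
  fit_a <- fit_pprc(pan)
  pan_b <- pan; pan_b$night_length <- pan$night_length + 2.5
  fit_b <- fit_pprc(pan_b)
  expect_equal(fit_b$cnl - fit_a$cnl, 2.5, tolerance = 1e-4)
  expect_equal(unname(coef(fit_b)["slope"]), unname(coef(fit_a)["slope"]),
               tolerance = 1e-3)
})

test_that("fitted curves are bounded, monotone, and consistent with glm at d=1", {
  fit <- suppressWarnings(fit_pprc(noiseless_panel(1, 1.5, 9)))
  grid <- seq(0, 24, 0.25)
  pred <- predict(fit, grid)
  expect_true(all(pred >= 0 & pred <= coef(fit)["asymptote"] + 1e-9))
  expect_true(all(diff(pred) >= 0))
})

test_that("two-parameter reduction agrees with stats::glm", {
  # exact logistic data with d = 1 over 4 night lengths
  nl <- c(5, 8, 11, 14)
  pr <- plogis(1.2 * (nl - 9))
  pan <- data.frame(night_length = nl, n_diapause = 200 * pr, n_total = 200)
  fit <- suppressWarnings(fit_pprc(pan))
  gfit <- suppressWarnings(glm(cbind(n_diapause, n_total - n_diapause) ~
                                 night_length, binomial(), data = pan))
  expect_equal(unname(coef(fit)["slope"]), unname(coef(gfit)[2]),
               tolerance = 1e-3)
  expect_equal(unname(coef(fit)["ed50"]),
               -unname(coef(gfit)[1] / coef(gfit)[2]), tolerance = 1e-3)
})

test_that("bootstrap CI is seeded-deterministic and collapses when noiseless", {
  p <- strain_sim_params(cnl_true = 9, pprc_slope = 1.5, seed = 14)
  pan <- gen_diapause_panel(p, seq(4, 18, 2), n_per_point = 30)
  fit <- fit_pprc(pan)
  ci1 <- bootstrap_cnl_ci(fit, n_boot = 60, seed = 99)
  ci2 <- bootstrap_cnl_ci(fit, n_boot = 60, seed = 99)
  expect_identical(ci1, ci2)
  expect_true(ci1[["lower"]] < fit$cnl && fit$cnl < ci1[["upper"]])
  # near-step noiseless data: interval width shrinks towards 0
  sharp <- noiseless_panel(1, 30, 9, n = 5000)
  fit_s <- suppressWarnings(fit_pprc(sharp))
  ci_s <- bootstrap_cnl_ci(fit_s, n_boot = 60, seed = 1)
  expect_lt(ci_s[["upper"]] - ci_s[["lower"]], 0.15)
})

test_that("pprc_fit methods behave like a standard model object", {
  p <- strain_sim_params(cnl_true = 9, seed = 15)
  pan <- gen_diapause_panel(p, seq(4, 18, 2), n_per_point = 30)
  fit <- fit_pprc(pan)
  expect_s3_class(fit, "pprc_fit")
  expect_named(coef(fit), c("asymptote", "slope", "ed50"))
  expect_length(predict(fit, c(4, 9, 14)), 3)
  expect_length(residuals(fit), nrow(pan))
  expect_equal(attr(logLik(fit), "df"), 3L)
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_equal(dim(sims), c(nrow(pan), 2))
  expect_identical(sims, simulate(fit, nsim = 2, seed = 3))
  expect_output(print(fit), "CNL")
})

test_that("latitude correlation handles collinearity, exclusions and errors", {
  lat <- c(69, 62, 55, 48, 41)
  expect_equal(correlate_with_latitude(lat, 20 - 0.2 * lat)$r, -1,
               tolerance = 1e-12)
  # undefined metrics are excluded with a message
  expect_message(res <- correlate_with_latitude(lat, c(1, 2, NA, 4, 5)),
                 "excluding")
  expect_equal(res$n, 4)
  expect_error(correlate_with_latitude(lat, rep(1, 5)), "zero variance")
  expect_error(correlate_with_latitude(c(50, 51), c(1, 2)))
  # null behaviour: permuted pairings give roughly uniform p
  set.seed(20)
  ps <- replicate(200, correlate_with_latitude(rnorm(10), rnorm(10))$p_value)
  expect_gt(mean(ps > 0.05), 0.85)
})
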