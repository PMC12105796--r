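test_that("generators are deterministic under a fixed seed", {
  sch <- light_schedule(12, 12, "08:00", dd_start_day = 2)
  p <- strain_sim_params(seed = 123)
  a <- gen_dam_cohort(p, sch, n_flies = 2, n_ld_days = 1, n_dd_days = 1)
  b <- gen_dam_cohort(p, sch, n_flies = 2, n_ld_days = 1, n_dd_days = 1)
  expect_identical(lapply(a, `[[`, "counts"), lapply(b, `[[`, "counts"))
  expect_identical(attr(a, "truth"), attr(b, "truth"))

  pan_a <- gen_diapause_panel(p, seq(4, 18, 2))
  pan_b <- gen_diapause_panel(p, seq(4, 18, 2))
  expect_identical(pan_a$n_diapause, pan_b$n_diapause)

  cp <- cosinor_params(seed = 5)
  expect_identical(gen_staining_series(cp)$value, gen_staining_series(cp)$value)
})

test_that("flat activity model gives i.i.d. Poisson counts", {
  sch <- light_schedule(12, 12, "08:00", dd_start_day = 3)
  p <- strain_sim_params(m_amp = 0, e_amp = 0, siesta_depth = 0,
                         baseline_rate = 2, seed = 7)
  coh <- gen_dam_cohort(p, sch, n_flies = 5, n_ld_days = 2, n_dd_days = 0)
  x <- unlist(lapply(coh, `[[`, "counts"))
  expect_equal(mean(x), 2, tolerance = 0.03)
  # Poisson: variance/mean ratio near 1
  expect_equal(var(x) / mean(x), 1, tolerance = 0.05)
})

test_that("arrhythmic flies carry no periodic component in DD", {
  sch <- light_schedule(12, 12, "08:00", dd_start_day = 2)
  p <- strain_sim_params(rhythmic_fraction = 0, baseline_rate = 3, seed = 8)
  coh <- gen_dam_cohort(p, sch, n_flies = 4, n_ld_days = 1, n_dd_days = 9)
  truth <- attr(coh, "truth")
  expect_false(any(truth$rhythmic))
  # DD segment is flat Poisson: daily means indistinguishable across ZT halves
  dd <- coh[[1]]$counts[-(1:1440)]
  zt_bin <- rep(rep(c(1, 2), each = 720), length.out = length(dd))
  expect_equal(mean(dd[zt_bin == 1]), mean(dd[zt_bin == 2]), tolerance = 0.05)
})

test_that("diapause panel follows the logistic response", {
  p <- strain_sim_params(cnl_true = 9, pprc_slope = 2, pprc_asymptote = 1,
                         seed = 11)
  # at NL = cnl_true the expected fraction is asymptote/2
  pan <- gen_diapause_panel(p, rep(9, 200), n_per_point = 30)
  frac <- sum(pan$n_diapause) / sum(pan$n_total)
  se <- sqrt(0.25 / sum(pan$n_total))
  expect_lt(abs(frac - 0.5), 4 * se)
  # steep slope limit: step function around cnl_true
  p2 <- strain_sim_params(cnl_true = 9, pprc_slope = 500, seed = 12)
  pan2 <- gen_diapause_panel(p2, c(4, 6, 8, 10, 12, 14), n_per_point = 40)
  expect_true(all(pan2$n_diapause[pan2$night_length < 9] == 0))
  expect_true(all(pan2$n_diapause[pan2$night_length > 9] == 40))
  # input validation
  expect_error(gen_diapause_panel(p, numeric(0)), "non-empty")
  expect_error(gen_diapause_panel(p, c(0, 8)), "night lengths")
})

test_that("staining series realizes the cosinor model exactly at sigma 0", {
  tp <- seq(0, 21, 3)
  flat <- cosinor_params(mesor = 50, amp24 = 0, amp12 = 0, sigma = 0,
                         n_brains = 3, timepoints = tp, seed = 1)
  expect_true(all(gen_staining_series(flat)$value == 50))
  # cosine maximum at the phase
  c24 <- cosinor_params(mesor = 50, amp24 = 10, sigma = 0, phase24 = 6,
                        n_brains = 1, timepoints = tp, seed = 1)
  d <- gen_staining_series(c24)
  expect_equal(d$value[d$timepoint_h == 6], 60)
  # both harmonics superpose
  c12 <- cosinor_params(mesor = 0, amp24 = 2, amp12 = 1, phase24 = 0,
                        phase12 = 0, sigma = 0, n_brains = 1,
                        timepoints = tp, seed = 1)
  v <- gen_staining_series(c12)$value
  expect_equal(v, 2 * cos(2 * pi * tp / 24) + cos(2 * pi * tp / 12))
})

test_that("image fixture is piecewise constant with exact sidecar truth", {
  fx <- gen_image_fixture(shape = c(3, 32, 32),
                          somata = list(list(centre = c(16, 16), radius = 5,
                                             intensity = c(100, 50))),
                          background = 10)
  tr <- fx$truth$somata[[1]]
  # soma pixels have value background + intensity, elsewhere background
  expect_equal(unique(fx$ch1[1, , ][tr$mask]), 110)
  expect_equal(unique(as.numeric(fx$ch1[1, , ])[-tr$mask]), 10)
  expect_equal(tr$area_px, sum((outer((1:32 - 16)^2, (1:32 - 16)^2, "+")) <= 25))
  # channel ratio 2:1 everywhere (zero background) -> twice-subtraction
  # cancels exactly
  fx0 <- gen_image_fixture(shape = c(2, 16, 16),
                           somata = list(list(centre = c(8, 8), radius = 3,
                                              intensity = c(100, 50))),
                           background = 0)
  expect_true(all(fx0$ch1[1, , ] - 2 * fx0$ch2[1, , ] == 0))
  # overlap warns
  expect_warning(
    gen_image_fixture(shape = c(1, 20, 20),
                      somata = list(list(centre = c(10, 10), radius = 3,
                                         intensity = c(1, 1)),
                                    list(centre = c(11, 10), radius = 3,
                                         intensity = c(1, 1)))),
    "overlap")
  # geometry violations are errors
  expect_error(gen_image_fixture(shape = c(1, 10, 10),
                                 somata = list(list(centre = c(1, 1),
                                                    radius = 3,
                                                    intensity = c(1, 1)))),
               "beyond")
})

test_that("parameter invariants are enforced", {
  expect_error(strain_sim_params(pprc_asymptote = 1.2))
  expect_error(strain_sim_params(cnl_true = -1))
  expect_error(strain_sim_params(siesta_depth = 2))
  expect_error(cosinor_params(sigma = -1))
  sch <- light_schedule(12, 12, "08:00", dd_start_day = 2)
  expect_error(gen_dam_cohort(strain_sim_params(), sch, n_ld_days = 0),
               "duration|dd_start_day")
})
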