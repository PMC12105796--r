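test_that("max projection is a per-pixel maximum", {
  set.seed(60)
  st <- array(rpois(5 * 8 * 8, 20), dim = c(5, 8, 8))
  proj <- max_project(st)
  expect_equal(proj, apply(st, c(2, 3), max))       # brute-force oracle
  expect_equal(max_project(st, z_range = 3), st[3, , ])  # single plane: identity
  # disjoint bright spots from different planes both survive
  st2 <- array(0, dim = c(2, 4, 4)); st2[1, 1, 1] <- 9; st2[2, 4, 4] <- 7
  p2 <- max_project(st2)
  expect_equal(p2[1, 1], 9); expect_equal(p2[4, 4], 7)
  expect_error(max_project(st, integer(0)), "empty")
  expect_error(max_project(st, 9), "outside")
  # commutes with monotone pixelwise transforms
  expect_equal(max_project(st^2), proj^2)
})

test_that("nuclear ROI picks the brightest plane and subtracts background", {
  zp <- c(0.2, 0.5, 1, 0.6, 0.2, 0.1, 0.1, 0.1)
  fx <- gen_image_fixture(shape = c(8, 32, 32),
                          somata = list(list(centre = c(16, 16), radius = 4,
                                             intensity = c(80, 0),
                                             z_profile = zp)),
                          background = 10)
  m <- nuclear_intensity(fx$ch1, c(5, 16, 16), background = 10)
  expect_equal(m$plane, 3)                      # argmax over z profile
  expect_equal(m$value, 80)                     # 90 - 10, uniform nucleus
  # derived background ROI gives the same value on this flat background
  m2 <- nuclear_intensity(fx$ch1, c(5, 16, 16))
  expect_equal(m2$value, 80)
  expect_false(is.null(m2$bg_roi))
  # all-zero stack measures zero
  z <- array(0, dim = c(3, 16, 16))
  expect_equal(nuclear_intensity(z, c(2, 8, 8), background = 0)$value, 0)
  expect_error(nuclear_intensity(z, c(2, 1, 8), background = 0), "border")
})

test_that("top-10 ROI equals the sort-and-take oracle, with tie handling", {
  img <- matrix(0, 20, 20)
  img[1:2, 1:5] <- 50                          # exactly 10 px of value 50
  st <- array(img, dim = c(1, 20, 20))
  m <- top10_terminal_intensity(st, list(y = c(1, 20), x = c(1, 20)),
                                background = 0)
  expect_equal(m$value, 50)
  expect_equal(m$n_used, 10)
  # constant region: value c - background
  cst <- array(7, dim = c(1, 12, 12))
  expect_equal(top10_terminal_intensity(cst, list(y = c(1, 12), x = c(1, 12)),
                                        background = 2)$value, 5)
  # random region: brute-force sort oracle
  set.seed(61)
  r <- array(rnorm(1 * 15 * 15, 100, 20), dim = c(1, 15, 15))
  mr <- top10_terminal_intensity(r, list(y = c(1, 15), x = c(1, 15)),
                                 background = 0)
  expect_equal(mr$value, mean(sort(as.numeric(r), decreasing = TRUE)[1:10]))
  # ties at the cutoff renormalize over the pixels used
  tie <- array(0, dim = c(1, 10, 10)); tie[1, 1:2, 1:6] <- 4
  expect_message(mt <- top10_terminal_intensity(tie,
                                                list(y = c(1, 10),
                                                     x = c(1, 10)),
                                                background = 0), "tie")
  expect_equal(mt$n_used, 12)
  expect_equal(mt$value, 4)
  expect_error(top10_terminal_intensity(st, list(y = c(1, 3), x = c(1, 3)),
                                        background = 0), "smaller")
})

test_that("soma ROI measures mean intensity and rasterized area", {
  fx <- gen_image_fixture(shape = c(2, 40, 40),
                          somata = list(list(centre = c(20, 20), radius = 5,
                                             intensity = c(90, 0))),
                          background = 10, pixel_size = 0.5)
  tr <- fx$truth$somata[[1]]
  mask <- matrix(FALSE, 40, 40); mask[tr$mask] <- TRUE
  m <- soma_intensity_area(fx$ch1, mask, background = 10, pixel_size = 0.5)
  expect_equal(m$value, 90)
  expect_equal(m$area, tr$area_um2)
  # rasterized disc area close to pi r^2
  expect_lt(abs(m$area_px - pi * 25), 8)
  # one-pixel mask
  one <- matrix(FALSE, 40, 40); one[3, 3] <- TRUE
  m1 <- soma_intensity_area(fx$ch1, one, background = 0, pixel_size = 0.5)
  expect_equal(m1$value, 10)                    # background pixel
  expect_equal(m1$area, 0.25)
  expect_error(soma_intensity_area(fx$ch1, matrix(FALSE, 40, 40),
                                   background = 0), "empty")
})

test_that("channel subtraction clips at zero and respects masks", {
  set.seed(62)
  pdf_img <- matrix(rpois(100, 50), 10, 10)
  crz <- matrix(rpois(100, 20), 10, 10)
  out <- subtract_crz_channel(pdf_img, crz)
  expect_equal(out, pmax(pdf_img - 2 * crz, 0))   # elementwise oracle
  expect_true(all(out <= pdf_img))
  # pdf = 2 x crz exactly -> all-zero output
  expect_true(all(subtract_crz_channel(2 * crz, crz) == 0))
  # crz = 0 -> identity, and idempotent
  expect_equal(subtract_crz_channel(pdf_img, 0 * crz), pdf_img)
  # manual mask zeroes residual pixels
  mask <- matrix(FALSE, 10, 10); mask[1, ] <- TRUE
  expect_true(all(subtract_crz_channel(pdf_img, 0 * crz, manual_mask = mask)[1, ] == 0))
  expect_error(subtract_crz_channel(pdf_img, crz[1:5, ]), "mismatch")
})

test_that("whole-image terminal intensity sums the clipped residual", {
  img <- matrix(10, 12, 12)
  expect_equal(whole_image_terminal_intensity(img, 10)$value, 0)
  img[5, 5] <- 100
  expect_equal(whole_image_terminal_intensity(img, 10)$value, 90)
  set.seed(63)
  r <- matrix(rnorm(64, 20, 10), 8, 8)
  expect_equal(whole_image_terminal_intensity(r, 15)$value,
               sum(pmax(r - 15, 0)))
})

test_that("measures are monotone in any ROI pixel's intensity", {
  fx <- gen_image_fixture(shape = c(2, 24, 24),
                          somata = list(list(centre = c(12, 12), radius = 3,
                                             intensity = c(40, 0))),
                          background = 5)
  st <- fx$ch1
  base <- top10_terminal_intensity(st, list(y = c(8, 16), x = c(8, 16)),
                                   background = 5)$value
  st2 <- st; st2[1, 12, 12] <- st2[1, 12, 12] + 100
  up <- top10_terminal_intensity(st2, list(y = c(8, 16), x = c(8, 16)),
                                 background = 5)$value
  expect_gte(up, base)
})

test_that("image stack text round trip is exact", {
  set.seed(64)
  st <- array(rpois(3 * 6 * 5, 30), dim = c(3, 6, 5))
  path <- withr::local_tempfile(fileext = ".txt")
  write_image_stack(st, path)
  expect_equal(read_image_stack(path), st)
})
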