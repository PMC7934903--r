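test_that("area is the black-pixel count and is additive", {
  expect_equal(measure_area(matrix(0L, 50, 50)), 0)
  expect_equal(measure_area(make_square_mask(32)), 1024)
  a <- make_square_mask(10, x0 = 5, y0 = 5)
  b <- make_square_mask(10, x0 = 40, y0 = 40)
  expect_equal(measure_area(a | b), measure_area(a) + measure_area(b))
  expect_error(measure_area(matrix(c(0, 2), 2, 2)), "binary")
})

test_that("edge length tracks analytic perimeters and is additive", {
  sq <- make_square_mask(20)
  expect_lt(abs(measure_edge_length(sq) - 80), 4)

  two <- make_square_mask(20, x0 = 5, y0 = 5) | make_square_mask(20, x0 = 40, y0 = 40)
  expect_equal(measure_edge_length(two), 2 * measure_edge_length(sq))

  disc <- make_disc(15)
  expect_lt(abs(measure_edge_length(disc) - 2 * pi * 15) / (2 * pi * 15), 0.05)

  expect_equal(measure_edge_length(matrix(0L, 30, 30)), 0)
})

test_that("convex hull covers single elements and spans configurations", {
  sq <- make_square_mask(32, n = 120)
  expect_lt(abs(measure_convex_hull(sq) - 1024) / 1024, 0.03)

  disc <- make_disc(15)
  expect_lt(abs(measure_convex_hull(disc) - sum(disc)) / sum(disc), 0.03)

  two <- matrix(0L, 120, 120)
  two[3:12, 3:12] <- 1L
  two[109:118, 109:118] <- 1L
  expect_gte(measure_convex_hull(two) / sum(two), 10)

  empty <- measure_convex_hull(matrix(0L, 20, 20))
  expect_equal(as.numeric(empty), 0)
  expect_true(attr(empty, "empty"))
})

test_that("the radial power spectrum behaves like a Fourier spectrum", {
  # flat image: all power in DC
  flat <- matrix(1L, 64, 64)
  curve <- radial_power_spectrum(flat)
  expect_lt(max(curve$power), 1e-9 * attr(curve, "dc_power"))

  # sinusoidal grating at k cycles/image: one dominant radial bin
  k <- 9
  n <- 64
  g <- matrix(rep(sin(2 * pi * k * (0:(n - 1)) / n), each = n), n, n, byrow = TRUE)
  gc <- radial_power_spectrum(g)
  expect_equal(which.max(gc$power), k)
  expect_gt(gc$power[k], 100 * max(gc$power[-k]))

  # orientation averaging: a 90-degree rotation leaves the curve unchanged
  img <- generate_stimulus(3, "square", 1024, seed = 5)$pixels
  rot <- t(img)[, rev(seq_len(ncol(img)))]
  c1 <- radial_power_spectrum(img)
  c2 <- radial_power_spectrum(rot)
  expect_lt(max(abs(c1$power - c2$power) / (c1$power + 1e-12)), 1e-6)
})

test_that("total spectral power equals image energy (Parseval)", {
  set.seed(3)
  m <- matrix(rbinom(64 * 64, 1, 0.1), 64, 64)
  curve <- radial_power_spectrum(m)
  expect_lt(abs(attr(curve, "total_power") - 64^2 * sum(m^2)) /
              (64^2 * sum(m^2)), 1e-6)
})

test_that("sf_power is a linear functional of the curve", {
  zero <- tibble::tibble(freq = 1:60, power = rep(0, 60))
  class(zero) <- c("power_spectrum", class(zero))
  expect_equal(sf_power(zero), 0)

  img <- generate_stimulus(2, "circle", 1024, seed = 9)
  curve <- radial_power_spectrum(img)
  doubled <- curve
  doubled$power <- 2 * curve$power
  expect_equal(sf_power(doubled, f_min = 4), 2 * sf_power(curve, f_min = 4))
})

test_that("spatial-frequency power rises with element count at fixed area", {
  lib <- shared_test_library()
  means <- tapply(lib$sf_power, lib$n_elements, mean)
  expect_true(all(diff(means) > 0))
})

test_that("cues are invariant to translating the whole configuration", {
  base <- rasterize_element("square", 14, c(30, 30)) |
    rasterize_element("square", 14, c(70, 50))
  shifted <- rasterize_element("square", 14, c(35, 37)) |
    rasterize_element("square", 14, c(75, 57))
  base <- matrix(as.integer(base), 120, 120)
  shifted <- matrix(as.integer(shifted), 120, 120)
  expect_equal(measure_area(base), measure_area(shifted))
  expect_equal(measure_edge_length(base), measure_edge_length(shifted))
  expect_lt(abs(sf_power(base) - sf_power(shifted)) / sf_power(base), 0.01)
})

test_that("splitting an element raises edge length and spatial frequency", {
  one <- generate_stimulus(1, "square", 1024, seed = 31)
  fours <- purrr::map(1:5, ~ generate_stimulus(4, "square", 1024, seed = 310 + .x))
  expect_true(all(purrr::map_dbl(fours, measure_edge_length) >
                    measure_edge_length(one)))
  expect_gt(mean(purrr::map_dbl(fours, sf_power)), sf_power(one))
})

test_that("the s calibration anchors zero and orders counts", {
  lib <- shared_test_library()
  cal <- calibrate_s_mapping(lib)
  expect_equal(s_input(cal, 0), 0) # empty display has sf_power exactly 0

  lib_s <- measure_cues(dplyr::select(lib, n_elements, image), calibration = cal)
  means <- tapply(lib_s$s_input, lib_s$n_elements, mean)
  expect_true(all(diff(means) > 0))
  # the proportional fit over a mildly concave cue compresses the scale a
  # little; the 3-element mean must still sit mid-range
  expect_gt(means[["3"]], 2.5)
  expect_lt(means[["3"]], 4.0)

  flat <- tibble::tibble(n_elements = rep(1:3, each = 3), sf_power = 1)
  expect_error(calibrate_s_mapping(flat), class = "magbee_calibration_error")
})

test_that("cue covariation reports the rank structure of the set", {
  toy <- tibble::tibble(n_elements = rep(1:5, each = 4),
                        mono = rep(1:5, each = 4)^2)
  out <- cue_covariation(toy, cues = "mono")
  expect_equal(out$rho, 1)

  # constant cue + small jitter carries no rank information
  jit <- withr::with_seed(8, tibble::tibble(
    n_elements = rep(1:6, each = 40),
    area = 1024 + stats::rnorm(240, 0, 10)
  ))
  expect_lt(abs(cue_covariation(jit, cues = "area")$rho), 0.2)

  lib <- shared_test_library()
  tab <- cue_covariation(lib)
  expect_gt(tab$rho[tab$cue == "edge_length"], 0.85)
  expect_gt(tab$rho[tab$cue == "sf_power"], 0.85)
})
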