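test_that("rasterize_element draws shapes with the expected pixel counts", {
  expect_equal(sum(rasterize_element("square", 20, c(60, 60))), 400)

  # rotation by 45 degrees preserves area: with sub-pixel centering the
  # diamond matches the square's count within 2%
  diamond_counts <- vapply(
    list(c(60, 60), c(60.5, 60), c(60, 60.5), c(60.5, 60.5)),
    function(ctr) sum(rasterize_element("diamond", 20, ctr)),
    numeric(1)
  )
  expect_lte(min(abs(diamond_counts - 400)) / 400, 0.02)

  disc <- rasterize_element("circle", 11, c(60, 60))
  expect_lte(abs(sum(disc) - pi * 11^2) / (pi * 11^2), 0.03)
  # brute-force lattice count of the same disc
  expect_equal(sum(disc), sum(outer((-11):11, (-11):11,
                                    function(a, b) a^2 + b^2) <= 121))

  expect_error(rasterize_element("square", 30, c(5, 5)),
               class = "magbee_placement_error")
})

test_that("generated displays hold total area constant across counts", {
  empty <- generate_stimulus(0, "square", 1000, seed = 1)
  expect_equal(sum(empty$pixels), 0)

  one <- generate_stimulus(1, "square", 1024, seed = 2)
  expect_equal(sum(one$pixels), 1024)

  four <- generate_stimulus(4, "circle", 1024, seed = 7)
  expect_equal(count_components(four$pixels), 4)
  expect_gte(sum(four$pixels), 1004)
  expect_lte(sum(four$pixels), 1044)

  areas <- vapply(1:30, function(i) {
    sum(generate_stimulus(((i - 1) %% 6) + 1,
                          c("square", "diamond", "circle")[(i %% 3) + 1],
                          1024, seed = 1000 + i)$pixels)
  }, numeric(1))
  expect_lt(stats::sd(areas) / mean(areas), 0.02)
})

test_that("elements stay inside margins, apart, and countable", {
  for (seed in 1:8) {
    n <- (seed %% 6) + 1
    img <- generate_stimulus(n, c("square", "diamond", "circle")[(seed %% 3) + 1],
                             1024, seed = seed)
    m <- img$pixels
    # 2-px white margin all around
    expect_equal(sum(m[1:2, ]) + sum(m[119:120, ]) +
                   sum(m[, 1:2]) + sum(m[, 119:120]), 0)
    # the number of connected components equals the element count
    expect_equal(count_components(m), n)
  }
})

test_that("stimulus generation is deterministic given the seed", {
  a <- generate_stimulus(5, "diamond", 1024, seed = 99)
  b <- generate_stimulus(5, "diamond", 1024, seed = 99)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$elements, b$elements)
  c <- generate_stimulus(5, "diamond", 1024, seed = 100)
  expect_false(identical(a$pixels, c$pixels))
})

test_that("cue-biased pairs order edge, hull and spatial frequency jointly", {
  pair <- generate_cue_biased_pair(2, seed = 1)
  ch <- cue_vector(pair$high)
  cl <- cue_vector(pair$low)
  expect_gt(ch$edge_length, cl$edge_length)
  expect_gt(ch$convex_hull_area, cl$convex_hull_area)
  expect_gt(ch$sf_power, cl$sf_power)
  # area stays matched in the pair
  expect_lte(abs(ch$area - cl$area) / cl$area, 0.04)

  pair1 <- generate_cue_biased_pair(1, seed = 3)
  a1 <- measure_area(pair1$high)
  a2 <- measure_area(pair1$low)
  expect_lte(abs(a1 - a2) / a2, 0.02)
})

test_that("the incongruent-opposite construction beats a higher count on cues", {
  spec <- stimulus_set_spec("incongruent_opposite", seed = 5)
  set <- build_stimulus_set(spec)
  expect_setequal(set$n_elements, c(3, 2))
  hi <- measure_cues(set[set$cue_bias == "high", ])
  lo <- measure_cues(set[set$cue_bias == "low", ])
  # the 2-element display carries more edge, hull and SF than the 3-element
  expect_gt(hi$edge_length, lo$edge_length)
  expect_gt(hi$convex_hull_area, lo$convex_hull_area)
  expect_gt(hi$sf_power, lo$sf_power)
  expect_lt(hi$n_elements, lo$n_elements)
})

test_that("build_stimulus_set realizes each set kind", {
  tr <- build_stimulus_set(stimulus_set_spec("training", "more_than",
                                             n_displays = 6, seed = 11))
  by_trial <- split(tr, tr$trial)
  for (pair in by_trial) {
    expect_gt(pair$n_elements[pair$role == "correct"],
              pair$n_elements[pair$role == "incorrect"])
    expect_true(all(pair$shape_kind %in% c("square", "diamond")))
  }

  zc <- build_stimulus_set(stimulus_set_spec("zero_continuum", seed = 12))
  zeros <- zc[zc$n_elements == 0, ]
  others <- zc[zc$n_elements > 0, ]
  expect_equal(nrow(zeros), 6)
  expect_setequal(others$n_elements, 1:6)
  expect_true(all(zc$shape_kind == "circle"))

  tf <- build_stimulus_set(stimulus_set_spec("transfer_range", seed = 13))
  expect_setequal(tf$n_elements, c(5, 6))

  # reproducibility of a whole set
  s1 <- build_stimulus_set(stimulus_set_spec("training", n_displays = 3, seed = 8))
  s2 <- build_stimulus_set(stimulus_set_spec("training", n_displays = 3, seed = 8))
  expect_identical(purrr::map(s1$image, "pixels"), purrr::map(s2$image, "pixels"))
})

test_that("stimulus sets round-trip through PNG + manifest", {
  dir <- withr::local_tempdir()
  set <- build_stimulus_set(stimulus_set_spec("learning_test", seed = 21))
  manifest <- write_stimulus_set(set, dir)
  expect_equal(nrow(manifest), nrow(set))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "metadata.json")))
  m <- read_stimulus_image(file.path(dir, manifest$filename[1]))
  expect_identical(m, set$image[[1]]$pixels)
})
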