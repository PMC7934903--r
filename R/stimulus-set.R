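SET_KINDS <- c("training", "learning_test", "equal_incongruent",
               "incongruent_opposite", "conflict_zero", "transfer_range",
               "zero_continuum")

#' Specify a stimulus set
#'
#' Describes one labelled stimulus set of the two-alternative paradigm:
#' training streams over a count range, the learning test on the held-out
#' shape, cue-manipulated tests at equal or opposed numerosity, and the
#' zero-element test sets (conflict, beyond-range transfer, zero
#' continuum).
#'
#' @param set_kind one of `"training"`, `"learning_test"`,
#'   `"equal_incongruent"`, `"incongruent_opposite"`, `"conflict_zero"`,
#'   `"transfer_range"`, `"zero_continuum"`.
#' @param rule trained contingency, `"more_than"` or `"less_than"`.
#' @param counts element counts used by the set. Defaults by kind:
#'   training/learning 1-4, equal_incongruent `c(2, 2)`,
#'   incongruent_opposite `c(3, 2)`, conflict_zero `c(0, 3)`,
#'   transfer_range `c(5, 6)`, zero_continuum 0 vs 1..6.
#' @param n_displays number of training trials (training sets only).
#' @param target_area constant total black area (px^2).
#' @param width,height canvas size (px).
#' @param training_shapes the two shapes used in training.
#' @param test_shape the held-out shape used in tests.
#' @param seed master RNG seed of the set.
#' @return Object of class `stimulus_set_spec`.
#' @export
stimulus_set_spec <- function(set_kind, rule = c("more_than", "less_than"),
                              counts = NULL, n_displays = 20,
                              target_area = 1024, width = 120, height = 120,
                              training_shapes = c("square", "diamond"),
                              test_shape = "circle", seed = 1) {
  set_kind <- match.arg(set_kind, SET_KINDS)
  rule <- match.arg(rule)
  counts <- counts %||% switch(set_kind,
    training = 1:4,
    learning_test = c(1, 4),
    equal_incongruent = c(2, 2),
    incongruent_opposite = c(3, 2),
    conflict_zero = c(0, 3),
    transfer_range = c(5, 6),
    zero_continuum = 0:6
  )
  if (set_kind == "equal_incongruent" && length(unique(counts)) != 1) {
    abort("equal_incongruent requires two equal counts")
  }
  if (set_kind == "incongruent_opposite" &&
      !(length(counts) == 2 && counts[1] > counts[2])) {
    abort("incongruent_opposite requires counts c(higher, lower), e.g. c(3, 2)")
  }
  if (set_kind == "conflict_zero" && !0 %in% counts) {
    abort("conflict_zero requires a zero count")
  }
  if (set_kind == "transfer_range" && any(counts <= 4)) {
    abort("transfer_range counts must lie beyond the trained range (> 4)")
  }
  structure(
    list(set_kind = set_kind, rule = rule, counts = counts,
         n_displays = n_displays, target_area = target_area,
         width = width, height = height,
         training_shapes = training_shapes, test_shape = test_shape,
         seed = as.integer(seed)),
    class = "stimulus_set_spec"
  )
}

pair_rows <- function(trial, counts_pair, shapes, roles, seeds, spec,
                      cue_bias = c("none", "none")) {
  purrr::map2_dfr(1:2, seeds, function(k, sd) {
    img <- generate_stimulus(counts_pair[k], shapes[k], spec$target_area,
                             seed = sd, width = spec$width,
                             height = spec$height, cue_bias = cue_bias[k])
    tibble(trial = trial, role = roles[k],
           n_elements = counts_pair[k], shape_kind = shapes[k],
           cue_bias = cue_bias[k], seed = sd, image = list(img))
  })
}

#' Build a labelled stimulus set
#'
#' Generates every display of the set described by a
#' [stimulus_set_spec()], reproducibly from its seed, as a tibble with one
#' row per display and the raster in an `image` list-column. Training sets
#' draw the two training shapes; test sets use the held-out shape. Roles
#' are `"correct"`/`"incorrect"` under the set's trained rule, or
#' `"cue_high"`/`"cue_low"` for the cue-manipulated sets.
#'
#' @param spec a [stimulus_set_spec()].
#' @return Tibble: `stimulus_id`, `set_kind`, `rule`, `trial`, `role`,
#'   `n_elements`, `shape_kind`, `cue_bias`, `seed`, `image`.
#' @export
build_stimulus_set <- function(spec) {
  stopifnot(inherits(spec, "stimulus_set_spec"))
  withr::local_seed(spec$seed)
  more <- spec$rule == "more_than"
  res <- switch(spec$set_kind,
    training = purrr::map_dfr(seq_len(spec$n_displays), function(tr) {
      pr <- sort(sample(unique(spec$counts), 2))
      shp <- sample(spec$training_shapes, 2, replace = TRUE)
      correct_hi <- if (more) c("incorrect", "correct") else c("correct", "incorrect")
      pair_rows(tr, pr, shp, correct_hi,
                sample.int(.Machine$integer.max, 2), spec)
    }),
    learning_test = ,
    conflict_zero = ,
    transfer_range = {
      pr <- sort(spec$counts)[1:2]
      roles <- if (more) c("incorrect", "correct") else c("correct", "incorrect")
      pair_rows(1L, pr, rep(spec$test_shape, 2), roles,
                sample.int(.Machine$integer.max, 2), spec)
    },
    zero_continuum = purrr::map_dfr(seq_along(spec$counts[spec$counts > 0]),
      function(tr) {
        n <- sort(spec$counts[spec$counts > 0])[tr]
        roles <- if (more) c("incorrect", "correct") else c("correct", "incorrect")
        pair_rows(tr, c(0, n), rep(spec$test_shape, 2), roles,
                  sample.int(.Machine$integer.max, 2), spec)
      }),
    equal_incongruent = {
      pair <- generate_cue_biased_pair(spec$counts[1], spec$target_area,
                                       seed = sample.int(.Machine$integer.max, 1),
                                       shape_kind = spec$test_shape,
                                       width = spec$width, height = spec$height)
      tibble(trial = 1L, role = c("cue_high", "cue_low"),
             n_elements = spec$counts[1], shape_kind = spec$test_shape,
             cue_bias = c("high", "low"), seed = NA_integer_,
             image = list(pair$high, pair$low))
    },
    incongruent_opposite = {
      # higher-count member carries the LOWER cues; verified by measurement
      hi_n <- spec$counts[1]
      lo_n <- spec$counts[2]
      for (att in 1:50) {
        s1 <- sample.int(.Machine$integer.max, 1)
        s2 <- sample.int(.Machine$integer.max, 1)
        img_low <- generate_stimulus(hi_n, spec$test_shape, spec$target_area,
                                     seed = s1, width = spec$width,
                                     height = spec$height, cue_bias = "low")
        img_high <- generate_stimulus(lo_n, spec$test_shape, spec$target_area,
                                      seed = s2, width = spec$width,
                                      height = spec$height, cue_bias = "high")
        ch <- cue_vector(img_high)
        cl <- cue_vector(img_low)
        if (ch$edge_length > cl$edge_length &&
            ch$convex_hull_area > cl$convex_hull_area &&
            ch$sf_power > cl$sf_power) break
        if (att == 50) abort("could not oppose cues to numerosity",
                             class = "magbee_generation_error")
      }
      tibble(trial = 1L, role = c("cue_low", "cue_high"),
             n_elements = c(hi_n, lo_n), shape_kind = spec$test_shape,
             cue_bias = c("low", "high"), seed = c(s1, s2),
             image = list(img_low, img_high))
    }
  )
  dplyr::bind_cols(
    tibble(stimulus_id = sprintf("%s_%03d", spec$set_kind, seq_len(nrow(res))),
           set_kind = spec$set_kind, rule = spec$rule),
    res
  )
}

#' Build a cue-measured stimulus library
#'
#' Generates `n_per_cell` displays for every combination of element count
#' and shape, measures their cues, and returns the flat exemplar table used
#' by the experiment pipeline (training streams and tests sample from it).
#'
#' @param counts element counts to cover (0 is the empty display).
#' @param shapes shape kinds to cover.
#' @param n_per_cell exemplars per count x shape cell.
#' @param target_area,width,height display geometry.
#' @param seed master seed.
#' @return Tibble with `n_elements`, `shape_kind`, `exemplar`, `seed`,
#'   `image` and the measured cue columns.
#' @export
build_stimulus_library <- function(counts = 0:6,
                                   shapes = c("square", "diamond", "circle"),
                                   n_per_cell = 12, target_area = 1024,
                                   width = 120, height = 120, seed = 1) {
  withr::local_seed(seed)
  grid <- tidyr::expand_grid(
    n_elements = counts, shape_kind = shapes, exemplar = seq_len(n_per_cell)
  )
  grid$seed <- sample.int(.Machine$integer.max, nrow(grid))
  grid$image <- purrr::pmap(
    list(grid$n_elements, grid$shape_kind, grid$seed),
    function(n, sh, sd) {
      generate_stimulus(n, sh, target_area, seed = sd,
                        width = width, height = height)
    }
  )
  measure_cues(grid)
}

#' Write and read stimulus sets on disk
#'
#' `write_stimulus_set()` writes each display as a 1-bit-content grayscale
#' PNG plus a CSV manifest and a JSON metadata file (spec echo, seeds,
#' element records). `read_stimulus_image()` reads one PNG back into a 0/1
#' matrix.
#'
#' @param data a stimulus tibble from [build_stimulus_set()].
#' @param dir output directory (created if missing).
#' @return `write_stimulus_set()`: the manifest tibble, invisibly.
#' @export
write_stimulus_set <- function(data, dir) {
  stopifnot(is.data.frame(data), "image" %in% names(data))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s.png", data$stimulus_id)
  for (i in seq_len(nrow(data))) {
    png::writePNG(1 - data$image[[i]]$pixels, file.path(dir, files[i]))
  }
  manifest <- dplyr::select(data, -"image") |>
    dplyr::mutate(filename = files, .before = 1)
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  meta <- purrr::map2(data$image, files, function(img, f) {
    list(filename = f, n_elements = img$n_elements,
         shape_kind = img$shape_kind, seed = img$seed,
         cue_bias = img$cue_bias, width = img$width, height = img$height,
         pixel_coordinates = "0-based, row-major, origin top-left",
         elements = img$elements)
  })
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' @rdname write_stimulus_set
#' @param path PNG file path.
#' @return `read_stimulus_image()`: a 0/1 integer matrix (1 = black).
#' @export
read_stimulus_image <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  matrix(as.integer(m < 0.5), nrow(m), ncol(m))
}
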