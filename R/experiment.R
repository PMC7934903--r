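EXPERIMENTS <- c("novel_shape", "outside_range", "novel_pairs_zero",
                 "zero_continuum", "incongruent")

# test batteries: count pairs per experiment (lo, hi). Training is on
# counts 1-4 except novel_pairs_zero, which trains on pairs drawn from the
# whole 0-6 range with the learning-test pair held out.
battery_tests <- function(experiment) {
  switch(experiment,
    novel_shape = tibble(
      test = c("learning", "conflict", "transfer"),
      lo = c(1, 0, 2), hi = c(4, 3, 5)
    ),
    outside_range = tibble(
      test = c("learning", "conflict", "transfer"),
      lo = c(4, 0, 5), hi = c(5, 1, 6)
    ),
    novel_pairs_zero = tibble(
      test = c("learning", "conflict"),
      lo = c(1, 0), hi = c(4, 3)
    ),
    zero_continuum = tibble(
      test = sprintf("zero_vs_%d", 1:6),
      lo = 0, hi = 1:6
    ),
    incongruent = tibble(
      test = c("equal_incongruent", "incongruent_opposite", "equal_control"),
      lo = NA_real_, hi = NA_real_
    )
  )
}

#' Configure a model-bee experiment
#'
#' One experiment trains a population of independently seeded model bees on
#' a count discrimination rule and runs a battery of two-alternative tests,
#' mirroring the behavioural designs of the honeybee paradigm:
#'
#' * `novel_shape`: train on counts 1-4 (squares and diamonds), test with
#'   the held-out shape: learning 1 v 4, conflict 0 v 3, transfer 2 v 5.
#' * `outside_range`: train on 1-4; tests probe beyond the trained range:
#'   learning 4 v 5, conflict 0 v 1, transfer 5 v 6.
#' * `novel_pairs_zero`: train on pairs drawn from 0-6 (zero included) with
#'   the pair 1 v 4 held out; learning test 1 v 4, conflict 0 v 3.
#' * `zero_continuum`: train on 1-4; test 0 v n for n = 1..6.
#' * `incongruent`: train on 1-4; test cue-biased displays at equal count
#'   (2 high vs 2 low), with cues opposing numerosity (2 high vs 3 low),
#'   and an unbiased equal-count control.
#'
#' @param experiment battery name (see above).
#' @param rules rule groups to simulate, subset of `c("more_than",
#'   "less_than")`.
#' @param n_bees model bees per rule group.
#' @param training_counts counts used in training (ignored by
#'   `novel_pairs_zero`, which uses 0-6).
#' @param n_test_repeats noisy evaluations per test pair and bee.
#' @param n_exemplars stimulus exemplars generated per count x shape cell.
#' @param eta,sigma_N,w_init_max model-bee parameters (see [bee_model()],
#'   [tuning_params()]).
#' @param target_area,width display geometry (px).
#' @param max_trials,window,prop,min_choices training-to-criterion settings
#'   (see [train_bee()]).
#' @param noise simulate rate noise (switch off only for diagnostics).
#' @param seed master seed; every stimulus, bee and test derives from it.
#' @return Object of class `magbee_config`.
#' @export
experiment_config <- function(experiment = "novel_shape",
                              rules = c("more_than", "less_than"),
                              n_bees = 50, training_counts = 1:4,
                              n_test_repeats = 100, n_exemplars = 30,
                              eta = 1e-3, sigma_N = 10, w_init_max = 0.01,
                              target_area = 1024, width = 120,
                              max_trials = 500, window = 10, prop = 0.8,
                              min_choices = 20, noise = TRUE, seed = 1) {
  experiment <- match.arg(experiment, EXPERIMENTS)
  rules <- match.arg(rules, c("more_than", "less_than"), several.ok = TRUE)
  stopifnot(n_bees >= 1, n_test_repeats >= 1,
            all(training_counts >= 0 & training_counts <= 6))
  structure(
    list(experiment = experiment, rules = rules, n_bees = n_bees,
         training_counts = training_counts,
         n_test_repeats = n_test_repeats, n_exemplars = n_exemplars,
         eta = eta, sigma_N = sigma_N, w_init_max = w_init_max,
         target_area = target_area, width = width,
         max_trials = max_trials, window = window, prop = prop,
         min_choices = min_choices, noise = noise, seed = as.integer(seed),
         tests = battery_tests(experiment),
         training_shapes = c("square", "diamond"), test_shape = "circle"),
    class = "magbee_config"
  )
}

# counts + pairs the experiment trains on
training_design <- function(config) {
  if (config$experiment == "novel_pairs_zero") {
    counts <- 0:6
    cmb <- utils::combn(counts, 2)
    pairs <- tibble(lo = cmb[1, ], hi = cmb[2, ])
    # hold out the learning-test pair so it is novel at test time
    pairs <- dplyr::filter(pairs, !(.data$lo == 1 & .data$hi == 4))
  } else {
    counts <- config$training_counts
    cmb <- utils::combn(sort(unique(counts)), 2)
    pairs <- tibble(lo = cmb[1, ], hi = cmb[2, ])
  }
  list(counts = counts, pairs = pairs)
}

# build the stimulus exemplars an experiment needs, cue-measured; for the
# incongruent battery this includes the cue-biased displays
build_experiment_library <- function(config) {
  des <- training_design(config)
  test_counts <- unique(stats::na.omit(c(config$tests$lo, config$tests$hi)))
  lib_train <- build_stimulus_library(
    counts = sort(unique(des$counts)),
    shapes = config$training_shapes,
    n_per_cell = config$n_exemplars,
    target_area = config$target_area, width = config$width,
    height = config$width,
    seed = sample.int(.Machine$integer.max, 1)
  )
  lib_train$pool <- "training"
  out <- lib_train
  if (length(test_counts) > 0) {
    lib_test <- build_stimulus_library(
      counts = sort(test_counts),
      shapes = config$test_shape,
      n_per_cell = config$n_exemplars,
      target_area = config$target_area, width = config$width,
      height = config$width,
      seed = sample.int(.Machine$integer.max, 1)
    )
    lib_test$pool <- "test"
    out <- dplyr::bind_rows(out, lib_test)
  }
  if (config$experiment == "incongruent") {
    biased <- purrr::map_dfr(seq_len(max(4, ceiling(config$n_exemplars / 3))),
      function(i) {
        # a fresh high/low pair per outer round: some high-pair draws have
        # too little edge length to dominate any 3-element comparator
        low3 <- NULL
        for (round in 1:20) {
          pr <- generate_cue_biased_pair(2, config$target_area,
                                         seed = sample.int(.Machine$integer.max, 1),
                                         shape_kind = config$test_shape,
                                         width = config$width, height = config$width)
          ch <- cue_vector(pr$high)
          for (att in 1:10) {
            cand <- generate_stimulus(3, config$test_shape, config$target_area,
                                      seed = sample.int(.Machine$integer.max, 1),
                                      width = config$width, height = config$width,
                                      cue_bias = "low")
            cc <- cue_vector(cand)
            if (ch$edge_length > cc$edge_length &&
                ch$convex_hull_area > cc$convex_hull_area &&
                ch$sf_power > cc$sf_power) {
              low3 <- cand
              break
            }
          }
          if (!is.null(low3)) break
        }
        if (is.null(low3)) {
          abort("could not oppose cues to numerosity",
                class = "magbee_generation_error")
        }
        tibble(
          n_elements = c(2L, 2L, 3L), shape_kind = config$test_shape,
          exemplar = i, seed = NA_integer_,
          image = list(pr$high, pr$low, low3),
          pool = c("cue_high_2", "cue_low_2", "cue_low_3")
        )
      })
    biased <- measure_cues(biased)
    out <- dplyr::bind_rows(out, biased)
  }
  out
}

# sample one exemplar s-value per requested count from a cue-measured pool
sample_s <- function(pool, count) {
  v <- pool$s_input[pool$n_elements == count]
  if (length(v) == 0) abort(sprintf("no exemplar with %d elements", count))
  v[sample.int(length(v), 1)]
}

#' Run one model bee through an experiment
#'
#' Trains a single seeded model bee to criterion on the experiment's
#' training design (fresh exemplar draws every trial) and runs every test
#' of the battery, scoring each test as the fraction of noisy repeats in
#' which the bee chose the display its rule designates as correct (for the
#' cue-biased tests: the display its learned cue preference predicts).
#'
#' @param config a [experiment_config()].
#' @param rule this bee's trained rule.
#' @param bee_seed integer seed; the bee's weights, training stream and
#'   test noise all derive from it.
#' @param library cue-measured exemplar table from the internal experiment
#'   library builder (with `s_input` already calibrated).
#' @param calibration the frozen [calibrate_s_mapping()] of the experiment.
#' @return Tibble: one row per test with the oriented `choice_fraction`,
#'   `mean_diff`, convergence info and the seeds used.
#' @export
run_model_bee <- function(config, rule, bee_seed, library, calibration) {
  withr::local_seed(bee_seed)
  des <- training_design(config)
  train_pool <- dplyr::filter(library, .data$pool == "training")
  model <- bee_model(
    eta = config$eta,
    tuning = tuning_params(sigma_N = config$sigma_N),
    w_init_max = config$w_init_max
  )
  model <- train_bee(model, train_pool, rule = rule, pairs = des$pairs,
                     noise = config$noise, window = config$window,
                     prop = config$prop, min_choices = config$min_choices,
                     max_trials = config$max_trials)
  tests <- config$tests
  purrr::map_dfr(seq_len(nrow(tests)), function(i) {
    tst <- tests$test[i]
    if (config$experiment == "incongruent") {
      sides <- switch(tst,
        equal_incongruent = c("cue_high_2", "cue_low_2"),
        incongruent_opposite = c("cue_high_2", "cue_low_3"),
        equal_control = c("cue_low_2", "cue_low_2")
      )
      s_hi_cue <- sample_s(dplyr::filter(library, .data$pool == sides[1]),
                           if (sides[1] == "cue_low_3") 3L else 2L)
      s_lo_cue <- sample_s(dplyr::filter(library, .data$pool == sides[2]),
                           if (sides[2] == "cue_low_3") 3L else 2L)
      # orient by the learned cue preference: more_than bees should follow
      # the higher-cue display, less_than bees the lower-cue one
      if (rule == "more_than") {
        s_A <- s_hi_cue
        s_B <- s_lo_cue
      } else {
        s_A <- s_lo_cue
        s_B <- s_hi_cue
      }
      pair_label <- tst
    } else {
      test_pool <- dplyr::filter(library, .data$pool == "test")
      s_lo <- sample_s(test_pool, tests$lo[i])
      s_hi <- sample_s(test_pool, tests$hi[i])
      if (rule == "more_than") {
        s_A <- s_hi
        s_B <- s_lo
      } else {
        s_A <- s_lo
        s_B <- s_hi
      }
      pair_label <- sprintf("%d_vs_%d", tests$lo[i], tests$hi[i])
    }
    pref <- test_preference(model, s_A, s_B, n_repeats = config$n_test_repeats,
                            noise = config$noise)
    tibble(
      experiment = config$experiment, rule = rule, bee_seed = bee_seed,
      test = tst, pair = pair_label,
      choice_fraction = pref$choice_fraction, mean_diff = pref$mean_diff,
      converged = model$converged,
      trials = model$trial_index
    )
  })
}

#' Run a population of model bees
#'
#' Builds the experiment's stimulus library, freezes the
#' spatial-frequency-to-s calibration on the training stimuli, trains
#' `n_bees` independently seeded model bees per rule group, runs the test
#' battery on each, and summarises every test with the Wilcoxon
#' signed-rank z of the per-bee choice fractions against chance (per rule
#' and pooled across rules). For the zero-continuum battery a
#' Kruskal-Wallis test across the six pair distances is added.
#'
#' @param config a [experiment_config()].
#' @return Object of class `bee_experiment`: `config`, `scores` (per bee x
#'   test), `summary` (statistics table), `calibration`, `cues` (library
#'   cue table without images), `valid` (at least 80% of bees converged).
#' @export
run_population <- function(config) {
  stopifnot(inherits(config, "magbee_config"))
  withr::local_seed(config$seed)
  library <- build_experiment_library(config)
  train_rows <- library$pool == "training" & library$n_elements >= 1
  calibration <- calibrate_s_mapping(library[train_rows, ])
  library$s_input <- s_input(calibration, library$sf_power)
  bee_seeds <- matrix(
    sample.int(.Machine$integer.max, config$n_bees * length(config$rules)),
    nrow = config$n_bees
  )
  scores <- purrr::imap_dfr(config$rules, function(rule, ri) {
    purrr::map_dfr(seq_len(config$n_bees), function(b) {
      run_model_bee(config, rule, bee_seeds[b, ri], library, calibration)
    })
  })
  conv <- scores |>
    dplyr::distinct(.data$rule, .data$bee_seed, .data$converged)
  prop_conv <- mean(conv$converged)
  valid <- prop_conv >= 0.8
  if (!valid) {
    warn(sprintf("only %.0f%% of model bees reached criterion; run flagged invalid",
                 100 * prop_conv))
  }
  structure(
    list(config = config, scores = scores,
         summary = summarize_experiment(scores),
         calibration = calibration,
         cues = dplyr::select(library, -"image"),
         prop_converged = prop_conv, valid = valid),
    class = "bee_experiment"
  )
}

#' Run the cue-conflict battery
#'
#' Convenience wrapper: [run_population()] with the `incongruent`
#' experiment, testing trained model bees on equal-count cue-biased pairs
#' and on pairs where cues oppose numerosity.
#'
#' @param config a [experiment_config()]; its `experiment` field is set to
#'   `"incongruent"`.
#' @return A `bee_experiment` object.
#' @export
incongruent_battery <- function(config) {
  config$experiment <- "incongruent"
  config$tests <- battery_tests("incongruent")
  run_population(config)
}

#' Summarise per-bee scores into the statistics table
#'
#' One row per (rule, test) plus a pooled row per test: mean preference,
#' s.e.m., and the Wilcoxon signed-rank z of the per-bee choice fractions
#' against 0.5. Zero-continuum scores additionally get a Kruskal-Wallis
#' test across the six pair distances.
#'
#' @param scores tibble from [run_model_bee()]/[run_population()].
#' @return Summary tibble.
#' @export
summarize_experiment <- function(scores) {
  stopifnot(all(c("rule", "test", "pair", "choice_fraction") %in% names(scores)))
  groups <- dplyr::bind_rows(
    scores |> dplyr::mutate(group = .data$rule),
    if (length(unique(scores$rule)) > 1) {
      scores |> dplyr::mutate(group = "pooled")
    }
  )
  out <- groups |>
    dplyr::group_by(.data$experiment, .data$group, .data$test, .data$pair) |>
    dplyr::group_modify(function(d, key) {
      wt <- wilcoxon_signed_rank(d$choice_fraction - 0.5)
      small <- nrow(d) < 10
      tibble(
        n = nrow(d),
        mean_pref = mean(d$choice_fraction),
        sem = stats::sd(d$choice_fraction) / sqrt(nrow(d)),
        mean_decision_diff = mean(d$mean_diff),
        statistic_name = wt$statistic_name,
        statistic = if (small) NA_real_ else wt$statistic,
        p = if (small) NA_real_ else wt$p,
        note = if (small) "n too small for the normal approximation" else wt$note
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::rename(rule = "group")
  if (any(grepl("^zero_vs_", scores$test))) {
    kw <- scores |>
      dplyr::filter(grepl("^zero_vs_", .data$test)) |>
      dplyr::group_by(.data$experiment, rule = .data$rule) |>
      dplyr::group_modify(function(d, key) {
        res <- kruskal_wallis(split(d$choice_fraction, d$test))
        tibble(test = "distance_effect", pair = "0_vs_1..6",
               n = res$n, mean_pref = NA_real_, sem = NA_real_,
               mean_decision_diff = NA_real_,
               statistic_name = res$statistic_name,
               statistic = res$statistic, p = res$p, note = res$note)
      }) |>
      dplyr::ungroup()
    out <- dplyr::bind_rows(out, kw)
  }
  out
}

#' @export
print.bee_experiment <- function(x, ...) {
  cat(sprintf(
    "<bee_experiment> %s: %d bee(s) x %s rule(s), %.0f%% converged%s\n",
    x$config$experiment, x$config$n_bees,
    paste(x$config$rules, collapse = "+"),
    100 * x$prop_converged, if (x$valid) "" else " [INVALID]"
  ))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Tidy / glance methods for experiments
#'
#' `tidy()` returns the per-bee, per-test scores; `glance()` a one-row run
#' summary.
#'
#' @param x a `bee_experiment`.
#' @param ... unused.
#' @method tidy bee_experiment
#' @export
tidy.bee_experiment <- function(x, ...) x$scores

#' @rdname tidy.bee_experiment
#' @method glance bee_experiment
#' @export
glance.bee_experiment <- function(x, ...) {
  tibble(
    experiment = x$config$experiment,
    n_bees = x$config$n_bees,
    rules = paste(x$config$rules, collapse = "+"),
    prop_converged = x$prop_converged,
    valid = x$valid,
    seed = x$config$seed
  )
}

#' Export experiment results
#'
#' Writes `results.csv` (per-bee scores), `summary.csv` (statistics table)
#' and `config.json` (configuration echo) into a directory.
#'
#' @param x a `bee_experiment`.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_experiment_result <- function(x, dir) {
  stopifnot(inherits(x, "bee_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x$scores, file.path(dir, "results.csv"))
  readr::write_csv(x$summary, file.path(dir, "summary.csv"))
  cfg <- x$config
  cfg$tests <- NULL
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
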