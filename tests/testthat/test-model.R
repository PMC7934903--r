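test_that("tuning curves match the printed constants", {
  tp <- tuning_params()
  # peak response at the preferred value: R0 + RMax
  expect_equal(tuning_response(4, tp, neuron = 5), 250)
  # far from every preferred value: baseline R0
  expect_equal(tuning_response(1e3, tp, neuron = 1), 50)
  # printed formula at s = 3 for the f = 4 neuron
  expect_equal(tuning_response(3, tp, neuron = 5), 50 + 200 * exp(-1 / 12.5),
               tolerance = 1e-10)
  # noise-free bounds across the axis
  g <- vapply(seq(0, 6, by = 0.1), tuning_response, numeric(7), tuning = tp)
  expect_true(all(g >= 50 & g <= 250))
})

test_that("the logistic activation and its derivative agree", {
  dp <- decision_params()
  expect_equal(activation(50, dp), 50)
  expect_equal(activation_derivative(50, dp), 1.25)
  # within the responsive range; in the saturated tails the finite
  # difference itself loses all precision to cancellation
  xs <- seq(-100, 200, by = 3)
  h <- 1e-4
  fd <- (activation(xs + h, dp) - activation(xs - h, dp)) / (2 * h)
  expect_lt(max(abs(fd - activation_derivative(xs, dp)) / abs(fd)), 1e-6)
})

test_that("decision responses stay in (0, A0) and hit printed values", {
  model <- bee_model(seed = 1)
  model$W <- rep(0, 7)
  expect_equal(decision_response(model, 3), 100 / (1 + exp(2.5)),
               tolerance = 1e-10)
  set.seed(2)
  for (i in 1:25) {
    model$W <- runif(7, -0.3, 0.3) # keeps the readout off the float-saturated tails
    d <- decision_response(model, runif(1, 0, 6))
    expect_gt(d, 0)
    expect_lt(d, 100)
  }
})

test_that("analytic weight gradient equals the finite-difference gradient", {
  set.seed(7)
  h <- 1e-4
  for (i in 1:100) {
    model <- bee_model(seed = i)
    model$W <- runif(7, -0.05, 0.05) # responsive (non-saturated) regime
    s_p <- runif(1, 0, 6)
    s_n <- runif(1, 0, 6)
    ana <- decision_gradient(model, s_p, s_n)
    num <- vapply(1:7, function(k) {
      up <- model
      up$W[k] <- up$W[k] + h
      dn <- model
      dn$W[k] <- dn$W[k] - h
      ((decision_response(up, s_p) - decision_response(up, s_n)) -
         (decision_response(dn, s_p) - decision_response(dn, s_n))) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(ana - num)) / max(abs(num)), 1e-5)
  }
})

test_that("updates are gated by reinforcement and ascend the objective", {
  model <- bee_model(seed = 3)
  same <- update_weights(model, 4, 2, r = 0)
  expect_identical(same$W, model$W)

  # single small-step update cannot decrease the decision difference
  before <- decision_response(model, 4) - decision_response(model, 2)
  stepped <- update_weights(model, 4, 2, r = 1)
  after <- decision_response(stepped, 4) - decision_response(stepped, 2)
  expect_gte(after, before)

  # objective is zero when nothing is reinforced or nothing differs
  trials <- tibble::tibble(s_p = c(4, 5), s_n = c(2, 1), r = 0)
  expect_equal(objective(model, trials), 0)
  trials2 <- tibble::tibble(s_p = c(3, 3), s_n = c(3, 3), r = 1)
  expect_equal(objective(model, trials2), 0)

  # 100 noise-free ascent steps on a fixed trial set do not lower L
  m <- bee_model(seed = 4)
  fixed <- tibble::tibble(s_p = c(4, 3, 4), s_n = c(1, 2, 2), r = 1)
  l0 <- objective(m, fixed)
  for (i in 1:100) {
    j <- (i %% 3) + 1
    m <- update_weights(m, fixed$s_p[j], fixed$s_n[j], r = 1)
  }
  expect_gte(objective(m, fixed), l0)
})

test_that("training reaches criterion and is reproducible", {
  pool <- tibble::tibble(n_elements = rep(1:4, each = 2),
                         s_input = rep(1:4, each = 2) + rep(c(-0.05, 0.05), 4))

  # noise-free, well-separated inputs: criterion with perfect closing window
  quiet <- bee_model(seed = 5, tuning = tuning_params(sigma_N = 0))
  quiet <- train_bee(quiet, pool, "more_than", noise = FALSE, seed = 50)
  expect_true(quiet$converged)
  expect_equal(mean(utils::tail(quiet$log$correct, 10)), 1)

  a <- train_bee(bee_model(seed = 6), pool, "more_than", seed = 60)
  b <- train_bee(bee_model(seed = 6), pool, "more_than", seed = 60)
  expect_identical(a$log, b$log)
  expect_identical(a$W, b$W)

  # with default noise, nearly all seeded bees reach criterion quickly
  conv <- vapply(1:50, function(i) {
    m <- train_bee(bee_model(seed = 600 + i), pool, "more_than", seed = 700 + i)
    m$converged
  }, logical(1))
  expect_gte(mean(conv), 0.9)
})

test_that("test preferences are symmetric, antisymmetric and bounded", {
  model <- train_bee(bee_model(seed = 8),
                     tibble::tibble(n_elements = 1:4, s_input = 1:4),
                     "more_than", seed = 80)

  same <- withr::with_seed(81, test_preference(model, 3, 3, n_repeats = 400))
  expect_lt(abs(same$mean_diff), 3)
  expect_lt(abs(same$choice_fraction - 0.5), 0.1)

  fwd <- withr::with_seed(82, test_preference(model, 4, 1, n_repeats = 100))
  rev <- withr::with_seed(82, test_preference(model, 1, 4, n_repeats = 100))
  expect_equal(fwd$mean_diff, -rev$mean_diff)
  expect_gt(fwd$choice_fraction, 0.5)

  expect_error(test_preference(model, 1, 2, n_repeats = 0), "n_repeats")
})

test_that("tidy and glance expose the fitted state", {
  model <- train_bee(bee_model(seed = 9),
                     tibble::tibble(n_elements = 1:4, s_input = 1:4),
                     "more_than", seed = 90)
  td <- tidy(model)
  expect_equal(nrow(td), 7)
  expect_equal(td$preferred, 0:6)
  gl <- glance(model)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
  expect_equal(gl$trials, model$trial_index)
})
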