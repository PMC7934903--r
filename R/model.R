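#' Tuning-curve parameters of the sensory layer
#'
#' Seven sensory neurons encode the scalar magnitude input `s` with fixed
#' Gaussian tuning curves: `g_i(s) = R0 + RMax * exp(-(s - f_i)^2 / (2
#' sigma^2)) + N(0, sigma_N)`. Preferred values `f_i` span the input axis
#' from zero to six.
#'
#' @param R0 spontaneous firing rate (spike/s).
#' @param RMax maximum evoked rate above baseline (spike/s).
#' @param sigma tuning width on the s axis.
#' @param preferred the 7 preferred values (strictly increasing).
#' @param sigma_N s.d. of the additive Gaussian rate noise (spike/s).
#' @return Object of class `tuning_params`.
#' @export
tuning_params <- function(R0 = 50, RMax = 200, sigma = 2.5,
                          preferred = 0:6, sigma_N = 10) {
  stopifnot(R0 >= 0, RMax > 0, sigma > 0, sigma_N >= 0,
            length(preferred) == 7, all(diff(preferred) > 0))
  structure(list(R0 = R0, RMax = RMax, sigma = sigma,
                 preferred = as.numeric(preferred), sigma_N = sigma_N),
            class = "tuning_params")
}

#' Decision-neuron parameters
#'
#' The decision neuron applies a logistic activation `F(x) = A0 / (1 +
#' exp(-a (x - b)))` to the weighted sum of the sensory rates.
#'
#' @param A0 maximum activity (spike/s).
#' @param a input sensitivity.
#' @param b input offset (sets the spontaneous activity).
#' @return Object of class `decision_params`.
#' @export
decision_params <- function(A0 = 100, a = 0.05, b = 50) {
  stopifnot(A0 > 0, a > 0)
  structure(list(A0 = A0, a = a, b = b), class = "decision_params")
}

#' Create a model bee
#'
#' One "model bee" is an instance of the nine-neuron magnitude network:
#' seven Gaussian-tuned sensory neurons, one logistic decision neuron, and
#' a reinforcement signal gating an online gradient rule on the seven
#' synaptic weights. Initial weights are drawn uniformly from
#' `[0, w_init_max]`, a near-zero start that keeps the initial decision
#' response far from saturation.
#'
#' @param seed RNG seed for the initial weights (optional; when `NULL` the
#'   current RNG stream is used).
#' @param eta learning rate of the weight update.
#' @param tuning a [tuning_params()] object.
#' @param decision a [decision_params()] object.
#' @param w_init_max upper bound of the uniform weight initialization.
#' @return Object of class `bee_model`.
#' @export
bee_model <- function(seed = NULL, eta = 1e-3, tuning = tuning_params(),
                      decision = decision_params(), w_init_max = 0.01) {
  stopifnot(eta > 0)
  if (!is.null(seed)) withr::local_seed(seed)
  W <- stats::runif(7, 0, w_init_max)
  structure(
    list(W = W, eta = eta, tuning = tuning, decision = decision,
         seed = seed %||% NA_integer_, trial_index = 0L,
         converged = NA, log = NULL),
    class = "bee_model"
  )
}

#' @export
print.bee_model <- function(x, ...) {
  cat(sprintf(
    "<bee_model> eta=%g sigma_N=%g trials=%d converged=%s\n  W: %s\n",
    x$eta, x$tuning$sigma_N, x$trial_index, as.character(x$converged),
    paste(sprintf("%.3f", x$W), collapse = " ")
  ))
  invisible(x)
}

#' Sensory tuning response
#'
#' Evaluates the Gaussian tuning curves at input `s`, optionally adding
#' fresh Gaussian rate noise. Noise-free responses are bounded in
#' `[R0, R0 + RMax]`.
#'
#' @param s scalar input on the magnitude axis.
#' @param tuning a [tuning_params()] object.
#' @param noise logical; add `N(0, sigma_N)` rate noise.
#' @param neuron optional index 1..7 to return a single neuron's rate.
#' @return Numeric vector of length 7 (or 1 if `neuron` is given), spike/s.
#' @export
tuning_response <- function(s, tuning = tuning_params(), noise = FALSE,
                            neuron = NULL) {
  stopifnot(is.finite(s))
  f <- tuning$preferred
  g <- tuning$R0 + tuning$RMax * exp(-(s - f)^2 / (2 * tuning$sigma^2))
  if (noise && tuning$sigma_N > 0) {
    g <- g + stats::rnorm(length(f), 0, tuning$sigma_N)
  }
  if (!is.null(neuron)) g[neuron] else g
}

#' Logistic activation of the decision neuron and its derivative
#'
#' @param x net input (weighted sum of sensory rates).
#' @param decision a [decision_params()] object.
#' @return `activation()`: response in (0, A0); `activation_derivative()`:
#'   the positive slope `A0 a e^{-a(x-b)} / (1 + e^{-a(x-b)})^2`.
#' @export
activation <- function(x, decision = decision_params()) {
  decision$A0 * stats::plogis(decision$a * (x - decision$b))
}

#' @rdname activation
#' @export
activation_derivative <- function(x, decision = decision_params()) {
  p <- stats::plogis(decision$a * (x - decision$b))
  decision$A0 * decision$a * p * (1 - p)
}

#' Decision-neuron response to a stimulus
#'
#' `D(s) = F(sum_k W_k g_k(s))`, the logistic readout of the weighted
#' sensory population.
#'
#' @param model a [bee_model()].
#' @param s scalar input.
#' @param noise logical; use noisy tuning responses.
#' @param g optional precomputed tuning-response vector (overrides `s`).
#' @return Response in (0, A0), spike/s.
#' @export
decision_response <- function(model, s, noise = FALSE, g = NULL) {
  if (is.null(g)) g <- tuning_response(s, model$tuning, noise = noise)
  activation(sum(model$W * g), model$decision)
}

#' Gradient of the decision difference with respect to the weights
#'
#' The analytic gradient of `D(s_p) - D(s_n)` in each weight:
#' `g_i(s_p) F'(x_p) - g_i(s_n) F'(x_n)` with `x = sum_k W_k g_k`.
#'
#' @inheritParams decision_response
#' @param s_p,s_n inputs of the rewarded and punished displays.
#' @param g_p,g_n optional precomputed tuning vectors (e.g. the noisy draws
#'   of the current trial's forward pass).
#' @return Numeric length-7 gradient.
#' @export
decision_gradient <- function(model, s_p, s_n, g_p = NULL, g_n = NULL) {
  if (is.null(g_p)) g_p <- tuning_response(s_p, model$tuning)
  if (is.null(g_n)) g_n <- tuning_response(s_n, model$tuning)
  x_p <- sum(model$W * g_p)
  x_n <- sum(model$W * g_n)
  g_p * activation_derivative(x_p, model$decision) -
    g_n * activation_derivative(x_n, model$decision)
}

#' One reinforcement-gated weight update
#'
#' Online gradient ascent on the decision difference, gated by the
#' reinforcement signal: `W <- W + eta * d/dW [D(s_p) - D(s_n)] * r`. With
#' `r = 0` the weights are returned unchanged. By default the gradient uses
#' the same tuning-response draws as the trial's forward pass, so pass the
#' noisy `g_p`/`g_n` of the trial when training with noise.
#'
#' @inheritParams decision_gradient
#' @param r reinforcement signal, 0 or 1.
#' @return The updated `bee_model`.
#' @export
update_weights <- function(model, s_p, s_n, r = 1, g_p = NULL, g_n = NULL) {
  stopifnot(r %in% c(0, 1))
  if (r == 0) {
    model$trial_index <- model$trial_index + 1L
    return(model)
  }
  grad <- decision_gradient(model, s_p, s_n, g_p, g_n)
  if (any(!is.finite(grad))) {
    abort("non-finite weight gradient", class = "magbee_numerical_error")
  }
  model$W <- model$W + model$eta * grad * r
  model$trial_index <- model$trial_index + 1L
  model
}

#' Training objective
#'
#' The reinforcement-weighted sum of noise-free decision differences over a
#' trial list: `L = sum_t [D(s_p_t) - D(s_n_t)] r_t`.
#'
#' @param model a [bee_model()].
#' @param trials data frame with columns `s_p`, `s_n` and `r`.
#' @return Scalar objective value.
#' @export
objective <- function(model, trials) {
  stopifnot(all(c("s_p", "s_n", "r") %in% names(trials)))
  sum(vapply(seq_len(nrow(trials)), function(i) {
    (decision_response(model, trials$s_p[i]) -
       decision_response(model, trials$s_n[i])) * trials$r[i]
  }, numeric(1)))
}

#' Train a model bee to criterion
#'
#' Streams two-alternative training trials (fresh stimulus exemplars each
#' trial) and applies the reinforcement-gated update after every choice.
#' A choice is correct when the noisy decision response to the rewarded
#' display exceeds the response to the punished one. Training stops once
#' the running accuracy over the last `window` choices reaches `prop`
#' (default 80% of 10) after a minimum of `min_choices` choices, mirroring
#' the behavioural training-to-criterion protocol, or at `max_trials`.
#'
#' @param model a [bee_model()].
#' @param s_pool data frame of available exemplars: columns `n_elements`
#'   and `s_input`.
#' @param rule `"more_than"` (reward the higher count) or `"less_than"`.
#' @param pairs two-column data frame (`lo`, `hi`) of count pairs to sample
#'   trials from; defaults to all distinct pairs available in `s_pool`.
#' @param noise logical; train with noisy forward passes (the noisy draws
#'   are reused in the gradient).
#' @param window,prop,min_choices criterion: at least `prop` correct over
#'   the last `window` choices, evaluated from choice `min_choices` on.
#' @param max_trials hard trial cap; non-convergence is flagged, the state
#'   still returned.
#' @param seed optional RNG seed for the whole training stream.
#' @return The trained `bee_model`, with `$log` (tibble: trial, s_p, s_n,
#'   correct, D_p, D_n, L), `$converged`, `$trials_to_criterion`.
#' @export
train_bee <- function(model, s_pool, rule = c("more_than", "less_than"),
                      pairs = NULL, noise = TRUE, window = 10, prop = 0.8,
                      min_choices = 20, max_trials = 500, seed = NULL) {
  rule <- match.arg(rule)
  stopifnot(all(c("n_elements", "s_input") %in% names(s_pool)))
  if (!is.null(seed)) withr::local_seed(seed)
  counts <- sort(unique(s_pool$n_elements))
  if (is.null(pairs)) {
    cmb <- utils::combn(counts, 2)
    pairs <- tibble(lo = cmb[1, ], hi = cmb[2, ])
  }
  stopifnot(all(c("lo", "hi") %in% names(pairs)), all(pairs$lo < pairs$hi))
  s_by_count <- split(s_pool$s_input, s_pool$n_elements)
  draw_s <- function(count) {
    v <- s_by_count[[as.character(count)]]
    v[sample.int(length(v), 1)]
  }

  n_pairs <- nrow(pairs)
  log_sp <- log_sn <- log_dp <- log_dn <- log_L <- numeric(max_trials)
  log_correct <- logical(max_trials)
  correct_hist <- integer(max_trials)
  converged <- FALSE
  t_done <- max_trials
  for (t in seq_len(max_trials)) {
    i <- sample.int(n_pairs, 1)
    s_lo <- draw_s(pairs$lo[i])
    s_hi <- draw_s(pairs$hi[i])
    if (rule == "more_than") {
      s_p <- s_hi
      s_n <- s_lo
    } else {
      s_p <- s_lo
      s_n <- s_hi
    }
    g_p <- tuning_response(s_p, model$tuning, noise = noise)
    g_n <- tuning_response(s_n, model$tuning, noise = noise)
    D_p <- activation(sum(model$W * g_p), model$decision)
    D_n <- activation(sum(model$W * g_n), model$decision)
    correct <- if (D_p == D_n) stats::runif(1) < 0.5 else D_p > D_n
    model <- update_weights(model, s_p, s_n, r = 1, g_p = g_p, g_n = g_n)
    log_sp[t] <- s_p
    log_sn[t] <- s_n
    log_dp[t] <- D_p
    log_dn[t] <- D_n
    log_L[t] <- D_p - D_n
    log_correct[t] <- correct
    correct_hist[t] <- as.integer(correct)
    if (t >= min_choices && t >= window &&
        sum(correct_hist[(t - window + 1):t]) >= prop * window) {
      converged <- TRUE
      t_done <- t
      break
    }
  }
  keep <- seq_len(t_done)
  model$log <- tibble(
    trial = keep, s_p = log_sp[keep], s_n = log_sn[keep],
    D_p = log_dp[keep], D_n = log_dn[keep],
    correct = log_correct[keep], L = cumsum(log_L[keep])
  )
  model$converged <- converged
  model$trials_to_criterion <- if (converged) t_done else NA_integer_
  model$trial_index <- as.integer(t_done)
  model
}

#' Test preference of a trained model bee
#'
#' Presents the pair (`s_A`, `s_B`) for `n_repeats` noisy evaluations and
#' returns both the mean decision difference `D(s_A) - D(s_B)` and the
#' fraction of repeats in which `D(s_A) > D(s_B)` (ties split at random) --
#' the per-bee choice fraction fed to the population statistics. Noise
#' draws are assigned to the smaller input first, so swapping the two
#' stimuli exactly negates the mean difference under the same seed.
#'
#' @param model a trained [bee_model()].
#' @param s_A,s_B scalar inputs of the two test displays.
#' @param n_repeats number of noisy evaluations (>= 1).
#' @param noise logical; noise-free evaluation yields a 0/1 choice
#'   fraction.
#' @return List: `mean_diff`, `choice_fraction` (for `s_A`), `n_repeats`.
#' @export
test_preference <- function(model, s_A, s_B, n_repeats = 100, noise = TRUE) {
  if (n_repeats < 1) abort("`n_repeats` must be >= 1")
  tun <- model$tuning
  g_A <- tuning_response(s_A, tun)
  g_B <- tuning_response(s_B, tun)
  sdN <- if (noise) tun$sigma_N else 0
  draw <- function() {
    if (sdN > 0) matrix(stats::rnorm(7 * n_repeats, 0, sdN), 7, n_repeats)
    else matrix(0, 7, n_repeats)
  }
  E1 <- draw()
  E2 <- draw()
  if (s_A <= s_B) {
    GA <- g_A + E1
    GB <- g_B + E2
  } else {
    GB <- g_B + E1
    GA <- g_A + E2
  }
  D_A <- activation(as.vector(model$W %*% GA), model$decision)
  D_B <- activation(as.vector(model$W %*% GB), model$decision)
  ties <- D_A == D_B
  wins <- D_A > D_B
  if (any(ties)) wins[ties] <- stats::runif(sum(ties)) < 0.5
  list(
    mean_diff = mean(D_A - D_B),
    choice_fraction = mean(wins),
    n_repeats = as.integer(n_repeats)
  )
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy a model bee
#'
#' @param x a `bee_model`.
#' @param ... unused.
#' @return Tibble with one row per sensory neuron: `neuron`, `preferred`,
#'   `weight`.
#' @method tidy bee_model
#' @export
tidy.bee_model <- function(x, ...) {
  tibble(neuron = 1:7, preferred = x$tuning$preferred, weight = x$W)
}

#' @rdname tidy.bee_model
#' @return `glance()`: one-row tibble with learning-rate, noise, trial and
#'   convergence summaries.
#' @method glance bee_model
#' @export
glance.bee_model <- function(x, ...) {
  tibble(
    eta = x$eta,
    sigma_N = x$tuning$sigma_N,
    trials = x$trial_index,
    converged = x$converged,
    trials_to_criterion = x$trials_to_criterion %||% NA_integer_,
    final_accuracy = if (!is.null(x$log)) {
      mean(utils::tail(x$log$correct, 10))
    } else {
      NA_real_
    }
  )
}
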