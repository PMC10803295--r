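#' Closed-form DDM choice probability
#'
#' For a drift-diffusion process `dx = mu dt + sigma dW` started at
#' `initial_state` between absorbing bounds at `-bound` and `+bound`, the
#' probability of absorption at the upper (rightward) bound is
#' \deqn{P(B+) = \frac{1 - e^{-2\mu(B+I)/\sigma^2}}{1 - e^{-4\mu B/\sigma^2}},}
#' with the continuous limit \eqn{(B+I)/(2B)} at `mu = 0`. Evaluated
#' stably on both drift signs via `expm1`; the zero-drift limit is used
#' when `|mu * bound / diffusion_var| < 1e-8`.
#'
#' @param drift Drift rate mu (evidence per second); vectorized.
#' @param bound Bound magnitude B > 0.
#' @param diffusion_var Squared diffusion coefficient sigma^2 > 0.
#' @param initial_state Initial accumulator value I with `|I| <= bound`;
#'   vectorized (recycled against `drift`).
#' @return Probability of choosing the option at `+bound`, in `[0, 1]`.
#'   Strictly increasing in both `drift` and `initial_state`.
#' @examples
#' choice_prob_analytic(1, bound = 1, diffusion_var = 1)  # ~0.8808
#' choice_prob_analytic(0, 1, 1, initial_state = 0.5)     # 0.75
#' @export
choice_prob_analytic <- function(drift, bound = 1, diffusion_var = 1,
                                 initial_state = 0) {
  if (bound <= 0) abort("bound must be positive")
  if (diffusion_var <= 0) abort("diffusion_var must be positive")
  if (any(abs(initial_state) > bound)) {
    abort("|initial_state| must not exceed bound")
  }
  k <- drift / diffusion_var
  n <- max(length(drift), length(initial_state))
  mu <- rep_len(drift, n)
  I <- rep_len(initial_state, n)
  k <- rep_len(k, n)
  p <- numeric(n)
  tiny <- abs(k * bound) < 1e-8
  p[tiny] <- (bound + I[tiny]) / (2 * bound)
  pos <- !tiny & k > 0
  # numerator/denominator as expm1 ratios (exponents negative, no overflow)
  p[pos] <- expm1(-2 * k[pos] * (bound + I[pos])) / expm1(-4 * k[pos] * bound)
  neg <- !tiny & k < 0
  # multiply through by exp(4 k B): exponents 2k(B - I) and 4kB are negative
  p[neg] <- (exp(2 * k[neg] * (bound - I[neg])) - exp(4 * k[neg] * bound)) /
    -expm1(4 * k[neg] * bound)
  pmin(pmax(p, 0), 1)
}

#' Psychometric curve implied by a fixed initial state
#'
#' Evaluates the closed-form choice probability over a span of drift rates
#' for a single initial-state value. With `initial_state = 0` the curve is
#' exactly logistic in `drift * bound / diffusion_var`; away from zero it
#' shifts toward the favored bound and, for large offsets, flattens at the
#' inflection point - the mechanism by which pooled history-biased curves
#' acquire apparent lapses.
#'
#' @inheritParams choice_prob_analytic
#' @param drifts Numeric vector of drift rates (ideally symmetric about 0).
#' @return A tibble with columns `drift` and `p_right`.
#' @export
psychometric_from_initial_state <- function(drifts, bound = 1,
                                            diffusion_var = 1,
                                            initial_state = 0) {
  tibble::tibble(
    drift = drifts,
    p_right = choice_prob_analytic(drifts, bound, diffusion_var,
                                   initial_state)
  )
}

#' Simulate a closed-loop session of the analytic DDM
#'
#' Draws a sequence of trials in which the drift rate is sampled uniformly
#' from `drift_levels`, the initial state follows the history filters
#' driven by the agent's own realized choices and outcomes, and the choice
#' is a Bernoulli draw from the closed-form choice probability. The
#' rewarded side is the sign of the drift (random on zero-drift trials).
#'
#' @param n_trials Number of trials.
#' @param history A [history_params()] object.
#' @param bound,diffusion_var DDM parameters.
#' @param drift_levels Drift rates to sample from (symmetric recommended).
#' @param seed Integer seed (local RNG; the global RNG state is preserved).
#' @param start_state A [history_state()].
#' @return A session tibble with columns `trial_index`, `drift`,
#'   `initial_state`, `choice`, `outcome`.
#' @export
simulate_analytic_session <- function(n_trials, history, bound = 1,
                                      diffusion_var = 1,
                                      drift_levels = seq(-3, 3, length.out = 9),
                                      seed = 1,
                                      start_state = history_state()) {
  stopifnot(inherits(history, "history_params"))
  with_local_seed(seed, {
    drifts <- sample(drift_levels, n_trials, replace = TRUE)
    u_choice <- runif(n_trials)
    u_side <- runif(n_trials)
    filt <- start_state$filters
    choice <- character(n_trials)
    outcome <- character(n_trials)
    I <- numeric(n_trials)
    for (n in seq_len(n_trials)) {
      I[n] <- sum(filt)
      Iclip <- max(min(I[n], bound), -bound)
      p <- choice_prob_analytic(drifts[n], bound, diffusion_var, Iclip)
      choice[n] <- if (u_choice[n] < p) "R" else "L"
      side <- if (drifts[n] > 0) "R" else if (drifts[n] < 0) "L" else
        (if (u_side[n] < 0.5) "R" else "L")
      outcome[n] <- if (choice[n] == side) "win" else "loss"
      pair <- paste0(choice[n], if (outcome[n] == "win") "w" else "l")
      filt <- history$beta * filt
      filt[pair] <- filt[pair] + history$eta[pair]
    }
    tibble::tibble(trial_index = seq_len(n_trials), drift = drifts,
                   initial_state = I, choice = choice, outcome = outcome)
  })
}

#' Pooled and history-conditioned psychometric curves of the analytic model
#'
#' Simulates a closed-loop analytic-DDM session, fits the 4-parameter
#' logistic to the pooled choices, and refits conditioned on the previous
#' trial being a rightward or leftward win. With no history updates the
#' pooled curve is lapse-free; growing update magnitudes inflate the fitted
#' lapse rates (apparent lapses) and separate the conditioned curves in
#' both threshold and asymptote.
#'
#' @inheritParams simulate_analytic_session
#' @return An object of class `pooled_psychometric`: a list with the
#'   simulated `session`, `fit_pooled`, `fit_prev_rw`, `fit_prev_lw`
#'   ([fit_psychometric()] objects; the conditioned fits are `NULL` when a
#'   condition has too few distinct stimuli), and `modulation`
#'   ([modulation_metrics()] of the conditioned fits).
#' @export
pooled_psychometric <- function(history, bound = 1, diffusion_var = 1,
                                drift_levels = seq(-3, 3, length.out = 9),
                                n_trials = 10000, seed = 1,
                                start_state = history_state()) {
  ses <- simulate_analytic_session(n_trials, history, bound, diffusion_var,
                                   drift_levels, seed, start_state)
  y <- ses$choice == "R"
  fit_pooled <- fit_psychometric(ses$drift, y)
  prev <- paste0(dplyr::lag(ses$choice), ifelse(dplyr::lag(ses$outcome) == "win",
                                                "w", "l"))
  safe_fit <- function(idx) {
    if (length(unique(ses$drift[idx])) < 4) return(NULL)
    fit_psychometric(ses$drift[idx], y[idx])
  }
  fit_rw <- safe_fit(which(prev == "Rw"))
  fit_lw <- safe_fit(which(prev == "Lw"))
  mod <- if (!is.null(fit_rw) && !is.null(fit_lw)) {
    modulation_metrics(fit_rw$params, fit_lw$params)
  } else NULL
  structure(list(session = ses, fit_pooled = fit_pooled,
                 fit_prev_rw = fit_rw, fit_prev_lw = fit_lw,
                 modulation = mod),
            class = "pooled_psychometric")
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a sub-seed (< 2^31) deterministically from a base seed and a tag.
derive_seed <- function(seed, tag) {
  h <- if (is.numeric(tag)) as.numeric(tag) %% 2147483647 else
    Reduce(function(a, b) (a * 31 + b) %% 2147483647,
           as.numeric(utf8ToInt(as.character(tag))), 17)
  (as.numeric(seed) * 69069 + h * 104729 + 1) %% 2147483647
}
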