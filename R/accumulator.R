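#' Accumulator model parameters
#'
#' Parameters of the pulsatile-evidence accumulator. Evidence clicks arrive
#' on two sides; each click's magnitude undergoes multiplicative sensory
#' adaptation (strength `phi`, recovery timescale `tau_phi`) and carries
#' multiplicative Gaussian sensory noise with variance `sigma2_s` (per-click
#' noise `xi ~ N(1, sigma2_s)`, so a click of adapted magnitude C delivers
#' mean `C` and variance `C^2 sigma2_s`). Between clicks the accumulator
#' drifts by `lambda * x` per second (leaky if negative, unstable if
#' positive), diffuses with variance `sigma2_a` per second, and freezes once
#' `|x|` reaches the sticky bound `bound`. The terminal value is compared to
#' `bias` to produce a choice (rightward if above). `drift` adds a constant,
#' click-independent drift per second; it is zero for the click task and is
#' provided so the engine can also represent a classical constant-drift DDM.
#'
#' @param lambda Leak/instability rate per second.
#' @param sigma2_a Accumulator diffusion variance per second.
#' @param sigma2_s Per-click sensory noise variance (>= 0).
#' @param bound Absorbing bound magnitude B > 0.
#' @param phi Adaptation strength (> 0; 1 disables adaptation; < 1
#'   depression, > 1 facilitation).
#' @param tau_phi Adaptation recovery time constant (seconds, > 0).
#' @param bias Decision criterion on the terminal accumulator value.
#' @param drift Constant drift per second (default 0).
#' @return An object of class `accumulator_params`.
#' @export
accumulator_params <- function(lambda = 0, sigma2_a = 1, sigma2_s = 1.5,
                               bound = 3, phi = 0.8, tau_phi = 0.05,
                               bias = 0, drift = 0) {
  if (bound <= 0) abort("bound must be positive")
  if (tau_phi <= 0) abort("tau_phi must be positive")
  if (phi <= 0) abort("phi must be positive")
  if (sigma2_a < 0 || sigma2_s < 0) abort("variances must be non-negative")
  structure(list(lambda = lambda, sigma2_a = sigma2_a, sigma2_s = sigma2_s,
                 bound = bound, phi = phi, tau_phi = tau_phi, bias = bias,
                 drift = drift),
            class = "accumulator_params")
}

#' Fokker-Planck grid settings
#'
#' The accumulator density is propagated on `n_bins` interior bins spanning
#' `(-B, B)` (centers symmetric about zero) plus two sticky absorbing states
#' at the bounds, with transition steps of `dt` seconds. Clicks are assigned
#' to the step containing their time. The defaults (201 bins, 2 ms) change
#' single-trial choice probabilities by well under 1e-3 upon refinement;
#' fitting uses a coarser grid (see [fit_mle()]).
#'
#' @param n_bins Odd integer >= 51; number of interior bins.
#' @param dt Transition time step in seconds.
#' @return An object of class `fp_grid`.
#' @export
fp_grid <- function(n_bins = 201, dt = 0.002) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 51 || n_bins %% 2 == 0) abort("n_bins must be odd and >= 51")
  if (dt <= 0) abort("dt must be positive")
  structure(list(n_bins = n_bins, dt = dt), class = "fp_grid")
}

#' Sensory adaptation of click magnitudes
#'
#' Each click multiplies the shared adaptation state C by `phi`; between
#' clicks C relaxes exponentially back to 1 with time constant `tau_phi`
#' (`C(t) = 1 + (C0 - 1) exp(-dt/tau_phi)`). A click's reported magnitude is
#' the value of C just before its own jump (set `jump = "before"` to apply
#' the click's own jump first). The adaptation state starts fully recovered
#' (`C(0) = 1`), so an isolated first click always has magnitude 1, and
#' `phi = 1` leaves every magnitude at 1.
#'
#' @param left_clicks,right_clicks Ascending click times (seconds, >= 0).
#' @param phi Adaptation strength.
#' @param tau_phi Recovery time constant (seconds).
#' @param jump Whether a click's own jump applies `"after"` (default) or
#'   `"before"` its magnitude is read.
#' @return A list with numeric vectors `left` and `right` of per-click
#'   magnitudes (same order as the inputs).
#' @examples
#' adapt_click_magnitudes(c(0, 0.1), numeric(0), phi = 0.5, tau_phi = 0.2)
#' @export
adapt_click_magnitudes <- function(left_clicks, right_clicks, phi, tau_phi,
                                   jump = c("after", "before")) {
  jump <- match.arg(jump)
  if (any(c(left_clicks, right_clicks) < 0)) abort("click times must be >= 0")
  nl <- length(left_clicks)
  nr <- length(right_clicks)
  times <- c(left_clicks, right_clicks)
  ord <- order(times)
  mags <- numeric(nl + nr)
  C <- 1
  t_prev <- 0
  for (i in ord) {
    C <- 1 + (C - 1) * exp(-(times[i] - t_prev) / tau_phi)
    if (jump == "before") C <- phi * C
    mags[i] <- C
    if (jump == "after") C <- phi * C
    t_prev <- times[i]
  }
  list(left = mags[seq_len(nl)],
       right = if (nr > 0) mags[nl + seq_len(nr)] else numeric(0))
}

# Per-trial step inputs for the FP engine: click step indices (1-based),
# per-click mean input (signed adapted magnitude) and variance (C^2 sigma2_s),
# plus the constant-drift contribution folded into every step.
trial_step_inputs <- function(left_clicks, right_clicks, duration, params,
                              grid) {
  n_steps <- max(1L, as.integer(ceiling(duration / grid$dt - 1e-9)))
  mags <- adapt_click_magnitudes(left_clicks, right_clicks, params$phi,
                                 params$tau_phi)
  step_of <- function(t) pmin(pmax(as.integer(ceiling(t / grid$dt - 1e-12)), 1L),
                              n_steps)
  # time order matters: clicks sharing a transition step are applied as
  # sequential kicks with absorption checked in between, but exactly
  # simultaneous clicks act at one instant and are summed into one packet
  times <- c(left_clicks, right_clicks)
  ord <- order(times)
  tkey <- round(times[ord] / 1e-9)
  grp <- cumsum(!duplicated(tkey) | c(TRUE, diff(tkey) != 0))
  mean_all <- c(-mags$left, mags$right)[ord]
  var_all <- (c(mags$left, mags$right)^2 * params$sigma2_s)[ord]
  step_all <- c(step_of(left_clicks), step_of(right_clicks))[ord]
  click_step <- as.integer(tapply(step_all, grp, `[`, 1))
  click_mean <- as.numeric(tapply(mean_all, grp, sum))
  click_var <- as.numeric(tapply(var_all, grp, sum))
  list(n_steps = n_steps, click_step = click_step,
       click_mean = click_mean, click_var = click_var)
}

# Interpolation weights of a delta at I onto the interior centers.
delta_weights <- function(I, n_bins, bound) {
  dx <- 2 * bound / (n_bins + 1)
  w <- numeric(n_bins)
  pos <- (I + bound) / dx - 1
  j0 <- floor(pos)
  f <- pos - j0
  if (j0 < 0) w[1] <- 1
  else if (j0 >= n_bins - 1) w[n_bins] <- 1
  else {
    w[j0 + 1] <- 1 - f
    w[j0 + 2] <- f
  }
  w
}

#' Evolve the accumulator density for one trial
#'
#' Propagates the probability density of the accumulator through a trial's
#' click train, starting from a point mass at `initial_state`, and records
#' the mass absorbed at each bound in every time step. Interior mass plus
#' absorbed mass is conserved to machine precision at every step. If
#' `|initial_state| >= bound` all mass is absorbed at the corresponding
#' bound at time zero (returned, not an error).
#'
#' @param left_clicks,right_clicks Click times (seconds).
#' @param duration Evolution horizon in seconds (the stimulus duration for
#'   fixed-duration trials; for reaction-time use, evolve at least to the
#'   observed reaction time).
#' @param params An [accumulator_params()].
#' @param initial_state Initial accumulator value I(n).
#' @param grid An [fp_grid()].
#' @return An object of class `fp_result`: list with `centers`, final
#'   `interior` mass, per-step absorbed mass `absorbed_lo`/`absorbed_up`,
#'   step-center times `t`, totals `total_lo`/`total_up`, `survivor`
#'   (final interior mass), `dt` and the inputs' `duration`.
#' @export
fokker_planck_evolve <- function(left_clicks, right_clicks, duration, params,
                                 initial_state, grid = fp_grid()) {
  stopifnot(inherits(params, "accumulator_params"), inherits(grid, "fp_grid"))
  steps <- trial_step_inputs(left_clicks, right_clicks, duration, params, grid)
  B <- params$bound
  n <- grid$n_bins
  if (abs(initial_state) >= B) {
    up0 <- as.numeric(initial_state >= B)
    res <- list(interior = rep(0, n),
                absorbed_lo = rep(0, steps$n_steps),
                absorbed_up = rep(0, steps$n_steps),
                total_lo = 1 - up0, total_up = up0,
                centers = fp_centers_cpp(n, B))
    res$absorbed_at_t0 <- TRUE
  } else {
    init <- delta_weights(initial_state, n, B)
    res <- fp_forward_cpp(init, 0, 0, n, B, params$lambda, params$drift,
                          grid$dt, params$sigma2_a, steps$n_steps,
                          steps$click_step, steps$click_mean,
                          steps$click_var)
    res$absorbed_at_t0 <- FALSE
  }
  res$t <- (seq_len(steps$n_steps) - 0.5) * grid$dt
  res$survivor <- sum(res$interior)
  res$dt <- grid$dt
  res$duration <- duration
  class(res) <- "fp_result"
  res
}

#' Choice probability for a fixed-duration trial
#'
#' Integrates the terminal accumulator density above the decision criterion:
#' mass absorbed at the upper bound counts as rightward, mass at the lower
#' bound as leftward, and the interior bin containing the criterion is split
#' linearly. Mass sitting exactly at the criterion contributes 1/2.
#'
#' @inheritParams fokker_planck_evolve
#' @return Probability of a rightward choice, in `[0, 1]`.
#' @export
choice_likelihood <- function(left_clicks, right_clicks, duration, params,
                              initial_state, grid = fp_grid()) {
  fp <- fokker_planck_evolve(left_clicks, right_clicks, duration, params,
                             initial_state, grid)
  prob_right_from_fp(fp, params$bias, params$bound)
}

prob_right_from_fp <- function(fp, bias, bound) {
  p <- 0
  if (bias < bound) p <- p + fp$total_up
  else if (bias == bound) p <- p + 0.5 * fp$total_up
  if (bias < -bound) p <- p + fp$total_lo
  else if (bias == -bound) p <- p + 0.5 * fp$total_lo
  centers <- fp$centers
  n <- length(centers)
  dx <- 2 * bound / (n + 1)
  above <- centers - bias
  w <- as.numeric(above > dx / 2) +
    ifelse(abs(above) <= dx / 2, 0.5 + above / dx, 0)
  w <- pmin(pmax(w, 0), 1)
  p + sum(fp$interior * w)
}

#' First-passage density of the accumulator
#'
#' For reaction-time trials: the probability that the accumulator first
#' reaches the upper or lower bound within each time step, assuming the
#' stimulus continues while the accumulator is unabsorbed. The masses and
#' the survivor (interior mass at the horizon) sum to one.
#'
#' @inheritParams fokker_planck_evolve
#' @param horizon Evolution horizon in seconds.
#' @return A tibble with columns `t` (step centers), `mass_upper`,
#'   `mass_lower`, and attributes `survivor` and `dt`.
#' @export
first_passage_density <- function(left_clicks, right_clicks, horizon, params,
                                  initial_state, grid = fp_grid()) {
  fp <- fokker_planck_evolve(left_clicks, right_clicks, horizon, params,
                             initial_state, grid)
  out <- tibble::tibble(t = fp$t, mass_upper = fp$absorbed_up,
                        mass_lower = fp$absorbed_lo)
  if (fp$absorbed_at_t0) {
    out$mass_upper[1] <- out$mass_upper[1] + fp$total_up
    out$mass_lower[1] <- out$mass_lower[1] + fp$total_lo
  }
  attr(out, "survivor") <- fp$survivor
  attr(out, "dt") <- fp$dt
  out
}

# Batch adjoint pass over trials: likelihood-versus-initial-state curves.
# trials: list of lists with left_clicks, right_clicks, duration, and payoff
# spec built by the caller. Returns list(centers, curves [n_trials x n_bins],
# lo0, up0).
fp_choice_curves <- function(trial_list, params, grid) {
  B <- params$bound
  n <- grid$n_bins
  payload <- lapply(trial_list, function(tr) {
    steps <- tr$steps %||% trial_step_inputs(tr$left_clicks,
                                             tr$right_clicks, tr$duration,
                                             params, grid)
    c(steps, tr$payoff)
  })
  m <- fp_curve_batch_cpp(n, B, params$lambda, params$drift, grid$dt,
                          params$sigma2_a, payload)
  list(centers = fp_centers_cpp(n, B),
       curves = m[, seq_len(n), drop = FALSE],
       lo0 = m[, n + 1], up0 = m[, n + 2])
}

# Terminal payoff vector: indicator(x > bias) with linear split of the
# criterion bin (0.5 at the criterion itself).
terminal_choice_payoff <- function(n_bins, bound, bias) {
  centers <- fp_centers_cpp(n_bins, bound)
  dx <- 2 * bound / (n_bins + 1)
  above <- centers - bias
  w <- as.numeric(above > dx / 2) +
    ifelse(abs(above) <= dx / 2, 0.5 + above / dx, 0)
  pmin(pmax(w, 0), 1)
}

# Interpolate per-trial curves at arbitrary initial states.
interp_curves <- function(curves, centers, lo0, up0, I, bound) {
  n <- length(centers)
  ntr <- nrow(curves)
  I <- rep_len(I, ntr)
  out <- numeric(ntr)
  below <- I <= -bound
  above <- I >= bound
  out[below] <- lo0[below]
  out[above] <- up0[above]
  mid <- !(below | above)
  if (any(mid)) {
    dx <- centers[2] - centers[1]
    pos <- (I[mid] - centers[1]) / dx + 1
    j0 <- pmin(pmax(floor(pos), 1), n - 1)
    f <- pmin(pmax(pos - j0, 0), 1)
    rows <- which(mid)
    out[mid] <- curves[cbind(rows, j0)] * (1 - f) +
      curves[cbind(rows, j0 + 1)] * f
  }
  out
}
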