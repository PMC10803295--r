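#' Non-decision-time parameters
#'
#' Non-decision times (NDTs) are modeled as first-passage times of a
#' side-specific drift-to-bound process, i.e. Wald / Inverse-Gaussian draws
#' with bound `omega_k` and base drift `nu_k` for each response side k. The
#' effective drift declines linearly with trial number (`alpha` per trial,
#' capturing within-session slowing) and increases by `gamma_o` after an
#' error. The NDT for side k on trial n is
#' `IG(mean = omega_k / (nu_k - alpha n + gamma_o 1[prev error]),
#' shape = omega_k^2)`.
#'
#' @param omega_L,omega_R Wald bounds (> 0).
#' @param nu_L,nu_R Base drifts.
#' @param alpha Per-trial drift decrement (>= 0 in practice).
#' @param gamma_o Post-error drift increment.
#' @return An object of class `ndt_params`.
#' @export
ndt_params <- function(omega_L = 2, omega_R = 2, nu_L = 10, nu_R = 10,
                       alpha = 0, gamma_o = 0) {
  if (omega_L <= 0 || omega_R <= 0) abort("omega bounds must be positive")
  structure(list(omega_L = omega_L, omega_R = omega_R, nu_L = nu_L,
                 nu_R = nu_R, alpha = alpha, gamma_o = gamma_o),
            class = "ndt_params")
}

ndt_effective_drift <- function(side, trial_number, prev_error, params) {
  nu <- ifelse(side == "R", params$nu_R, params$nu_L)
  nu - params$alpha * trial_number + params$gamma_o * as.numeric(prev_error)
}

#' Non-decision-time density and sampler
#'
#' Inverse-Gaussian density of the NDT for a given response side, trial
#' number, and previous-trial outcome. The distribution's mean is
#' `omega / effective drift` and its shape `omega^2`.
#'
#' @param t Times in seconds (> 0); vectorized.
#' @param side `"L"` or `"R"`.
#' @param trial_number Trial number n (enters the drift decrement).
#' @param prev_error Logical: was the previous trial an error?
#' @param params An [ndt_params()].
#' @return `ndt_density()`: density values; `ndt_sample()`: `n` draws.
#' @export
ndt_density <- function(t, side, trial_number = 1, prev_error = FALSE,
                        params = ndt_params()) {
  stopifnot(inherits(params, "ndt_params"))
  nu <- ndt_effective_drift(side, trial_number, prev_error, params)
  if (any(nu <= 0)) {
    abort("effective NDT drift must be positive (nu - alpha n + gamma_o)")
  }
  omega <- if (side == "R") params$omega_R else params$omega_L
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- statmod::dinvgauss(t[pos], mean = omega / nu,
                                 shape = omega^2)
  out
}

#' @rdname ndt_density
#' @param n Number of samples.
#' @export
ndt_sample <- function(n, side, trial_number = 1, prev_error = FALSE,
                       params = ndt_params()) {
  nu <- ndt_effective_drift(side, trial_number, prev_error, params)
  if (any(nu <= 0)) {
    abort("effective NDT drift must be positive (nu - alpha n + gamma_o)")
  }
  omega <- if (side == "R") params$omega_R else params$omega_L
  statmod::rinvgauss(n, mean = omega / nu, shape = omega^2)
}

#' Joint likelihood of an observed choice and reaction time
#'
#' The accumulation branch marginalizes over bound-hitting times: the
#' first-passage mass for the observed choice in each time bin up to the
#' observed RT, times the NDT density of the residual `RT - tau`. On
#' true-lapse trials the RT is assumed to arise from the NDT alone, so the
#' lapse branch is the lapse choice probability times the NDT density at
#' the full RT. The two branches mix with weight `kappa`. Accumulator mass
#' still unabsorbed at the horizon contributes nothing (censoring): the
#' joint density then integrates to `(1 - kappa)(1 - survivor) + kappa`
#' over both choices and all RTs.
#'
#' @param left_clicks,right_clicks Click times (seconds) observed up to the
#'   reaction time.
#' @param choice Observed choice, `"L"` or `"R"`.
#' @param rt Observed reaction time (seconds, > 0).
#' @param initial_state Initial accumulator state for the trial.
#' @param acc_params An [accumulator_params()].
#' @param ndt An [ndt_params()].
#' @param lapse A [lapse_params()] (its `kappa` is the mixture weight).
#' @param trial_number,prev_error Modulators of the NDT drift.
#' @param grid An [fp_grid()].
#' @return The joint likelihood density value (per second).
#' @export
joint_choice_rt_likelihood <- function(left_clicks, right_clicks, choice, rt,
                                       initial_state, acc_params, ndt,
                                       lapse, trial_number = 1,
                                       prev_error = FALSE,
                                       grid = fp_grid()) {
  if (rt <= 0) abort("rt must be positive")
  if (!choice %in% c("L", "R")) abort("choice must be 'L' or 'R'")
  fpd <- first_passage_density(left_clicks, right_clicks, rt, acc_params,
                               initial_state, grid)
  mass <- if (choice == "R") fpd$mass_upper else fpd$mass_lower
  g <- ndt_density(rt - fpd$t, choice, trial_number, prev_error, ndt)
  acc_branch <- sum(mass * g)
  p_lapse_r <- true_lapse_prob(lapse, initial_state)
  p_lapse <- if (choice == "R") p_lapse_r else 1 - p_lapse_r
  lapse_branch <- p_lapse * ndt_density(rt, choice, trial_number, prev_error,
                                        ndt)
  (1 - lapse$kappa) * acc_branch + lapse$kappa * lapse_branch
}
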