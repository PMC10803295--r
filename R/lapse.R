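#' True-lapse parameters
#'
#' On a fraction `kappa` of trials the choice arises from a process
#' extraneous to evidence accumulation. Three variants are supported:
#' * `"motor"` (motor error / exploration): rightward with fixed
#'   probability `rho`, independent of everything.
#' * `"inattention"`: the subject deterministically chooses the side
#'   favored by the initial state relative to a criterion `rho` on the
#'   initial-state axis (rightward if `I - rho > 0`, a fair coin at
#'   equality).
#' * `"hybrid"`: rightward with probability `1 / (1 + exp(-m (I - rho)))`,
#'   a sigmoid in the initial state with matching slope `m`; recovers the
#'   motor variant at `m = 0` (with `rho` shifted to the I axis) and the
#'   inattention rule as `m` grows.
#'
#' Note `rho` is a probability for the motor variant but a criterion in
#' initial-state units for the inattention and hybrid variants.
#'
#' @param kappa Mixture fraction in `[0, 1]`.
#' @param rho Lapse bias (probability for `"motor"`, criterion otherwise).
#' @param match_slope Sigmoid slope `m >= 0`; hybrid variant only.
#' @param variant `"motor"`, `"inattention"`, or `"hybrid"`.
#' @return An object of class `lapse_params`.
#' @export
lapse_params <- function(kappa = 0, rho = 0.5, match_slope = NULL,
                         variant = c("motor", "inattention", "hybrid")) {
  variant <- match.arg(variant)
  if (kappa < 0 || kappa > 1) abort("kappa must lie in [0, 1]")
  if (variant == "motor" && (rho < 0 || rho > 1)) {
    abort("motor variant: rho is a probability and must lie in [0, 1]")
  }
  if (variant != "hybrid" && !is.null(match_slope)) {
    abort(paste0("match_slope is only meaningful for the hybrid variant, ",
                 "not ", variant))
  }
  if (variant == "hybrid") {
    if (is.null(match_slope)) abort("hybrid variant requires match_slope")
    if (match_slope < 0) abort("match_slope must be >= 0")
  }
  structure(list(kappa = kappa, rho = rho, match_slope = match_slope,
                 variant = variant),
            class = "lapse_params")
}

#' Rightward probability on a true-lapse trial
#'
#' @param params A [lapse_params()].
#' @param initial_state Initial accumulator state I(n); vectorized. Ignored
#'   by the motor variant.
#' @return Probability of a rightward choice.
#' @examples
#' true_lapse_prob(lapse_params(0.1, rho = 0.7), 0)            # 0.7
#' true_lapse_prob(lapse_params(0.1, 0, variant = "inattention"), c(-1, 0, 1))
#' @export
true_lapse_prob <- function(params, initial_state = 0) {
  stopifnot(inherits(params, "lapse_params"))
  switch(params$variant,
    motor = rep_len(params$rho, length(initial_state)),
    inattention = {
      d <- initial_state - params$rho
      ifelse(d > 0, 1, ifelse(d < 0, 0, 0.5))
    },
    hybrid = stats::plogis(params$match_slope *
                             (initial_state - params$rho))
  )
}

#' Mix accumulator and true-lapse choice probabilities
#'
#' Total rightward probability `(1 - kappa) p_acc + kappa p_lapse`. The
#' mixture compresses the asymptotic choice probabilities into
#' `[kappa * min(p_lapse), 1 - kappa (1 - max(p_lapse))]`: the floor and
#' ceiling that fitted lapse rates of a pure true-lapse model would show.
#'
#' @param p_acc Choice probability from the accumulation process.
#' @param params A [lapse_params()].
#' @param initial_state Initial state, for I-dependent lapse variants.
#' @return Mixed probability of a rightward choice.
#' @export
mixture_choice_prob <- function(p_acc, params, initial_state = 0) {
  if (any(p_acc < 0 | p_acc > 1)) abort("p_acc must lie in [0, 1]")
  (1 - params$kappa) * p_acc +
    params$kappa * true_lapse_prob(params, initial_state)
}
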