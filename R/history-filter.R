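#' History filter parameters
#'
#' The initial accumulator state is an exponentially filtered trace of past
#' choice-outcome pairs. Each pair `h` in {Rw, Lw, Rl, Ll} (right-win,
#' left-win, right-loss, left-loss) has its own filter that decays by
#' `beta[h]` every trial and is incremented by `eta[h]` when `h` was
#' observed on the previous trial; the initial state I(n) is the sum of the
#' four filters. Positive I favors the rightward bound.
#'
#' Three parameterizations are supported:
#' * `"unconstrained"`: all eight parameters free.
#' * `"side_constrained"`: loss updates shared across sides
#'   (`eta[Rl] == eta[Ll]`, `beta[Rl] == beta[Ll]`) and a common win
#'   timescale (`beta[Rw] == beta[Lw]`), leaving 5 free parameters.
#' * `"dbm"`: a single decay and a single increment magnitude, with the
#'   increment's sign set by the side the update favors (the rewarded side:
#'   positive after Rw and Ll, negative after Lw and Rl). This is the
#'   exponential-filter reduction of the Dynamic Belief Model; 2 free
#'   parameters.
#'
#' @param eta Named numeric, increments for `Rw, Lw, Rl, Ll`.
#' @param beta Named numeric in `[0, 1)`, decay factors for the same pairs.
#' @param constraint_mode One of `"unconstrained"`, `"side_constrained"`,
#'   `"dbm"`. The constraints are validated, not silently enforced; use
#'   [dbm_constrain()] to project onto the DBM family.
#' @return An object of class `history_params`.
#' @examples
#' hp <- history_params(
#'   eta = c(Rw = 0.3, Lw = -0.3, Rl = -0.1, Ll = 0.1),
#'   beta = c(Rw = 0.7, Lw = 0.7, Rl = 0.5, Ll = 0.5)
#' )
#' n_free_history_params(hp)
#' @export
history_params <- function(eta = c(Rw = 0, Lw = 0, Rl = 0, Ll = 0),
                           beta = c(Rw = 0, Lw = 0, Rl = 0, Ll = 0),
                           constraint_mode = c("unconstrained",
                                               "side_constrained", "dbm")) {
  constraint_mode <- match.arg(constraint_mode)
  pairs <- c("Rw", "Lw", "Rl", "Ll")
  eta <- unlist(eta)[pairs]
  beta <- unlist(beta)[pairs]
  if (anyNA(eta) || anyNA(beta)) {
    abort("eta and beta must both be named with Rw, Lw, Rl, Ll")
  }
  if (any(beta < 0 | beta >= 1)) abort("beta must lie in [0, 1)")
  tol <- 1e-12
  if (constraint_mode == "side_constrained") {
    ok <- abs(eta["Rl"] - eta["Ll"]) < tol &&
      abs(beta["Rl"] - beta["Ll"]) < tol &&
      abs(beta["Rw"] - beta["Lw"]) < tol
    if (!ok) abort("parameters do not satisfy the side_constrained ties")
  }
  if (constraint_mode == "dbm") {
    sgn <- c(Rw = 1, Lw = -1, Rl = -1, Ll = 1)
    ok <- max(beta) - min(beta) < tol &&
      max(abs(abs(eta) - abs(eta["Rw"]))) < tol &&
      all(eta * sgn >= -tol)
    if (!ok) abort("parameters do not satisfy the dbm ties")
  }
  structure(list(eta = eta, beta = beta, constraint_mode = constraint_mode),
            class = "history_params")
}

#' @rdname history_params
#' @param params A `history_params` object.
#' @export
n_free_history_params <- function(params) {
  switch(params$constraint_mode,
         unconstrained = 8L, side_constrained = 5L, dbm = 2L)
}

#' Project history parameters onto the Dynamic Belief Model family
#'
#' Ties all four decay factors to their mean, and all four increments to a
#' common magnitude (the mean of the absolute increments) with sign set by
#' the side the update favors: updates following right-wins and left-losses
#' push the initial state toward the rightward bound, updates following
#' left-wins and right-losses toward the leftward bound. Idempotent:
#' parameters already in the family are returned unchanged.
#'
#' @param params A [history_params()] object.
#' @return A `history_params` with `constraint_mode = "dbm"`.
#' @export
dbm_constrain <- function(params) {
  stopifnot(inherits(params, "history_params"))
  sgn <- c(Rw = 1, Lw = -1, Rl = -1, Ll = 1)
  beta_bar <- mean(params$beta)
  eta_bar <- mean(abs(params$eta))
  history_params(eta = sgn * eta_bar,
                 beta = setNames(rep(beta_bar, 4), names(sgn)),
                 constraint_mode = "dbm")
}

#' History filter state
#'
#' The four filter values entering a trial, and their sum: the initial
#' accumulator state I(n).
#'
#' @param filters Named numeric, one value per pair `Rw, Lw, Rl, Ll`.
#' @return An object of class `history_state` with elements `filters` and
#'   `initial_state` (`= sum(filters)`).
#' @export
history_state <- function(filters = c(Rw = 0, Lw = 0, Rl = 0, Ll = 0)) {
  pairs <- c("Rw", "Lw", "Rl", "Ll")
  filters <- unlist(filters)[pairs]
  if (anyNA(filters)) abort("filters must be named with Rw, Lw, Rl, Ll")
  structure(list(filters = filters, initial_state = sum(filters)),
            class = "history_state")
}

#' One history-filter update
#'
#' Advances the filter state by one trial: every filter decays by its
#' `beta`, and the filter matching the observed choice-outcome pair gains
#' its `eta`. On violation trials (`observed_pair = "none"`) the default is
#' to freeze the state entirely (no decay, no increment), since violations
#' carry no choice or outcome information; set `violation_mode = "decay"`
#' to let filters decay anyway.
#'
#' @param state A [history_state()].
#' @param observed_pair `"Rw"`, `"Lw"`, `"Rl"`, `"Ll"`, or `"none"`.
#' @param params A [history_params()].
#' @param violation_mode `"freeze"` (default) or `"decay"`.
#' @return The updated `history_state` (the state entering the next trial).
#' @export
update_history <- function(state, observed_pair, params,
                           violation_mode = c("freeze", "decay")) {
  violation_mode <- match.arg(violation_mode)
  stopifnot(inherits(state, "history_state"), inherits(params, "history_params"))
  pairs <- c("Rw", "Lw", "Rl", "Ll")
  if (!observed_pair %in% c(pairs, "none")) {
    abort(paste0("unknown choice-outcome pair: ", observed_pair))
  }
  if (observed_pair == "none" && violation_mode == "freeze") return(state)
  f <- params$beta * state$filters
  if (observed_pair != "none") {
    f[observed_pair] <- f[observed_pair] + params$eta[observed_pair]
  }
  history_state(f)
}

#' Initial-state sequence for a session
#'
#' Computes I(n) for every trial of a session from the realized
#' choice-outcome sequence. `I(1)` equals the start state; each subsequent
#' trial's value follows from the filter recursion applied to the previous
#' trial's pair. Violation trials propagate the state unchanged by default
#' (see [update_history()]).
#'
#' @param tbl Session tibble (ordered by `trial_index`).
#' @param params A [history_params()].
#' @param start_state A [history_state()]; defaults to all-zero filters
#'   (no information at session start).
#' @param violation_mode `"freeze"` or `"decay"`.
#' @return Numeric vector of length `nrow(tbl)`.
#' @export
initial_state_sequence <- function(tbl, params, start_state = history_state(),
                                   violation_mode = c("freeze", "decay")) {
  violation_mode <- match.arg(violation_mode)
  n <- nrow(tbl)
  if (n == 0) return(numeric(0))
  pairs_obs <- choice_outcome_pair(tbl$choice, tbl$outcome)
  initial_state_from_pairs(pairs_obs, params, start_state, violation_mode)
}

# Core recursion on a vector of pair labels (NA = violation). Vectorized
# via the linear recurrence i_k = beta * i_{k-1} + eta * 1[o_k = h]
# (stats::filter, recursive), with violations excised in freeze mode.
initial_state_from_pairs <- function(pairs_obs, params,
                                     start_state = history_state(),
                                     violation_mode = "freeze") {
  n <- length(pairs_obs)
  pairs <- c("Rw", "Lw", "Rl", "Ll")
  if (violation_mode == "freeze") {
    keep <- !is.na(pairs_obs)
    sub <- pairs_obs[keep]
    m <- length(sub)
    after <- matrix(0, nrow = m, ncol = 4, dimnames = list(NULL, pairs))
    for (h in pairs) {
      inp <- params$eta[[h]] * (sub == h)
      after[, h] <- if (m > 0) {
        as.numeric(stats::filter(inp, params$beta[[h]], method = "recursive",
                                 init = start_state$filters[[h]]))
      } else numeric(0)
    }
    I_after <- rowSums(after)            # state after valid trial k
    # trial n sees the state after the last valid trial before n
    n_valid_before <- cumsum(keep) - keep # valid trials strictly before n
    I <- ifelse(n_valid_before == 0, start_state$initial_state,
                I_after[pmax(n_valid_before, 1)])
    as.numeric(I)
  } else {
    after <- matrix(0, nrow = n, ncol = 4, dimnames = list(NULL, pairs))
    for (h in pairs) {
      inp <- params$eta[[h]] * (!is.na(pairs_obs) & pairs_obs == h)
      after[, h] <- as.numeric(
        stats::filter(inp, params$beta[[h]], method = "recursive",
                      init = start_state$filters[[h]])
      )
    }
    c(start_state$initial_state, head(rowSums(after), -1))
  }
}
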