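# Independent oracles and fixture builders shared across tests.

# Brute-force initial state by explicit summation over the full past:
# I(n) = sum over valid past trials m of eta[o_m] * beta[o_m]^(number of
# valid trials strictly between m and n). Independent of the package's
# filter recursion.
brute_force_initial_state <- function(pairs_obs, params) {
  n <- length(pairs_obs)
  valid_idx <- which(!is.na(pairs_obs))
  out <- numeric(n)
  for (trial in seq_len(n)) {
    past <- valid_idx[valid_idx < trial]
    tot <- 0
    for (m in past) {
      h <- pairs_obs[m]
      gap <- sum(valid_idx > m & valid_idx < trial)
      tot <- tot + params$eta[[h]] * params$beta[[h]]^gap
    }
    out[trial] <- tot
  }
  out
}

# Two-boundary Wiener first-passage density (sine series), boundaries at
# -B and +B, start I, drift mu, diffusion variance sigma2. side = "upper"
# or "lower". Standard closed form for constant-drift diffusion.
wiener_fpt_density <- function(t, mu, sigma2, B, I, side = c("upper", "lower"),
                               n_terms = 200) {
  side <- match.arg(side)
  a <- 2 * B
  z <- I + B
  if (side == "upper") {
    z <- a - z
    mu <- -mu
  }
  k <- seq_len(n_terms)
  sapply(t, function(tt) {
    s <- sum(k * sin(k * pi * z / a) * exp(-k^2 * pi^2 * sigma2 * tt / (2 * a^2)))
    (pi * sigma2 / a^2) * exp(-mu * z / sigma2 - mu^2 * tt / (2 * sigma2)) * s
  })
}

# Minimal hand-built session (non-violation unless stated).
tiny_session <- function(choices, outcomes, violation = NULL,
                         duration = 0.5, rt = NA_real_) {
  n <- length(choices)
  if (is.null(violation)) violation <- is.na(choices)
  session_table(
    session_id = "tiny", duration_s = rep(duration, n),
    left_clicks = rep(list(c(0.1, 0.2)), n),
    right_clicks = rep(list(c(0.15, 0.3)), n),
    choice = choices, outcome = outcomes, rt_s = rt, violation = violation
  )
}

# A small simulated fixed-duration session used by several tests.
demo_session <- function(n_trials = 600, seed = 42, kappa = 0.05) {
  cfg <- task_config(n_trials = n_trials)
  ag <- default_agent(cfg)
  ag$lapse$kappa <- kappa
  simulate_agent_session(cfg, ag, seed = seed)
}
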