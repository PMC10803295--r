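#' Task configuration for synthetic sessions
#'
#' Describes the pulsatile two-alternative task the generator emulates: two
#' simultaneous Poisson click streams whose rates sum to `total_click_rate`,
#' with trial difficulty set by the rate ratio and the rewarded side drawn
#' independently of difficulty. In fixed-duration mode the stimulus lasts
#' `duration` seconds and the rewarded side follows the realized click
#' counts (`greater_count`); in reaction-time mode the stimulus plays until
#' the agent responds (up to `rt_horizon`) and reward follows the
#' generative rates (`greater_rate`).
#'
#' @param n_trials Number of trials.
#' @param task_mode `"fixed_duration"` or `"reaction_time"`.
#' @param total_click_rate Summed Poisson rate of the two streams (Hz).
#' @param rate_ratios Right:left generative rate ratios to sample from;
#'   must be symmetric about 1 (each ratio's reciprocal also present).
#' @param duration Stimulus duration in seconds (fixed-duration mode).
#' @param rt_horizon Longest stimulus the generator simulates (seconds,
#'   reaction-time mode).
#' @param reward_rule `"greater_count"` or `"greater_rate"`; defaults by
#'   task mode as above.
#' @param violation_rate Probability a trial is a violation (no choice or
#'   outcome recorded); 0 by default.
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_trials = 1000,
                        task_mode = c("fixed_duration", "reaction_time"),
                        total_click_rate = 40,
                        rate_ratios = c(39 / 1, 26 / 14, 23 / 17,
                                        17 / 23, 14 / 26, 1 / 39),
                        duration = 0.5, rt_horizon = 10,
                        reward_rule = NULL, violation_rate = 0) {
  task_mode <- match.arg(task_mode)
  if (is.null(reward_rule)) {
    reward_rule <- if (task_mode == "reaction_time") "greater_rate" else
      "greater_count"
  }
  reward_rule <- match.arg(reward_rule, c("greater_count", "greater_rate"))
  if (total_click_rate <= 0) abort("total_click_rate must be positive")
  lr <- sort(log(rate_ratios))
  if (max(abs(lr + rev(lr))) > 1e-8) {
    abort("rate_ratios must be symmetric about 1")
  }
  if (violation_rate < 0 || violation_rate >= 1) {
    abort("violation_rate must lie in [0, 1)")
  }
  structure(list(n_trials = as.integer(n_trials), task_mode = task_mode,
                 total_click_rate = total_click_rate,
                 rate_ratios = rate_ratios, duration = duration,
                 rt_horizon = rt_horizon, reward_rule = reward_rule,
                 violation_rate = violation_rate),
            class = "task_config")
}

#' A complete generative agent
#'
#' Bundles the component parameters of the full generative model: history
#' filters setting the initial state, the click accumulator, the true-lapse
#' mixture, and (for reaction-time sessions) the non-decision-time process.
#'
#' @param history A [history_params()].
#' @param acc An [accumulator_params()].
#' @param lapse A [lapse_params()].
#' @param ndt An [ndt_params()] or `NULL` (fixed-duration agent).
#' @return An object of class `generative_agent`.
#' @export
generative_agent <- function(history = history_params(),
                             acc = accumulator_params(),
                             lapse = lapse_params(),
                             ndt = NULL) {
  stopifnot(inherits(history, "history_params"),
            inherits(acc, "accumulator_params"),
            inherits(lapse, "lapse_params"),
            is.null(ndt) || inherits(ndt, "ndt_params"))
  structure(list(history = history, acc = acc, lapse = lapse, ndt = ndt),
            class = "generative_agent")
}

#' Generate Poisson click trains
#'
#' Samples per-trial stimuli: the rewarded side and the difficulty level
#' (rate ratio) are drawn independently, the larger generative rate is
#' assigned to the rewarded side under the `greater_rate` rule, and each
#' stream is a homogeneous Poisson process over the trial's stimulus
#' window. Under the `greater_count` rule the correct side is instead
#' determined by the realized counts (ties broken at random), so the
#' sampled side only orients the rates.
#'
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @return A tibble with columns `trial_index`, `rate_L`, `rate_R`,
#'   `left_clicks`, `right_clicks` (list-columns), `duration_s`,
#'   `correct_side`.
#' @export
generate_click_trains <- function(config, seed = 1) {
  stopifnot(inherits(config, "task_config"))
  with_local_seed(seed, {
    n <- config$n_trials
    horizon <- if (config$task_mode == "reaction_time") config$rt_horizon else
      config$duration
    ratio <- sample(config$rate_ratios, n, replace = TRUE)
    side_hi <- sample(c("L", "R"), n, replace = TRUE)
    # orient the sampled ratio so the higher rate sits on side_hi
    r_hi <- pmax(ratio, 1 / ratio)
    rate_R <- ifelse(side_hi == "R", r_hi, 1 / r_hi)
    rate_R <- config$total_click_rate * rate_R / (1 + rate_R)
    rate_L <- config$total_click_rate - rate_R
    draw_train <- function(rate) {
      k <- rpois(1, rate * horizon)
      sort(runif(k, 0, horizon))
    }
    left <- lapply(rate_L, draw_train)
    right <- lapply(rate_R, draw_train)
    correct <- if (config$reward_rule == "greater_rate") {
      ifelse(rate_R > rate_L, "R", ifelse(rate_R < rate_L, "L",
                                          sample(c("L", "R"), n, TRUE)))
    } else {
      nr <- lengths(right)
      nl <- lengths(left)
      tie <- sample(c("L", "R"), n, replace = TRUE)
      ifelse(nr > nl, "R", ifelse(nr < nl, "L", tie))
    }
    tibble::tibble(trial_index = seq_len(n), rate_L = rate_L,
                   rate_R = rate_R, left_clicks = left, right_clicks = right,
                   duration_s = horizon, correct_side = correct)
  })
}

#' Simulate a closed-loop session of the full generative agent
#'
#' Runs the complete generative model trial by trial: the initial state
#' follows the history filters driven by the agent's own realized choices
#' and outcomes; with probability `kappa` the trial is a true lapse
#' (choice from the lapse rule, and in reaction-time mode an RT drawn from
#' the NDT alone); otherwise a single accumulator path is simulated by
#' Euler-Maruyama through the trial's click train. In reaction-time mode
#' the response time is the bound-hitting time plus an NDT draw, and the
#' recorded click train is truncated at the response (the stimulus stops
#' when fixation breaks). Ground truth the fitting code must not see
#' (initial states, lapse flags, decision times) is returned in a separate
#' `truth` table.
#'
#' @param config A [task_config()].
#' @param agent A [generative_agent()].
#' @param seed Integer seed.
#' @param session_id Identifier stored in the session table.
#' @param sim_dt Euler step for the accumulator path (seconds).
#' @return A list with elements `session` (a session tibble accepted by
#'   [validate_session_table()]), `truth` (per-trial tibble: `initial_state`,
#'   `lapse`, `decision_time`, `ndt`, `correct_side`, rates), and `agent`.
#' @export
simulate_agent_session <- function(config, agent, seed = 1,
                                   session_id = "synthetic", sim_dt = 1e-3) {
  stopifnot(inherits(config, "task_config"), inherits(agent, "generative_agent"))
  rt_mode <- config$task_mode == "reaction_time"
  if (rt_mode && is.null(agent$ndt)) {
    abort("reaction-time mode requires an agent with ndt parameters")
  }
  stim <- generate_click_trains(config, seed = derive_seed(seed, "stim"))
  acc <- agent$acc
  with_local_seed(derive_seed(seed, "agent"), {
    n <- config$n_trials
    filt <- c(Rw = 0, Lw = 0, Rl = 0, Ll = 0)
    choice <- character(n)
    outcome <- character(n)
    violation <- runif(n) < config$violation_rate
    rt <- rep(NA_real_, n)
    I_seq <- numeric(n)
    lapse_flag <- logical(n)
    dtime <- rep(NA_real_, n)
    ndt_draw <- rep(NA_real_, n)
    duration <- stim$duration_s
    left_rec <- stim$left_clicks
    right_rec <- stim$right_clicks
    prev_err <- FALSE
    u_lapse <- runif(n)
    u_choice <- runif(n)
    for (k in seq_len(n)) {
      I <- sum(filt)
      I_seq[k] <- I
      lc <- stim$left_clicks[[k]]
      rc <- stim$right_clicks[[k]]
      is_lapse <- u_lapse[k] < agent$lapse$kappa
      lapse_flag[k] <- is_lapse
      if (is_lapse) {
        ch <- if (u_choice[k] < true_lapse_prob(agent$lapse, I)) "R" else "L"
        if (rt_mode) {
          ndt_draw[k] <- ndt_sample(1, ch, k, prev_err, agent$ndt)
          rt[k] <- ndt_draw[k]
        }
      } else {
        mags <- adapt_click_magnitudes(lc, rc, acc$phi, acc$tau_phi)
        horizon <- if (rt_mode) config$rt_horizon else duration[k]
        sim <- click_trial_mc_cpp(
          c(lc, rc), c(rep(-1, length(lc)), rep(1, length(rc))),
          c(mags$left, mags$right), acc$lambda, acc$sigma2_a, acc$sigma2_s,
          acc$bound, max(min(I, acc$bound), -acc$bound), horizon, 1L, sim_dt,
          derive_seed(seed, k), TRUE
        )
        if (rt_mode) {
          if (sim$side[1] != 0) {
            dtime[k] <- sim$hit_time[1]
            ch <- if (sim$side[1] > 0) "R" else "L"
          } else {
            # never reached bound within the horizon: respond on the
            # current sign of the accumulator, decision time censored
            dtime[k] <- horizon
            ch <- if (sim$final_x[1] > acc$bias) "R" else "L"
          }
          ndt_draw[k] <- ndt_sample(1, ch, k, prev_err, agent$ndt)
          rt[k] <- dtime[k] + ndt_draw[k]
        } else {
          xT <- if (sim$side[1] != 0) sim$side[1] * acc$bound else
            sim$final_x[1]
          ch <- if (xT > acc$bias) "R" else if (xT < acc$bias) "L" else
            (if (u_choice[k] < 0.5) "R" else "L")
        }
      }
      if (rt_mode) {
        left_rec[[k]] <- lc[lc <= rt[k]]
        right_rec[[k]] <- rc[rc <= rt[k]]
        duration[k] <- rt[k]
      }
      correct_k <- stim$correct_side[k]
      if (violation[k]) {
        choice[k] <- NA_character_
        outcome[k] <- NA_character_
        rt[k] <- NA_real_
        # state frozen: no decay, no increment
      } else {
        choice[k] <- ch
        outcome[k] <- if (ch == correct_k) "win" else "loss"
        pair <- paste0(ch, if (outcome[k] == "win") "w" else "l")
        filt <- agent$history$beta * filt
        filt[pair] <- filt[pair] + agent$history$eta[pair]
        prev_err <- outcome[k] == "loss"
      }
    }
    session <- tibble::tibble(
      session_id = session_id, trial_index = seq_len(n),
      duration_s = duration, left_clicks = left_rec,
      right_clicks = right_rec, choice = choice, outcome = outcome,
      rt_s = rt, violation = violation
    )
    truth <- tibble::tibble(
      trial_index = seq_len(n), initial_state = I_seq, lapse = lapse_flag,
      decision_time = dtime, ndt = ndt_draw,
      correct_side = stim$correct_side, rate_L = stim$rate_L,
      rate_R = stim$rate_R
    )
    list(session = validate_session_table(session), truth = truth,
         agent = agent)
  })
}

#' Simulate a cohort of synthetic rats
#'
#' Draws `n_rats` agents with independent parameters sampled uniformly
#' from `parameter_ranges` and simulates one session per agent. Ranges are
#' a named list of length-2 numeric vectors; recognized names are the
#' history parameters (`eta_Rw`, `eta_Lw`, `eta_loss`, `beta_w`,
#' `beta_loss`), accumulator fields (`lambda`, `sigma2_a`, `sigma2_s`,
#' `bound`, `phi`, `tau_phi`, `bias`) and lapse fields (`kappa`, `rho`).
#' Unlisted parameters keep the values in `base_agent`. Reproducible:
#' a fixed seed yields an identical cohort.
#'
#' @param n_rats Number of synthetic subjects.
#' @param parameter_ranges Named list of `c(lo, hi)` ranges.
#' @param config A [task_config()] shared by all subjects.
#' @param seed Integer seed.
#' @param base_agent Template [generative_agent()].
#' @return A list of `n_rats` elements, each as returned by
#'   [simulate_agent_session()].
#' @export
make_cohort <- function(n_rats, parameter_ranges = list(), config,
                        seed = 1, base_agent = default_agent(config)) {
  if (n_rats == 0) return(list())
  draws <- with_local_seed(derive_seed(seed, "cohort"), {
    lapply(seq_len(n_rats), function(i) {
      vapply(parameter_ranges, function(rg) runif(1, rg[1], rg[2]),
             numeric(1))
    })
  })
  lapply(seq_len(n_rats), function(i) {
    agent <- modify_agent(base_agent, draws[[i]])
    sim <- simulate_agent_session(config, agent,
                                  seed = derive_seed(seed, paste0("rat", i)),
                                  session_id = sprintf("rat%02d", i))
    sim
  })
}

#' @rdname make_cohort
#' @param config A [task_config()]; reaction-time configs get an NDT block
#'   and stronger initial-state updating (the reaction-time dataset shows
#'   clearer history signatures).
#' @export
default_agent <- function(config) {
  rt <- config$task_mode == "reaction_time"
  eta_w <- if (rt) 1.2 else 0.8
  eta_l <- if (rt) 0.5 else 0.3
  generative_agent(
    history = history_params(
      eta = c(Rw = eta_w, Lw = -eta_w, Rl = -eta_l, Ll = eta_l),
      beta = c(Rw = 0.7, Lw = 0.7, Rl = 0.5, Ll = 0.5)
    ),
    acc = accumulator_params(),
    lapse = lapse_params(kappa = 0.05, rho = 0.5, variant = "motor"),
    ndt = if (config$task_mode == "reaction_time") {
      ndt_params(omega_L = 2, omega_R = 2, nu_L = 10, nu_R = 10,
                 alpha = 0, gamma_o = 0)
    } else NULL
  )
}

# Apply named parameter draws onto an agent.
modify_agent <- function(agent, draws) {
  if (length(draws) == 0) return(agent)
  eta <- agent$history$eta
  beta <- agent$history$beta
  for (nm in names(draws)) {
    v <- draws[[nm]]
    switch(nm,
      eta_Rw = { eta["Rw"] <- v },
      eta_Lw = { eta["Lw"] <- v },
      eta_loss = { eta["Rl"] <- v; eta["Ll"] <- v },
      beta_w = { beta["Rw"] <- v; beta["Lw"] <- v },
      beta_loss = { beta["Rl"] <- v; beta["Ll"] <- v },
      kappa = { agent$lapse$kappa <- v },
      rho = { agent$lapse$rho <- v },
      {
        if (!nm %in% names(agent$acc)) {
          abort(paste0("unknown parameter range: ", nm))
        }
        agent$acc[[nm]] <- v
      }
    )
  }
  agent$history <- history_params(eta, beta,
                                  constraint_mode = "unconstrained")
  agent
}
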