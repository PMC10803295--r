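#' Model specification for maximum-likelihood fitting
#'
#' Declares which model variant to fit and which parameters are free. The
#' full parameter vector (constrained history parameterization) is:
#' history `eta_Rw, eta_Lw, eta_loss, beta_w, beta_loss` (loss updates
#' shared across sides, common win timescale); accumulator `lambda,
#' sigma2_a, sigma2_s, bound, phi, tau_phi, bias, drift`; lapse `kappa,
#' rho, match_slope`; and, in reaction-time mode, NDT `omega_L, omega_R,
#' nu_L, nu_R, alpha, gamma_o`. Parameters not listed in `free` are held
#' at `fixed` values. Models without history-dependent initial states
#' (`with_hist = FALSE`) pin all history parameters at zero.
#'
#' @param with_hist Include history-dependent initial states?
#' @param lapse_variant `"motor"`, `"inattention"`, or `"hybrid"`.
#' @param task_mode `"fixed_duration"` or `"reaction_time"`.
#' @param free Character vector of free parameter names.
#' @param fixed Named numeric overriding default fixed values.
#' @param bounds Named list of `c(lo, hi)` overriding default box bounds.
#' @param label Optional model label used in comparisons; defaults to
#'   e.g. `"hist_motor"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(with_hist = TRUE,
                       lapse_variant = c("motor", "inattention", "hybrid"),
                       task_mode = c("fixed_duration", "reaction_time"),
                       free = c("eta_Rw", "eta_Lw", "beta_w", "bound",
                                "kappa"),
                       fixed = numeric(0), bounds = list(), label = NULL) {
  lapse_variant <- match.arg(lapse_variant)
  task_mode <- match.arg(task_mode)
  defaults <- c(
    eta_Rw = 0, eta_Lw = 0, eta_loss = 0, beta_w = 0, beta_loss = 0,
    lambda = 0, sigma2_a = 1, sigma2_s = 1.5, bound = 3, phi = 0.8,
    tau_phi = 0.05, bias = 0, drift = 0,
    kappa = 0.05, rho = if (lapse_variant == "motor") 0.5 else 0,
    match_slope = 1,
    omega_L = 2, omega_R = 2, nu_L = 10, nu_R = 10, alpha = 0, gamma_o = 0
  )
  default_bounds <- list(
    eta_Rw = c(-3, 3), eta_Lw = c(-3, 3), eta_loss = c(-3, 3),
    beta_w = c(0, 0.999), beta_loss = c(0, 0.999),
    lambda = c(-5, 5), sigma2_a = c(0, 25), sigma2_s = c(0, 25),
    bound = c(0.5, 10), phi = c(0.01, 2), tau_phi = c(0.005, 1),
    bias = c(-2, 2), drift = c(-20, 20),
    kappa = c(0, 0.5),
    rho = if (lapse_variant == "motor") c(0, 1) else c(-3, 3),
    match_slope = c(0, 50),
    omega_L = c(0.1, 10), omega_R = c(0.1, 10),
    nu_L = c(0.1, 50), nu_R = c(0.1, 50),
    alpha = c(0, 0.01), gamma_o = c(-5, 5)
  )
  hist_pars <- c("eta_Rw", "eta_Lw", "eta_loss", "beta_w", "beta_loss")
  if (!with_hist && any(free %in% hist_pars)) {
    abort("history parameters cannot be free when with_hist = FALSE")
  }
  if (lapse_variant != "hybrid" && "match_slope" %in% free) {
    abort("match_slope is only free in the hybrid variant")
  }
  unknown <- setdiff(free, names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown free parameters: ", paste(unknown, collapse = ", ")))
  }
  vals <- defaults
  vals[names(fixed)] <- fixed
  if (!with_hist) vals[hist_pars] <- 0
  bnd <- default_bounds
  bnd[names(bounds)] <- bounds
  if (is.null(label)) {
    label <- paste0(if (with_hist) "hist" else "nohist", "_", lapse_variant)
  }
  structure(list(with_hist = with_hist, lapse_variant = lapse_variant,
                 task_mode = task_mode, free = free, values = vals,
                 bounds = bnd, label = label),
            class = "model_spec")
}

# Expand the constrained fit vector into component parameter objects.
spec_components <- function(spec, params) {
  history <- history_params(
    eta = c(Rw = params[["eta_Rw"]], Lw = params[["eta_Lw"]],
            Rl = params[["eta_loss"]], Ll = params[["eta_loss"]]),
    beta = c(Rw = params[["beta_w"]], Lw = params[["beta_w"]],
             Rl = params[["beta_loss"]], Ll = params[["beta_loss"]])
  )
  acc <- accumulator_params(
    lambda = params[["lambda"]], sigma2_a = params[["sigma2_a"]],
    sigma2_s = params[["sigma2_s"]], bound = params[["bound"]],
    phi = params[["phi"]], tau_phi = params[["tau_phi"]],
    bias = params[["bias"]], drift = params[["drift"]]
  )
  lapse <- lapse_params(
    kappa = params[["kappa"]], rho = params[["rho"]],
    match_slope = if (spec$lapse_variant == "hybrid")
      params[["match_slope"]] else NULL,
    variant = spec$lapse_variant
  )
  ndt <- if (spec$task_mode == "reaction_time") {
    ndt_params(params[["omega_L"]], params[["omega_R"]], params[["nu_L"]],
               params[["nu_R"]], params[["alpha"]], params[["gamma_o"]])
  } else NULL
  list(history = history, acc = acc, lapse = lapse, ndt = ndt)
}

# Precompute data-dependent quantities reused across likelihood calls.
prepare_fit_data <- function(tbl, spec) {
  pairs_obs <- choice_outcome_pair(tbl$choice, tbl$outcome)
  valid <- which(!tbl$violation)
  prev_out <- dplyr::lag(tbl$outcome)
  prev_error <- !is.na(prev_out) & prev_out == "loss"
  pair_levels <- c("Rw", "Lw", "Rl", "Ll")
  list(tbl = tbl, pairs_obs = pairs_obs, valid = valid,
       prev_error = prev_error,
       choice_r = tbl$choice == "R",
       pair_code = match(pairs_obs[valid], pair_levels) - 1L,
       choice_r_valid = tbl$choice[valid] == "R")
}

# Inner NLL via the C++ kernel; full is the complete parameter vector.
inner_nll_full <- function(prep, spec, full, curves, lapse_g) {
  eta4 <- c(full[["eta_Rw"]], full[["eta_Lw"]], full[["eta_loss"]],
            full[["eta_loss"]])
  beta4 <- c(full[["beta_w"]], full[["beta_w"]], full[["beta_loss"]],
             full[["beta_loss"]])
  variant <- match(spec$lapse_variant, c("motor", "inattention", "hybrid")) - 1L
  inner_nll_cpp(curves$curves, curves$lo0, curves$up0,
                full[["bound"]], ncol(curves$curves), prep$pair_code,
                prep$choice_r_valid, eta4, beta4, rep(0, 4),
                full[["kappa"]], variant, full[["rho"]],
                full[["match_slope"]],
                if (is.null(lapse_g)) numeric(0) else lapse_g)
}

# Build per-trial payload (clicks + payoffs) for the adjoint batch.
# Choice-only: terminal payoff = P(report R | terminal state). RT mode:
# per-step payoffs = first-passage mass weights (NDT density of the RT
# residual) for the observed side.
build_trial_payload <- function(prep, spec, comps, grid, steps_list = NULL) {
  tbl <- prep$tbl
  acc <- comps$acc
  n_interior <- grid$n_bins
  step_of <- function(j) if (is.null(steps_list)) NULL else steps_list[[j]]
  if (spec$task_mode == "fixed_duration") {
    term <- terminal_choice_payoff(n_interior, acc$bound, acc$bias)
    # mass absorbed at a bound keeps that bound's rightward-report payoff
    pay_up <- if (acc$bias < acc$bound) 1 else if (acc$bias == acc$bound)
      0.5 else 0
    pay_lo <- if (acc$bias < -acc$bound) 1 else if (acc$bias == -acc$bound)
      0.5 else 0
    lapply(seq_along(prep$valid), function(j) {
      i <- prep$valid[j]
      list(left_clicks = tbl$left_clicks[[i]],
           right_clicks = tbl$right_clicks[[i]],
           duration = tbl$duration_s[i], steps = step_of(j),
           payoff = list(pay_terminal = term, pay_lo = pay_lo,
                         pay_up = pay_up, pay_lo0 = pay_lo,
                         pay_up0 = pay_up))
    })
  } else {
    lapply(seq_along(prep$valid), function(j) {
      i <- prep$valid[j]
      rt <- tbl$rt_s[i]
      n_steps <- max(1L, as.integer(ceiling(rt / grid$dt - 1e-9)))
      tcent <- (seq_len(n_steps) - 0.5) * grid$dt
      side <- tbl$choice[i]
      g <- ndt_density(rt - tcent, side, i, prep$prev_error[i], comps$ndt)
      g0 <- ndt_density(rt, side, i, prep$prev_error[i], comps$ndt)
      list(left_clicks = tbl$left_clicks[[i]],
           right_clicks = tbl$right_clicks[[i]],
           duration = rt, steps = step_of(j),
           payoff = list(
             pay_terminal = NULL,
             pay_lo = if (side == "L") g else rep(0, n_steps),
             pay_up = if (side == "R") g else rep(0, n_steps),
             pay_lo0 = if (side == "L") g0 else 0,
             pay_up0 = if (side == "R") g0 else 0
           ))
    })
  }
}

# Per-valid-trial likelihood of the observed data given curves and the
# initial-state sequence. Returns the vector of per-trial likelihoods.
trial_likelihoods <- function(prep, spec, comps, curves, I_all, lapse_g) {
  acc <- comps$acc
  Iv <- I_all[prep$valid]
  acc_val <- interp_curves(curves$curves, curves$centers, curves$lo0,
                           curves$up0, Iv, acc$bound)
  p_lapse_r <- true_lapse_prob(comps$lapse, Iv)
  kappa <- comps$lapse$kappa
  if (spec$task_mode == "fixed_duration") {
    p_r <- (1 - kappa) * acc_val + kappa * p_lapse_r
    ifelse(prep$choice_r[prep$valid], p_r, 1 - p_r)
  } else {
    p_lapse_obs <- ifelse(prep$choice_r[prep$valid], p_lapse_r, 1 - p_lapse_r)
    (1 - kappa) * acc_val + kappa * p_lapse_obs * lapse_g
  }
}

#' Negative log likelihood of a session under a model specification
#'
#' Sums `-log` per-trial likelihoods over non-violation trials: the choice
#' likelihood (fixed-duration mode) or the joint choice-RT likelihood
#' (reaction-time mode), each a lapse mixture around the Fokker-Planck
#' accumulator likelihood evaluated at that trial's history-dependent
#' initial state. Violation trials contribute nothing but the history
#' state threads through them frozen.
#'
#' @param tbl Session tibble.
#' @param spec A [model_spec()].
#' @param params Full named parameter vector (see [model_spec()]); missing
#'   entries fall back to the spec's fixed values.
#' @param grid An [fp_grid()].
#' @return The scalar negative log likelihood (finite; a non-finite
#'   per-trial likelihood raises an error naming the offending trial).
#' @export
negative_log_likelihood <- function(tbl, spec, params = NULL,
                                    grid = fp_grid(61, 0.005)) {
  stopifnot(inherits(spec, "model_spec"))
  full <- spec$values
  if (!is.null(params)) full[names(params)] <- params
  comps <- spec_components(spec, full)
  prep <- prepare_fit_data(tbl, spec)
  payload <- build_trial_payload(prep, spec, comps, grid)
  curves <- fp_choice_curves(payload, comps$acc, grid)
  I_all <- initial_state_from_pairs(prep$pairs_obs, comps$history)
  lapse_g <- if (spec$task_mode == "reaction_time") {
    vapply(seq_along(prep$valid), function(j) payload[[j]]$payoff$pay_lo0 +
             payload[[j]]$payoff$pay_up0, numeric(1))
  } else NULL
  lik <- trial_likelihoods(prep, spec, comps, curves, I_all, lapse_g)
  if (any(!is.finite(lik))) {
    abort(sprintf("non-finite likelihood at trial %d",
                  prep$valid[which(!is.finite(lik))[1]]))
  }
  floor_p <- 1e-12
  -sum(log(pmax(lik, floor_p)))
}

#' Maximum-likelihood fit of an accumulator model variant
#'
#' Fits the free parameters of `spec` to a session by constrained maximum
#' likelihood. The optimization exploits the linearity of the
#' Fokker-Planck propagator: for fixed accumulator (and NDT) parameters,
#' one adjoint pass per trial yields the trial's likelihood as a function
#' of the initial state across the whole grid, after which the history and
#' lapse parameters are optimized in a fast inner loop (Nelder-Mead with
#' multi-start on the first outer iteration, warm-started afterwards).
#' Accumulator-level free parameters are profiled in an outer loop
#' (Brent's method when one, Nelder-Mead when several). Box bounds are
#' enforced by penalty. Deterministic given `seed`.
#'
#' @param tbl Session tibble (should have passed [apply_session_filters()]).
#' @param spec A [model_spec()].
#' @param grid An [fp_grid()]; the default (61 bins, 5 ms) is the reduced
#'   resolution used for fitting, see the package vignette.
#' @param seed Integer seed (controls inner-start jitter only).
#' @param n_starts Inner multi-start count (default 5).
#' @param init Optional named vector of starting values for free
#'   parameters; defaults to the spec's fixed values.
#' @param control List: `outer_tol` (Brent tolerance, default 0.02),
#'   `outer_maxit` (Nelder-Mead outer iterations, default 60),
#'   `inner_maxit` (default 400).
#' @return An object of class `histddm_fit`: list with `best_params` (full
#'   named vector), `loglik`, `n_trials`, `k` (free parameter count),
#'   `per_trial_bic` (`(k log N - 2 logL) / N`), `diagnostics`, `seed`,
#'   `spec`, and `grid`.
#' @export
fit_mle <- function(tbl, spec, grid = fp_grid(61, 0.005), seed = 1,
                    n_starts = 5, init = NULL, control = list()) {
  stopifnot(inherits(spec, "model_spec"))
  ctl <- utils::modifyList(list(outer_tol = 0.02, outer_maxit = 60,
                                inner_maxit = 400), control)
  prep <- prepare_fit_data(tbl, spec)
  n_valid <- length(prep$valid)
  if (n_valid == 0) abort("no non-violation trials to fit")
  inner_pool <- c("eta_Rw", "eta_Lw", "eta_loss", "beta_w", "beta_loss",
                  "kappa", "rho", "match_slope")
  inner_names <- intersect(spec$free, inner_pool)
  outer_names <- setdiff(spec$free, inner_names)
  full0 <- spec$values
  if (!is.null(init)) full0[names(init)] <- init
  lob <- vapply(spec$bounds, `[`, numeric(1), 1)
  upb <- vapply(spec$bounds, `[`, numeric(1), 2)

  # seeded jitter offsets for the inner multi-start (first outer call only)
  jit <- with_local_seed(derive_seed(seed, "starts"), {
    lapply(seq_len(max(0, n_starts - 1)), function(s) {
      runif(length(inner_names), -0.25, 0.25)
    })
  })
  state <- new.env(parent = emptyenv())
  state$warm <- NULL
  state$n_outer <- 0L
  state$inner_conv <- 0L
  # click-step preprocessing depends only on (phi, tau_phi, sigma2_s, dt):
  # precompute once when none of those is profiled in the outer loop
  steps_list <- NULL
  if (!any(c("phi", "tau_phi", "sigma2_s") %in% outer_names)) {
    comps0 <- spec_components(spec, full0)
    durs <- if (spec$task_mode == "fixed_duration")
      prep$tbl$duration_s else prep$tbl$rt_s
    steps_list <- lapply(prep$valid, function(i) {
      trial_step_inputs(prep$tbl$left_clicks[[i]],
                        prep$tbl$right_clicks[[i]], durs[i], comps0$acc,
                        grid)
    })
  }

  inner_objective_factory <- function(comps_outer, curves, lapse_g) {
    function(inner_par) {
      full <- state$full_outer
      full[inner_names] <- inner_par
      if (any(inner_par < lob[inner_names] - 1e-12) ||
          any(inner_par > upb[inner_names] + 1e-12)) {
        over <- pmax(inner_par - upb[inner_names], 0) +
          pmax(lob[inner_names] - inner_par, 0)
        inner_par <- pmin(pmax(inner_par, lob[inner_names]), upb[inner_names])
        full[inner_names] <- inner_par
        penalty <- 1e4 * sum(over) * n_valid
      } else penalty <- 0
      inner_nll_full(prep, spec, full, curves, lapse_g) + penalty
    }
  }

  eval_outer <- function(outer_par) {
    full <- full0
    full[outer_names] <- pmin(pmax(outer_par, lob[outer_names]),
                              upb[outer_names])
    state$full_outer <- full
    comps <- spec_components(spec, full)
    payload <- build_trial_payload(prep, spec, comps, grid, steps_list)
    curves <- fp_choice_curves(payload, comps$acc, grid)
    lapse_g <- if (spec$task_mode == "reaction_time") {
      vapply(payload, function(p) p$payoff$pay_lo0 + p$payoff$pay_up0,
             numeric(1))
    } else NULL
    state$n_outer <- state$n_outer + 1L
    if (length(inner_names) == 0) {
      state$best_inner <- numeric(0)
      return(inner_nll_full(prep, spec, full, curves, lapse_g))
    }
    obj <- inner_objective_factory(comps, curves, lapse_g)
    starts <- if (is.null(state$warm)) {
      base <- pmin(pmax(full0[inner_names], lob[inner_names]),
                   upb[inner_names])
      c(list(base), lapply(jit, function(j) {
        pmin(pmax(base + j * (upb[inner_names] - lob[inner_names]) / 2,
                  lob[inner_names]), upb[inner_names])
      }))
    } else list(state$warm)
    best <- NULL
    for (s in starts) {
      r <- if (length(s) == 1) {
        o <- optim(s, obj, method = "Brent", lower = lob[inner_names],
                   upper = upb[inner_names])
        o
      } else {
        optim(s, obj, method = "Nelder-Mead",
              control = list(maxit = ctl$inner_maxit, reltol = 1e-8))
      }
      if (is.null(best) || r$value < best$value) best <- r
    }
    state$inner_conv <- max(state$inner_conv, best$convergence)
    state$warm <- pmin(pmax(best$par, lob[inner_names]), upb[inner_names])
    state$best_inner <- state$warm
    best$value
  }

  if (length(outer_names) == 0) {
    nll <- eval_outer(numeric(0))
    outer_best <- numeric(0)
    outer_conv <- 0L
  } else if (length(outer_names) == 1) {
    op <- optimize(eval_outer, lower = lob[outer_names],
                   upper = upb[outer_names], tol = ctl$outer_tol)
    outer_best <- op$minimum
    nll <- eval_outer(outer_best)  # refresh inner state at the optimum
    outer_conv <- 0L
  } else {
    start_outer <- pmin(pmax(full0[outer_names], lob[outer_names]),
                        upb[outer_names])
    op <- optim(start_outer, eval_outer, method = "Nelder-Mead",
                control = list(maxit = ctl$outer_maxit))
    outer_best <- pmin(pmax(op$par, lob[outer_names]), upb[outer_names])
    nll <- eval_outer(outer_best)
    outer_conv <- op$convergence
  }

  best_params <- full0
  best_params[outer_names] <- outer_best
  best_params[inner_names] <- state$best_inner
  k <- length(spec$free)
  loglik <- -nll
  structure(list(
    best_params = best_params, loglik = loglik, n_trials = n_valid, k = k,
    per_trial_bic = (k * log(n_valid) - 2 * loglik) / n_valid,
    diagnostics = list(converged = (outer_conv == 0 && state$inner_conv == 0),
                       outer_convergence = outer_conv,
                       inner_convergence = state$inner_conv,
                       n_outer_evals = state$n_outer,
                       n_starts = n_starts),
    seed = seed, spec = spec, grid = grid
  ), class = "histddm_fit")
}

#' @export
print.histddm_fit <- function(x, ...) {
  cat("accumulator model fit [", x$spec$label, "]: ",
      x$n_trials, " trials, k = ", x$k, "\n", sep = "")
  cat("logLik =", format(x$loglik, digits = 8),
      "; per-trial BIC =", format(x$per_trial_bic, digits = 6), "\n")
  print(round(x$best_params[x$spec$free], 4))
  if (!x$diagnostics$converged) cat("warning: optimizer flagged non-convergence\n")
  invisible(x)
}

#' @export
tidy.histddm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$best_params),
                 estimate = unname(x$best_params),
                 free = names(x$best_params) %in% x$spec$free)
}

#' @export
glance.histddm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, nobs = x$n_trials, k = x$k,
                 per_trial_bic = x$per_trial_bic,
                 converged = x$diagnostics$converged)
}

#' Compare two fits of the same session by per-trial BIC
#'
#' The per-trial BIC of a fit is `(k log N - 2 log L) / N`; the model with
#' the lower value is preferred. Both fits must describe the same trials.
#'
#' @param fit_a,fit_b `histddm_fit` objects for the same session.
#' @return A list of class `bic_comparison`: tibble `table` (label, k,
#'   logLik, per-trial BIC), `delta` (`a - b`), and `preferred` label.
#' @export
bic_compare <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "histddm_fit"), inherits(fit_b, "histddm_fit"))
  if (fit_a$n_trials != fit_b$n_trials) {
    abort("fits describe different numbers of trials")
  }
  tab <- tibble::tibble(
    label = c(fit_a$spec$label, fit_b$spec$label),
    k = c(fit_a$k, fit_b$k),
    logLik = c(fit_a$loglik, fit_b$loglik),
    per_trial_bic = c(fit_a$per_trial_bic, fit_b$per_trial_bic)
  )
  delta <- fit_a$per_trial_bic - fit_b$per_trial_bic
  preferred <- if (delta < 0) fit_a$spec$label else if (delta > 0)
    fit_b$spec$label else "tie"
  structure(list(table = tab, delta = delta, preferred = preferred),
            class = "bic_comparison")
}

#' @export
print.bic_comparison <- function(x, ...) {
  print(x$table)
  cat("per-trial BIC difference (first - second):",
      format(x$delta, digits = 6), "; preferred:", x$preferred, "\n")
  invisible(x)
}
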