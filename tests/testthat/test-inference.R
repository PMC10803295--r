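test_that("a coin-flip model has NLL of exactly N log 2", {
  tbl <- demo_session(200, seed = 1)$session
  spec <- model_spec(with_hist = FALSE, free = character(0),
                     fixed = c(kappa = 1, rho = 0.5))
  nll <- negative_log_likelihood(tbl, spec)
  expect_equal(nll, sum(!tbl$violation) * log(2), tolerance = 1e-10)
})

test_that("single-trial NLL reduces to the mixture choice probability", {
  tbl <- demo_session(40, seed = 2)$session[7, ]
  spec <- model_spec(fixed = c(kappa = 0.1, rho = 0.6))
  g <- fp_grid(61, 0.005)
  nll <- negative_log_likelihood(tbl, spec, grid = g)
  comps <- histddm:::spec_components(spec, spec$values)
  p_acc <- choice_likelihood(tbl$left_clicks[[1]], tbl$right_clicks[[1]],
                             tbl$duration_s[1], comps$acc, 0, g)
  p_r <- mixture_choice_prob(p_acc, comps$lapse, 0)
  p_obs <- if (tbl$choice[1] == "R") p_r else 1 - p_r
  expect_equal(nll, -log(p_obs), tolerance = 1e-10)
})

test_that("violation trials are excluded but thread the history state", {
  cfg <- task_config(n_trials = 400, violation_rate = 0.15)
  sim <- simulate_agent_session(cfg, default_agent(cfg), seed = 6)
  tbl <- sim$session
  expect_gt(sum(tbl$violation), 10)
  spec <- model_spec(fixed = c(eta_Rw = 0.8, eta_Lw = -0.8, eta_loss = -0.3,
                               beta_w = 0.7, beta_loss = 0.5))
  nll <- negative_log_likelihood(tbl, spec)
  expect_true(is.finite(nll))
  # dropping the violation rows changes the history threading, so the
  # likelihood of the remaining trials differs
  tbl_drop <- tbl[!tbl$violation, ]
  nll_drop <- negative_log_likelihood(tbl_drop, spec)
  expect_true(is.finite(nll_drop))
  # per-trial counts agree (violations contributed nothing directly)
  expect_equal(sum(!tbl$violation), nrow(tbl_drop))
})

test_that("the generative parameters dominate perturbed copies in likelihood", {
  sim <- demo_session(4000, seed = 13)
  tbl <- sim$session
  spec <- model_spec()
  truth <- spec$values
  truth[c("eta_Rw", "eta_Lw", "eta_loss", "beta_w", "beta_loss")] <-
    c(0.8, -0.8, -0.3, 0.7, 0.5)
  g <- fp_grid(61, 0.005)
  nll_true <- negative_log_likelihood(tbl, spec, truth, g)
  set.seed(99)
  worse <- 0
  for (r in 1:20) {
    pert <- truth
    which_par <- sample(c("eta_Rw", "eta_Lw", "beta_w", "bound", "kappa",
                          "sigma2_s"), 1)
    pert[which_par] <- pert[which_par] * runif(1, 1.3, 1.8) + 0.1
    if (which_par == "beta_w") pert[which_par] <- min(pert[which_par], 0.99)
    nll_p <- negative_log_likelihood(tbl, spec, pert, g)
    worse <- worse + (nll_p > nll_true)
  }
  expect_gte(worse, 18)
})

test_that("fit_mle is deterministic, converged, and a likelihood fixed point", {
  sim <- demo_session(800, seed = 3)
  spec <- model_spec(free = c("eta_Rw", "eta_Lw", "kappa"),
                     fixed = c(eta_loss = -0.3, beta_w = 0.7,
                               beta_loss = 0.5, rho = 0.5))
  g <- fp_grid(51, 0.01)
  fit <- fit_mle(sim$session, spec, grid = g, seed = 5, n_starts = 3)
  fit_same <- fit_mle(sim$session, spec, grid = g, seed = 5, n_starts = 3)
  expect_identical(fit$best_params, fit_same$best_params)
  expect_true(fit$diagnostics$converged)
  # refitting from the optimum does not improve the likelihood materially
  fit2 <- fit_mle(sim$session, spec, grid = g, seed = 5, n_starts = 1,
                  init = fit$best_params[spec$free])
  expect_lt(fit$loglik - fit2$loglik, 1e-4)
  # the reported likelihood matches the reference evaluation
  nll_ref <- negative_log_likelihood(sim$session, spec, fit$best_params, g)
  expect_equal(-fit$loglik, nll_ref, tolerance = 1e-8)
  # per-trial BIC definition
  expect_equal(fit$per_trial_bic,
               (fit$k * log(fit$n_trials) - 2 * fit$loglik) / fit$n_trials)
})

test_that("choice-only NLL agrees with the analytic DDM in the reduced regime", {
  # click-free constant-drift trials, phi = 1, no sensory noise: the FP
  # choice probability must match the closed form
  spec <- model_spec(with_hist = FALSE, free = character(0),
                     fixed = c(kappa = 0, sigma2_a = 1, sigma2_s = 0,
                               bound = 1, phi = 1, drift = 0.8))
  n <- 30
  tbl <- session_table(
    session_id = "cd", duration_s = rep(8, n),
    left_clicks = rep(list(numeric(0)), n),
    right_clicks = rep(list(numeric(0)), n),
    choice = rep(c("R", "L"), length.out = n),
    outcome = rep("win", n), violation = FALSE
  )
  nll <- negative_log_likelihood(tbl, spec, grid = fp_grid(201, 0.002))
  p <- choice_prob_analytic(0.8, 1, 1, 0)
  want <- -(sum(tbl$choice == "R") * log(p) +
              sum(tbl$choice == "L") * log(1 - p))
  expect_equal(nll, want, tolerance = want * 1e-3)
})

test_that("BIC comparison arithmetic and guards", {
  sim <- demo_session(500, seed = 9)
  spec_a <- model_spec(free = c("eta_Rw", "eta_Lw", "kappa"),
                       fixed = c(beta_w = 0.7, beta_loss = 0.5,
                                 eta_loss = -0.3))
  fit_a <- fit_mle(sim$session, spec_a, grid = fp_grid(51, 0.01), seed = 1,
                   n_starts = 2)
  cmp_same <- bic_compare(fit_a, fit_a)
  expect_equal(cmp_same$delta, 0)
  # equal log likelihood, different k: the penalty decides exactly
  fit_b <- fit_a
  fit_b$k <- fit_a$k + 2
  fit_b$per_trial_bic <- (fit_b$k * log(fit_b$n_trials) - 2 * fit_b$loglik) /
    fit_b$n_trials
  cmp <- bic_compare(fit_b, fit_a)
  expect_equal(cmp$delta, 2 * log(fit_a$n_trials) / fit_a$n_trials)
  expect_equal(cmp$preferred, fit_a$spec$label)
  fit_c <- fit_a
  fit_c$n_trials <- fit_a$n_trials - 1
  expect_error(bic_compare(fit_a, fit_c), "different")
})

test_that("tidy and glance summarize fits", {
  sim <- demo_session(400, seed = 4)
  spec <- model_spec(free = c("kappa"),
                     fixed = c(eta_Rw = 0.8, eta_Lw = -0.8, eta_loss = -0.3,
                               beta_w = 0.7, beta_loss = 0.5))
  fit <- fit_mle(sim$session, spec, grid = fp_grid(51, 0.01), seed = 2,
                 n_starts = 2)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "free") %in% names(td)))
  expect_equal(sum(td$free), 1)
  gl <- glance(fit)
  expect_equal(gl$nobs, fit$n_trials)
  expect_equal(gl$per_trial_bic, fit$per_trial_bic)
})
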