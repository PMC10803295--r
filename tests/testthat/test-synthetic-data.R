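test_that("click trains are Poisson with the configured rates", {
  cfg <- task_config(n_trials = 4000, rate_ratios = c(3, 1 / 3),
                     total_click_rate = 40, duration = 0.5)
  tr <- generate_click_trains(cfg, seed = 2)
  # rates are 30/10 in one orientation or the other
  expect_true(all(sort(unique(round(tr$rate_R, 6))) == c(10, 30)))
  hi <- tr$rate_R == 30
  mean_hi <- mean(lengths(tr$right_clicks[hi]))
  se <- sqrt(30 * 0.5 / sum(hi))
  expect_lt(abs(mean_hi - 15), 3 * se)
  # all click times inside the stimulus window, sorted
  expect_true(all(vapply(tr$right_clicks, function(x)
    !is.unsorted(x) && all(x >= 0 & x <= 0.5), logical(1))))
  # a zero-rate side yields no clicks, ever
  cfg0 <- task_config(n_trials = 50, rate_ratios = c(1e9, 1e-9),
                      total_click_rate = 40)
  tr0 <- generate_click_trains(cfg0, seed = 3)
  which0 <- tr0$rate_L < 1e-6
  expect_true(all(lengths(tr0$left_clicks[which0]) == 0))
})

test_that("the reward rule decides the correct side", {
  cfg <- task_config(n_trials = 2000, task_mode = "reaction_time",
                     rate_ratios = c(23 / 17, 17 / 23))
  tr <- generate_click_trains(cfg, seed = 5)
  # greater_rate: correct side follows the generative rates exactly,
  # independent of realized counts
  expect_equal(tr$correct_side, ifelse(tr$rate_R > tr$rate_L, "R", "L"))
  cfg2 <- task_config(n_trials = 2000, rate_ratios = c(23 / 17, 17 / 23))
  tr2 <- generate_click_trains(cfg2, seed = 5)
  nr <- lengths(tr2$right_clicks); nl <- lengths(tr2$left_clicks)
  neq <- nr != nl
  expect_equal(tr2$correct_side[neq], ifelse(nr[neq] > nl[neq], "R", "L"))
})

test_that("simulated sessions are reproducible and well-formed", {
  cfg <- task_config(n_trials = 300)
  ag <- default_agent(cfg)
  s1 <- simulate_agent_session(cfg, ag, seed = 77)
  s2 <- simulate_agent_session(cfg, ag, seed = 77)
  expect_identical(s1$session, s2$session)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_agent_session(cfg, ag, seed = 78)
  expect_false(identical(s1$session$choice, s3$session$choice))
  # truth sidecar aligns with the session
  expect_equal(nrow(s1$truth), nrow(s1$session))
  expect_true(all(s1$truth$lapse %in% c(TRUE, FALSE)))
})

test_that("a noiseless counting agent is the sign of the click difference", {
  cfg <- task_config(n_trials = 200)
  ag <- generative_agent(
    history = history_params(),  # eta = 0
    acc = accumulator_params(lambda = 0, sigma2_a = 0, sigma2_s = 0,
                             bound = 50, phi = 1, bias = 0),
    lapse = lapse_params(kappa = 0)
  )
  sim <- simulate_agent_session(cfg, ag, seed = 10)
  nr <- lengths(sim$session$right_clicks)
  nl <- lengths(sim$session$left_clicks)
  neq <- nr != nl
  expect_equal(sim$session$choice[neq], ifelse(nr[neq] > nl[neq], "R", "L"))
  expect_equal(sd(sim$truth$initial_state), 0)
})

test_that("win-stay behavior emerges from positive win increments", {
  sim <- demo_session(4000, seed = 15)
  tbl <- sim$session
  prev_choice <- dplyr::lag(tbl$choice)
  prev_win <- dplyr::lag(tbl$outcome) == "win"
  p_rep <- mean((tbl$choice == prev_choice)[which(prev_win)])
  expect_gt(p_rep, 0.53)
})

test_that("cohorts are reproducible and honor parameter ranges", {
  cfg <- task_config(n_trials = 150)
  expect_length(make_cohort(0, config = cfg), 0)
  co1 <- make_cohort(3, list(eta_Rw = c(0.2, 1), kappa = c(0, 0.1)), cfg,
                     seed = 9)
  co2 <- make_cohort(3, list(eta_Rw = c(0.2, 1), kappa = c(0, 0.1)), cfg,
                     seed = 9)
  expect_identical(co1[[1]]$session, co2[[1]]$session)
  expect_identical(co1[[3]]$truth, co2[[3]]$truth)
  etas <- vapply(co1, function(r) r$agent$history$eta[["Rw"]], numeric(1))
  expect_true(all(etas >= 0.2 & etas <= 1))
  expect_gt(length(unique(etas)), 1)
})

test_that("the simulator and likelihood engine describe the same process", {
  # calibration smoke test: the average log likelihood of simulated data
  # under the true parameters exceeds that under perturbed parameters
  sim <- demo_session(3000, seed = 23)
  spec <- model_spec()
  truth <- spec$values
  truth[c("eta_Rw", "eta_Lw", "eta_loss", "beta_w", "beta_loss")] <-
    c(0.8, -0.8, -0.3, 0.7, 0.5)
  g <- fp_grid(61, 0.005)
  nll_true <- negative_log_likelihood(sim$session, spec, truth, g)
  pert <- truth
  pert[c("eta_Rw", "eta_Lw")] <- 0   # remove history dependence
  nll_no_hist <- negative_log_likelihood(sim$session, spec, pert, g)
  expect_lt(nll_true, nll_no_hist)
  pert2 <- truth
  pert2["bound"] <- 1.2
  expect_lt(nll_true, negative_log_likelihood(sim$session, spec, pert2, g))
})
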