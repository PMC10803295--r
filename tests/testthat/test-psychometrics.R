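true_psy <- function(x, k0, k1, x0, b) k0 + k1 * stats::plogis(b * (x - x0))

test_that("noiseless logistic data are recovered nearly exactly", {
  xs <- seq(-4, 4, length.out = 9)
  p <- true_psy(xs, 0.07, 0.85, 0.6, 1.2)
  n_per <- 20000
  k <- round(p * n_per)
  x <- rep(xs, each = n_per)
  y <- unlist(lapply(seq_along(xs), function(i)
    rep(c(TRUE, FALSE), c(k[i], n_per - k[i]))))
  fit <- fit_psychometric(x, y)
  expect_equal(unname(fit$params), c(0.07, 0.85, 0.6, 1.2), tolerance = 1e-2)
  expect_false(fit$boundary)
  # symmetric data center at zero
  p2 <- true_psy(xs, 0.05, 0.9, 0, 1)
  k2 <- round(p2 * n_per)
  y2 <- unlist(lapply(seq_along(xs), function(i)
    rep(c(TRUE, FALSE), c(k2[i], n_per - k2[i]))))
  fit2 <- fit_psychometric(x, y2)
  expect_lt(abs(fit2$params[["x0"]]), 0.03)
  # degenerate data produce a flagged boundary fit, not an error
  fit3 <- fit_psychometric(rep(xs, each = 5), rep(TRUE, 45))
  expect_true(fit3$boundary)
  expect_error(fit_psychometric(rep(1:3, 10), rep(c(TRUE, FALSE), 15)),
               "4 distinct")
})

test_that("parameter estimates fall inside their own bootstrap intervals", {
  set.seed(100)
  xs <- sample(seq(-4, 4, length.out = 9), 8000, replace = TRUE)
  p <- true_psy(xs, 0.05, 0.9, 1, 0.8)
  y <- runif(8000) < p
  tbl <- tibble::tibble(x = xs, y = y)
  fit_fun <- function(d) fit_psychometric(d$x, d$y)$params
  ci <- bootstrap_ci(fit_fun, tbl, n_boot = 120, seed = 7)
  # truth inside the intervals for all four parameters (nominal 95%)
  truth <- c(kappa0 = 0.05, kappa1 = 0.9, x0 = 1, b = 0.8)
  expect_true(all(ci$conf.low <= truth + 1e-9 & truth <= ci$conf.high + 1e-9))
  # same seed reproduces identical intervals
  ci2 <- bootstrap_ci(fit_fun, tbl, n_boot = 120, seed = 7)
  expect_identical(ci, ci2)
})

test_that("bootstrap interval width shrinks roughly like 1/sqrt(N)", {
  widths <- sapply(c(1000, 4000, 16000), function(n) {
    set.seed(200 + n)
    xs <- sample(seq(-4, 4, length.out = 9), n, replace = TRUE)
    y <- runif(n) < true_psy(xs, 0.05, 0.9, 0.3, 0.9)
    tbl <- tibble::tibble(x = xs, y = y)
    ci <- bootstrap_ci(function(d) fit_psychometric(d$x, d$y)$params["x0"],
                       tbl, n_boot = 80, seed = 3)
    ci$conf.high - ci$conf.low
  })
  # each quadrupling of N should roughly halve the width (allow slack x1.5)
  expect_lt(widths[2], widths[1] / 2 * 1.5)
  expect_lt(widths[3], widths[2] / 2 * 1.5)
})

test_that("conditioning on history partitions the valid trials", {
  tbl <- tiny_session(rep(c("R", "L"), 10),
                      rep(c("win", "win"), 10))
  rw <- condition_on_history(tbl, "prev_Rw")
  lw <- condition_on_history(tbl, "prev_Lw")
  expect_equal(sort(c(rw$trial_index, lw$trial_index)), 2:20)
  expect_length(intersect(rw$trial_index, lw$trial_index), 0)
  # all-violation tail leaves empty subsets
  tbl2 <- tiny_session(c("R", rep(NA, 6)), c("win", rep(NA, 6)))
  expect_equal(nrow(condition_on_history(tbl2, "prev_Rw")), 0)
  # win-stay agents repeat after wins
  sim <- demo_session(3000, seed = 5)$session
  rw3 <- condition_on_history(sim, "prev_Rw")
  expect_gt(mean(rw3$choice == "R"), 0.5)
})

test_that("modulation metrics follow their defining arithmetic", {
  pa <- c(kappa0 = 0.10, kappa1 = 0.88, x0 = 0.5, b = 1)
  pb <- c(kappa0 = 0.02, kappa1 = 0.90, x0 = -0.5, b = 1)
  m <- modulation_metrics(pa, pb)
  expect_equal(m$threshold_mod, 1.0)
  expect_equal(m$lapse_mod, 2 * 0.08 - 0.02)
  m0 <- modulation_metrics(pa, pa)
  expect_equal(m0$threshold_mod, 0)
  expect_equal(m0$lapse_mod, 0)
})

test_that("model-predicted and simulated modulations agree on synthetic data", {
  # the generative model's own choice probabilities, pushed through the
  # same psychometric machinery, reproduce the modulations of its
  # simulated choices (a small-scale model-vs-data consistency loop)
  sim <- demo_session(6000, seed = 17)
  tbl <- sim$session
  hp_sim <- history_psychometric(tbl)
  ag <- sim$agent
  # predicted choice probabilities at the true initial states
  spec <- model_spec()
  params <- spec$values
  params[c("eta_Rw", "eta_Lw", "eta_loss", "beta_w", "beta_loss")] <-
    c(0.8, -0.8, -0.3, 0.7, 0.5)
  g <- fp_grid(61, 0.005)
  prep <- histddm:::prepare_fit_data(tbl, spec)
  comps <- histddm:::spec_components(spec, params)
  payload <- histddm:::build_trial_payload(prep, spec, comps, g)
  curves <- histddm:::fp_choice_curves(payload, comps$acc, g)
  I <- sim$truth$initial_state
  p_acc <- histddm:::interp_curves(curves$curves, curves$centers, curves$lo0,
                                   curves$up0, I, comps$acc$bound)
  p_r <- mixture_choice_prob(p_acc, ag$lapse, I)
  # binarize the prediction, conditioning on the realized previous trial
  set.seed(4)
  pred_right <- runif(nrow(tbl)) < p_r
  pairs <- histddm:::choice_outcome_pair(tbl$choice, tbl$outcome)
  prev <- dplyr::lag(pairs)
  xs <- stimulus_strength(tbl)
  fit_pred <- function(cond) {
    idx <- which(prev == cond)
    fit_psychometric(xs[idx], pred_right[idx])
  }
  mod_pred <- modulation_metrics(fit_pred("Rw"), fit_pred("Lw"))
  expect_equal(mod_pred$threshold_mod, hp_sim$modulation$threshold_mod,
               tolerance = 0.6)
  expect_equal(sign(mod_pred$threshold_mod),
               sign(hp_sim$modulation$threshold_mod))
})
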