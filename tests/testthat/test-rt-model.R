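test_that("NDT densities are proper Inverse-Gaussians with the stated mean", {
  p <- ndt_params(omega_L = 2, omega_R = 2, nu_L = 4, nu_R = 4)
  # IG mean = omega / nu
  ts <- seq(1e-4, 10, length.out = 20001)
  d <- ndt_density(ts, "R", 1, FALSE, p)
  dt <- ts[2] - ts[1]
  expect_equal(sum(d) * dt, 1, tolerance = 1e-6)
  expect_equal(sum(ts * d) * dt, 0.5, tolerance = 1e-4)
  # density vanishes for t <= 0 and is non-negative
  expect_equal(ndt_density(c(-1, 0), "L", 1, FALSE, p), c(0, 0))
  expect_true(all(d >= 0))
})

test_that("drift modulation by trial number and previous outcome", {
  p <- ndt_params(omega_L = 2, omega_R = 2, nu_L = 10, nu_R = 10,
                  alpha = 0.01, gamma_o = 2)
  # effective drift nu - alpha n + gamma_o on post-error trials
  nu_eff <- 10 - 0.01 * 500 + 2
  set.seed(31)
  draws <- ndt_sample(200000, "R", trial_number = 500, prev_error = TRUE,
                      params = p)
  m <- mean(draws)
  want <- 2 / nu_eff
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(m - want), 3 * se)
  # non-positive effective drift is a parameter-domain error
  expect_error(ndt_density(0.3, "R", 1100, FALSE, p), "positive")
})

test_that("pure-lapse trials reduce to the NDT density", {
  acc <- accumulator_params()
  ndt <- ndt_params()
  lap <- lapse_params(kappa = 1, rho = 0.7)
  lik <- joint_choice_rt_likelihood(numeric(0), c(0.05, 0.2), "R", 0.31,
                                    0.2, acc, ndt, lap,
                                    grid = fp_grid(61, 0.005))
  expect_equal(lik, 0.7 * ndt_density(0.31, "R", 1, FALSE, ndt),
               tolerance = 1e-12)
  lik_l <- joint_choice_rt_likelihood(numeric(0), c(0.05, 0.2), "L", 0.31,
                                      0.2, acc, ndt, lap,
                                      grid = fp_grid(61, 0.005))
  expect_equal(lik_l, 0.3 * ndt_density(0.31, "L", 1, FALSE, ndt),
               tolerance = 1e-12)
  expect_error(
    joint_choice_rt_likelihood(numeric(0), 0.1, "R", -0.1, 0, acc, ndt, lap),
    "rt"
  )
})

test_that("the joint choice-RT density integrates to one", {
  set.seed(12)
  acc <- accumulator_params()
  ndt <- ndt_params()
  lap <- lapse_params(kappa = 0.08, rho = 0.5)
  lc <- sort(runif(6, 0, 3)); rc <- sort(runif(22, 0, 3))
  g <- fp_grid(101, 0.005)
  rts <- seq(0.005, 5, by = 0.005)
  dens <- sapply(c("L", "R"), function(side) {
    sapply(rts, function(rt) joint_choice_rt_likelihood(
      lc, rc, side, rt, 0.3, acc, ndt, lap, grid = g))
  })
  total <- sum(dens) * 0.005
  fpd <- first_passage_density(lc, rc, 5, acc, 0.3, g)
  surv <- attr(fpd, "survivor")
  # survivor mass at the horizon is censored, not renormalized
  expect_equal(total, (1 - lap$kappa) * (1 - surv) + lap$kappa,
               tolerance = 1e-3)
  expect_lt(surv, 0.01)
})

test_that("per-trial joint likelihoods match a generative simulation", {
  # forward-simulate one trial many times and compare the 2-D histogram
  # of (choice, RT) against the likelihood on a small set of probe cells
  set.seed(77)
  acc <- accumulator_params(sigma2_a = 1, sigma2_s = 1.5, bound = 2.5)
  ndt <- ndt_params(omega_L = 2, omega_R = 2, nu_L = 10, nu_R = 10)
  lap <- lapse_params(kappa = 0, rho = 0.5)
  lc <- sort(runif(10, 0, 4)); rc <- sort(runif(30, 0, 4))
  I <- 0.5
  n_mc <- 50000L
  mags <- adapt_click_magnitudes(lc, rc, acc$phi, acc$tau_phi)
  sim <- histddm:::click_trial_mc_cpp(
    c(lc, rc), c(rep(-1, length(lc)), rep(1, length(rc))),
    c(mags$left, mags$right), acc$lambda, acc$sigma2_a, acc$sigma2_s,
    acc$bound, I, 4, n_mc, 1e-3, 991, TRUE
  )
  absorbed <- sim$side != 0
  side <- ifelse(sim$side > 0, "R", "L")
  rt_mc <- sim$hit_time +
    ifelse(sim$side > 0,
           ndt_sample(n_mc, "R", 1, FALSE, ndt),
           ndt_sample(n_mc, "L", 1, FALSE, ndt))
  g <- fp_grid(101, 0.005)
  breaks <- c(0.2, 0.4, 0.6, 0.9)
  for (s in c("L", "R")) {
    for (b in seq_len(length(breaks) - 1)) {
      p_mc <- mean(absorbed & side == s & rt_mc >= breaks[b] &
                     rt_mc < breaks[b + 1])
      mid_rts <- seq(breaks[b] + 0.01, breaks[b + 1] - 0.01, by = 0.02)
      p_fp <- sum(sapply(mid_rts, function(rt) joint_choice_rt_likelihood(
        lc, rc, s, rt, I, acc, ndt, lap, grid = g))) * 0.02
      se <- sqrt(max(p_mc * (1 - p_mc), 1e-6) / n_mc)
      expect_lt(abs(p_mc - p_fp), 3 * se + 0.003)
    }
  }
})
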