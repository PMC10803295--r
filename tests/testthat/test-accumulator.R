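test_that("sensory adaptation follows the jump-and-recover dynamics", {
  # phi = 1: no adaptation at all
  m <- adapt_click_magnitudes(c(0.05, 0.2), c(0.1, 0.3), phi = 1,
                              tau_phi = 0.04)
  expect_equal(m$left, c(1, 1))
  expect_equal(m$right, c(1, 1))
  # an isolated first click is unadapted
  expect_equal(adapt_click_magnitudes(numeric(0), 0.37, 0.3, 0.1)$right, 1)
  # closed-form two-click example: 1 and 1 - 0.5 exp(-0.5)
  m2 <- adapt_click_magnitudes(numeric(0), c(0, 0.1), phi = 0.5,
                               tau_phi = 0.2)
  expect_equal(m2$right, c(1, 1 - 0.5 * exp(-0.5)), tolerance = 1e-12)
  # against a fine-step ODE integration of the adaptation dynamics
  set.seed(4)
  lc <- sort(runif(7, 0, 0.4))
  rc <- sort(runif(9, 0, 0.4))
  phi <- 0.6; tau <- 0.08
  got <- adapt_click_magnitudes(lc, rc, phi, tau)
  # Euler integration of dC/dt = (1-C)/tau with jumps C -> phi C at clicks
  times <- sort(c(lc, rc))
  dt <- 1e-6
  C <- 1; t <- 0; mags <- numeric(length(times))
  for (i in seq_along(times)) {
    while (t < times[i] - dt / 2) { C <- C + dt * (1 - C) / tau; t <- t + dt }
    mags[i] <- C
    C <- phi * C
  }
  ord <- order(c(lc, rc))
  want <- numeric(length(times))
  want[ord] <- mags  # back to (left, right) storage order
  expect_equal(c(got$left, got$right), want, tolerance = 1e-4)
})

test_that("degenerate evolutions behave deterministically", {
  frozen <- accumulator_params(lambda = 0, sigma2_a = 0, sigma2_s = 0,
                               bound = 1, phi = 1, bias = 0)
  g <- fp_grid(101, 0.002)
  expect_equal(choice_likelihood(numeric(0), numeric(0), 1, frozen, 0.3, g), 1)
  expect_equal(choice_likelihood(numeric(0), numeric(0), 1, frozen, -0.3, g), 0)
  # starting on the bound: all mass absorbed at t = 0
  fpd <- first_passage_density(numeric(0), numeric(0), 0.5, frozen, 1, g)
  expect_equal(fpd$mass_upper[1], 1)
  expect_equal(sum(fpd$mass_lower), 0)
  # bias beyond the support forces the other choice
  far <- accumulator_params(lambda = 0, sigma2_a = 0.2, sigma2_s = 0,
                            bound = 1, phi = 1, bias = 1.5)
  expect_equal(choice_likelihood(numeric(0), numeric(0), 0.5, far, 0, g), 0)
})

test_that("mass is conserved to near machine precision at every step", {
  set.seed(9)
  acc <- accumulator_params()
  g <- fp_grid(61, 0.005)
  for (rep in 1:5) {
    lc <- sort(runif(rpois(1, 10), 0, 0.5))
    rc <- sort(runif(rpois(1, 10), 0, 0.5))
    I <- runif(1, -2, 2)
    fp <- fokker_planck_evolve(lc, rc, 0.5, acc, I, g)
    running <- cumsum(fp$absorbed_lo + fp$absorbed_up)
    # interior + absorbed = 1 at the final step; per-step drift bounded
    expect_lt(abs(sum(fp$interior) + fp$total_lo + fp$total_up - 1), 1e-10)
    expect_true(all(running <= 1 + 1e-10))
  }
})

test_that("symmetric inputs give a balanced choice", {
  acc <- accumulator_params(lambda = 0, sigma2_a = 0.5, sigma2_s = 0.5,
                            bound = 2, phi = 1, bias = 0)
  clicks <- c(0.1, 0.22, 0.4)
  p <- choice_likelihood(clicks, clicks, 0.5, acc, 0, fp_grid(201, 0.002))
  expect_equal(p, 0.5, tolerance = 1e-3)
})

test_that("choice probability increases with the initial state", {
  set.seed(14)
  acc <- accumulator_params()
  g <- fp_grid(61, 0.005)
  lc <- sort(runif(9, 0, 0.5)); rc <- sort(runif(12, 0, 0.5))
  Is <- seq(-2.5, 2.5, length.out = 11)
  p <- sapply(Is, function(I) choice_likelihood(lc, rc, 0.5, acc, I, g))
  expect_true(all(diff(p) > 0))
})

test_that("the deterministic counting limit reduces to a click count", {
  acc <- accumulator_params(lambda = 0, sigma2_a = 1e-8, sigma2_s = 0,
                            bound = 10, phi = 1, bias = 0)
  g <- fp_grid(201, 0.005)
  # 3 right vs 1 left clicks, I = -1: sum = +1 -> rightward
  expect_gt(choice_likelihood(0.1, c(0.15, 0.3, 0.4), 0.5, acc, -1, g), 0.99)
  # I = -3.5: sum = -1.5 -> leftward
  expect_lt(choice_likelihood(0.1, c(0.15, 0.3, 0.4), 0.5, acc, -3.5, g), 0.01)
})

test_that("choice probabilities are stable under grid refinement", {
  set.seed(2)
  acc <- accumulator_params()
  lc <- sort(runif(10, 0, 0.5)); rc <- sort(runif(14, 0, 0.5))
  p1 <- choice_likelihood(lc, rc, 0.5, acc, 0.5, fp_grid(101, 0.004))
  p2 <- choice_likelihood(lc, rc, 0.5, acc, 0.5, fp_grid(401, 0.001))
  expect_lt(abs(p1 - p2), 1e-3)
})

test_that("fixed-duration choice splits are complementary", {
  set.seed(21)
  acc <- accumulator_params(bias = 0.3)
  g <- fp_grid(61, 0.005)
  lc <- sort(runif(8, 0, 0.5)); rc <- sort(runif(8, 0, 0.5))
  fp <- fokker_planck_evolve(lc, rc, 0.5, acc, 0.2, g)
  p_r <- histddm:::prob_right_from_fp(fp, acc$bias, acc$bound)
  # P(L) computed directly as below-bias mass mirrors 1 - P(R)
  below <- 1 - histddm:::prob_right_from_fp(fp, acc$bias, acc$bound)
  expect_equal(p_r + below, 1, tolerance = 1e-12)
  expect_true(p_r >= 0 && p_r <= 1)
})

test_that("first-passage densities match the constant-drift series solution", {
  mu <- 1.2; s2 <- 1; B <- 1; I <- 0.2
  acc <- accumulator_params(lambda = 0, sigma2_a = s2, sigma2_s = 0,
                            bound = B, phi = 1, drift = mu)
  g <- fp_grid(301, 1e-3)
  fpd <- first_passage_density(numeric(0), numeric(0), 6, acc, I, g)
  keep <- fpd$t > 0.02  # series and grid both struggle at t ~ 0
  for (side in c("upper", "lower")) {
    dens_fp <- (if (side == "upper") fpd$mass_upper else fpd$mass_lower) /
      attr(fpd, "dt")
    dens_series <- wiener_fpt_density(fpd$t, mu, s2, B, I, side)
    expect_lt(max(abs(dens_fp[keep] - dens_series[keep])), 1e-3)
  }
  # total absorption splits agree with the analytic choice probability
  # (the tiny surviving interior mass is the censored remainder)
  expect_lt(abs(sum(fpd$mass_upper) + attr(fpd, "survivor") / 2 -
                  choice_prob_analytic(mu, B, s2, I)), 2e-3)
})

test_that("passage times concentrate near (B - I)/drift in the noiseless limit", {
  mu <- 2
  acc <- accumulator_params(lambda = 0, sigma2_a = 1e-6, sigma2_s = 0,
                            bound = 1, phi = 1, drift = mu)
  fpd <- first_passage_density(numeric(0), numeric(0), 2, acc, 0.2,
                               fp_grid(201, 0.002))
  t_hat <- sum(fpd$t * fpd$mass_upper) / sum(fpd$mass_upper)
  expect_equal(t_hat, (1 - 0.2) / mu, tolerance = 0.02)
  expect_gt(sum(fpd$mass_upper), 0.999)
})
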