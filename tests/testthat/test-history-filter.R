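hp_example <- history_params(
  eta = c(Rw = 0.3, Lw = 0, Rl = 0, Ll = -0.2),
  beta = c(Rw = 0.5, Lw = 0.5, Rl = 0.5, Ll = 0.5)
)

test_that("single-step updates follow the filter recursion", {
  s0 <- history_state()
  s1 <- update_history(s0, "Rw", hp_example)
  expect_equal(s1$initial_state, 0.3)
  s2 <- update_history(s1, "Rw", hp_example)
  expect_equal(s2$initial_state, 0.45)
  s3 <- update_history(s2, "Ll", hp_example)
  expect_equal(s3$initial_state, 0.225 - 0.2)

  # zero increments -> identically zero state
  hp0 <- history_params(beta = c(Rw = 0.9, Lw = 0.9, Rl = 0.9, Ll = 0.9))
  s <- history_state()
  for (p in c("Rw", "Ll", "Rl", "Lw")) s <- update_history(s, p, hp0)
  expect_equal(s$initial_state, 0)

  # memoryless limit: beta = 0 keeps only the previous trial
  hpm <- history_params(eta = c(Rw = 0.7, Lw = -0.1, Rl = 0, Ll = 0))
  s <- update_history(history_state(c(Rw = 5, Lw = -2, Rl = 1, Ll = 0)),
                      "Rw", hpm)
  expect_equal(s$initial_state, 0.7)

  expect_error(update_history(s0, "Xw", hp_example), "unknown")
})

test_that("initial-state sequences match a brute-force summation oracle", {
  hp <- history_params(
    eta = c(Rw = 0.4, Lw = -0.35, Rl = -0.15, Ll = 0.2),
    beta = c(Rw = 0.8, Lw = 0.7, Rl = 0.4, Ll = 0.55)
  )
  set.seed(11)
  pairs <- sample(c("Rw", "Lw", "Rl", "Ll", NA), 100, replace = TRUE,
                  prob = c(0.3, 0.3, 0.15, 0.15, 0.1))
  got <- histddm:::initial_state_from_pairs(pairs, hp)
  want <- brute_force_initial_state(pairs, hp)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("violation trials freeze the state by default, decay on request", {
  pairs <- c("Rw", NA, NA, "Rw")
  hp <- history_params(eta = c(Rw = 1, Lw = 0, Rl = 0, Ll = 0),
                       beta = c(Rw = 0.5, Lw = 0.5, Rl = 0.5, Ll = 0.5))
  frozen <- histddm:::initial_state_from_pairs(pairs, hp)
  expect_equal(frozen, c(0, 1, 1, 1))
  decayed <- histddm:::initial_state_from_pairs(pairs, hp,
                                                violation_mode = "decay")
  expect_equal(decayed, c(0, 1, 0.5, 0.25))
})

test_that("geometric decay after a single event", {
  hp <- history_params(eta = c(Rw = 1, Lw = 0, Rl = 0, Ll = 0),
                       beta = c(Rw = 0.9, Lw = 0.9, Rl = 0.9, Ll = 0.9))
  pairs <- c("Rw", rep("Lw", 20))
  I <- histddm:::initial_state_from_pairs(pairs, hp)
  expect_equal(I[-1], 0.9^(0:19))
})

test_that("filters are bounded and linear in the increments", {
  hp <- history_params(
    eta = c(Rw = 0.6, Lw = -0.8, Rl = 0.3, Ll = -0.1),
    beta = c(Rw = 0.95, Lw = 0.9, Rl = 0.7, Ll = 0.2)
  )
  bound_theory <- sum(abs(hp$eta) / (1 - hp$beta))
  set.seed(3)
  for (rep in 1:5) {
    pairs <- sample(c("Rw", "Lw", "Rl", "Ll"), 400, replace = TRUE)
    I <- histddm:::initial_state_from_pairs(pairs, hp)
    expect_true(all(abs(I) <= bound_theory + 1e-12))
    # scaling all eta by c scales I by c
    hp2 <- history_params(eta = 2.5 * hp$eta, beta = hp$beta)
    expect_equal(histddm:::initial_state_from_pairs(pairs, hp2), 2.5 * I,
                 tolerance = 1e-12)
  }
})

test_that("initial_state_sequence threads a session table", {
  tbl <- tiny_session(c("R", "R", "L", NA, "R"),
                      c("win", "win", "loss", NA, "loss"))
  hp <- history_params(eta = c(Rw = 0.3, Lw = 0, Rl = 0, Ll = -0.2),
                       beta = c(Rw = 0.5, Lw = 0.5, Rl = 0.5, Ll = 0.5))
  I <- initial_state_sequence(tbl, hp)
  expect_length(I, 5)
  expect_equal(I[1], 0)
  expect_equal(I[2], 0.3)
  expect_equal(I[4], I[3] * 0.5 - 0.2)  # decay plus the Ll increment
  expect_equal(I[5], I[4])        # violation frozen
})

test_that("dbm constraint projects and reduces the free-parameter count", {
  hp <- history_params(
    eta = c(Rw = 0.5, Lw = -0.3, Rl = -0.2, Ll = 0.4),
    beta = c(Rw = 0.9, Lw = 0.8, Rl = 0.6, Ll = 0.7)
  )
  d <- dbm_constrain(hp)
  expect_equal(d$constraint_mode, "dbm")
  expect_equal(unname(d$beta), rep(mean(hp$beta), 4))
  expect_equal(unname(abs(d$eta)), rep(mean(abs(hp$eta)), 4))
  expect_equal(sign(unname(d$eta)), c(1, -1, -1, 1))
  # idempotent
  expect_equal(dbm_constrain(d), d)
  # parameter counts decrease with constraints
  expect_lt(n_free_history_params(d),
            n_free_history_params(history_params(
              eta = hp$eta, beta = c(Rw = 0.8, Lw = 0.8, Rl = 0.6, Ll = 0.6),
              constraint_mode = "unconstrained"
            )))
  pc <- history_params(
    eta = c(Rw = 0.5, Lw = -0.3, Rl = -0.2, Ll = -0.2),
    beta = c(Rw = 0.8, Lw = 0.8, Rl = 0.6, Ll = 0.6),
    constraint_mode = "side_constrained"
  )
  expect_equal(n_free_history_params(pc), 5L)
  expect_lt(n_free_history_params(d), n_free_history_params(pc))
})

test_that("conditional means of I differ in sign after R versus L wins", {
  sim <- demo_session(4000, seed = 8)
  pairs <- histddm:::choice_outcome_pair(sim$session$choice,
                                         sim$session$outcome)
  I <- sim$truth$initial_state
  prev <- dplyr::lag(pairs)
  m_rw <- mean(I[which(prev == "Rw")])
  m_lw <- mean(I[which(prev == "Lw")])
  expect_gt(m_rw, 0)
  expect_lt(m_lw, 0)
})
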