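test_that("model registry carries the documented parameter counts and bounds", {
  counts <- c(VSE = 5L, VSE_LA = 6L, EV = 3L, PVL = 4L, PVL_Delta = 4L,
              VPP = 8L, ORL = 5L)
  for (m in names(counts)) expect_equal(model_spec(m)$k, counts[[m]])
  p <- model_spec("VSE")$params
  expect_true(is.na(p["phi", "lower"])) # exploration bonus is unbounded
  expect_equal(p["cons", c("lower", "upper")],
               data.frame(lower = 0, upper = 5, row.names = "cons"))
  expect_equal(model_spec("ORL")$params["K", "upper"], 242)
  expect_equal(model_spec("EV")$params["cons", c("lower", "upper")],
               data.frame(lower = -2, upper = 2, row.names = "cons"))
  expect_error(model_spec("XYZ"))
})

test_that("latent state initializes at zero except unit exploration weights", {
  for (m in igt_models()) {
    st <- init_state(m)
    expect_equal(st$exploit, rep(0, 4))
    expect_equal(st$explore, rep(1, 4))
    expect_equal(st$pers, rep(0, 4))
    expect_equal(st$freq, rep(0, 4))
  }
})

test_that("VSE utility transforms gain and loss magnitudes separately", {
  expect_equal(vse_utility(100, 0, 0.5), 10)
  expect_equal(vse_utility(100, 100, 0.37), 0)
  expect_equal(vse_utility(50, 250, 1.0), -200)
  # 0^0 convention: a zero amount contributes nothing at theta = 0
  expect_equal(vse_utility(100, 0, 0), 1)
  expect_equal(vse_utility(0, 0, 0), 0)
  expect_error(vse_utility(-1, 0, 0.5), "nonnegative")
})

test_that("prospect utility applies loss aversion to the net outcome", {
  expect_equal(prospect_utility(100, 0, 0.5, 2), 10)
  expect_equal(prospect_utility(0, 100, 0.5, 2), -20)
  expect_equal(prospect_utility(100, 100, 0.5, 3), 0)
})

test_that("the VSE update follows the decay and exploration-bonus rules", {
  st <- init_state("VSE")
  st$exploit <- c(2, 1, 0, 0)
  st$explore <- c(1, 1, 1, 1)
  p <- c(theta = 1, delta = 0.5, alpha = 0.5, phi = 3, cons = 2)
  # choose deck 1 with a net outcome of +3
  out <- vse_update(st, 1L, gain = 3, loss = 0, params = p)
  expect_equal(out$exploit[1], 2 * 0.5 + 3)
  expect_equal(out$exploit[2], 0.5)
  expect_equal(out$explore[1], 0) # falls to zero when sampled
  expect_equal(out$explore[2], 1 + 0.5 * (3 - 1))
  # explore of the chosen deck zeroes regardless of its prior value
  st2 <- out
  out2 <- vse_update(st2, 2L, 0, 0, p)
  expect_equal(out2$explore[2], 0)
  expect_error(vse_update(st, 9L, 1, 0, p), "invalid deck")
})

test_that("competitor updates match their printed rules", {
  p_ev <- c(a = 0.5, w = 0.5, cons = 0)
  st <- init_state("EV")
  out <- competitor_update("EV", st, 1L, gain = 100, loss = 0, params = p_ev)
  expect_equal(out$exploit[1], 0.5 * (0.5 * 100))

  p_pvl <- c(delta = 0.25, nu = 0.5, lambda = 1, cons = 1)
  st <- init_state("PVL"); st$exploit <- c(8, 8, 0, 0)
  out <- competitor_update("PVL", st, 1L, 100, 0, p_pvl)
  expect_equal(out$exploit[2], 2) # unchosen: pure decay
  expect_equal(out$exploit[1], 8 * 0.25 + 10)

  p_pvld <- c(a = 0.4, nu = 0.5, lambda = 1, cons = 1)
  st <- init_state("PVL_Delta")
  out <- competitor_update("PVL_Delta", st, 3L, 100, 0, p_pvld)
  expect_equal(out$exploit[3], 0.4 * 10)
  expect_equal(out$exploit[1], 0) # delta rule leaves unchosen untouched

  p_vpp <- c(a = 0.4, nu = 0.5, lambda = 1, cons = 1, eps_gain = 0.5,
             eps_loss = -1, delta_pers = 0.5, w_ev = 0.5)
  st <- init_state("VPP"); st$pers <- c(1, 0, 0, 0)
  out <- competitor_update("VPP", st, 1L, 0, 100, p_vpp)
  expect_equal(out$pers[1], 0.5 * 1 - 1) # discounted then loss increment
})

test_that("the ORL update uses sign-dependent rates and hyperbolic perseveration", {
  p <- c(a_rew = 0.4, a_pun = 0.2, K = 1, w_f = 1, w_p = 1)
  st <- init_state("ORL")
  out <- competitor_update("ORL", st, 1L, gain = 100, loss = 0, params = p)
  expect_equal(out$exploit[1], 0.4 * 100)
  expect_equal(out$freq[1], 0.4 * 1)
  expect_equal(out$freq[2], 0.2 * (-1 / 3)) # fictive update, opposite rate
  expect_equal(out$pers[1], 1 / (1 + 1))
  out2 <- competitor_update("ORL", out, 2L, gain = 0, loss = 50, params = p)
  expect_equal(out2$exploit[2], 0.2 * (-50))
  expect_equal(out2$freq[2], out$freq[2] + 0.2 * (-1 - out$freq[2]))
  expect_equal(out2$freq[1], out$freq[1] + 0.4 * (1 / 3 - out$freq[1]))
  expect_equal(out2$pers, c(out$pers[1], 1, 0, 0) / 2)
})

test_that("consistency transforms follow each family's rule", {
  expect_equal(consistency_from_beta(0, "VSE"), 0)
  expect_equal(consistency_from_beta(5, "VSE"), 242)
  expect_equal(consistency_from_beta(0, "EV", t = 50), 1)
  expect_equal(consistency_from_beta(2, "EV", t = 20), 4)
  expect_error(consistency_from_beta(1, "EV"), "trial index")
  expect_equal(consistency_from_beta(0.7, "ORL"), 1)
})

test_that("softmax probabilities are symmetric, overflow-safe and consistent", {
  st <- init_state("VSE")
  p_hi <- de_params(cons = 5)
  expect_prob_vector(choice_probabilities(st, p_hi, "VSE"))
  # equal combined values -> uniform at any consistency
  expect_equal(choice_probabilities(st, p_hi, "VSE"), rep(0.25, 4))
  # zero consistency -> uniform whatever the values
  st$exploit <- c(100, -50, 3, 0)
  expect_equal(choice_probabilities(st, uniform_params(), "VSE"), rep(0.25, 4))
  # softmax limit at C = 242 with a 10-unit lead, no overflow
  st$exploit <- c(10, 0, 0, 0); st$explore <- rep(0, 4)
  p <- choice_probabilities(st, p_hi, "VSE")
  expect_gt(p[1], 1 - 1e-9)
  expect_true(all(is.finite(p)))
  st$exploit <- c(1e6, 0, 0, 0)
  expect_true(all(is.finite(choice_probabilities(st, p_hi, "VSE"))))
  st$exploit <- c(NaN, 0, 0, 0)
  expect_error(choice_probabilities(st, p_hi, "VSE"), "non-finite")
})

test_that("an unchosen deck's exploration weight converges monotonically to phi", {
  p <- de_params(phi = 3, alpha = 0.3)
  st <- init_state("VSE")
  gaps <- numeric(20)
  for (t in 1:20) {
    st <- vse_update(st, 1L, 50, 0, p) # deck 4 never chosen
    gaps[t] <- abs(st$explore[4] - 3)
  }
  expect_true(all(diff(gaps) < 0))
  expect_equal(gaps[-1] / gaps[-20], rep(1 - 0.3, 19)) # geometric rate 1 - alpha
  expect_lt(gaps[20], 1e-2)
})

test_that("exploitation weights are bounded by max|v| / (1 - delta)", {
  set.seed(2)
  p <- c(theta = 0.8, delta = 0.7, alpha = 0.3, phi = 1, cons = 1)
  st <- init_state("VSE")
  vmax <- vse_utility(100, 0, 0.8)
  bound <- vse_utility(100, 1250, 0.8) # most negative utility in play
  for (t in 1:200) {
    st <- vse_update(st, sample.int(4L, 1L), 100, sample(c(0, 1250), 1L), p)
    expect_true(all(st$exploit <= vmax / (1 - 0.7) + 1e-9))
    expect_true(all(st$exploit >= bound / (1 - 0.7) - 1e-9))
  }
})

test_that("state trajectories are sequence-deterministic", {
  s <- cyclic_session(40)
  p <- c(theta = 0.4, delta = 0.6, alpha = 0.2, phi = 1.5, cons = 2)
  a <- session_log_likelihood(s, "VSE", p, details = TRUE)
  b <- session_log_likelihood(s, "VSE", p, details = TRUE)
  expect_identical(a, b)
})

test_that("compiled likelihood matches the stepwise R implementation", {
  set.seed(31)
  sess <- simulate_agent("VSE", de_params(cons = 1), canonical_schedule(),
                         60, seed = 8)
  for (m in igt_models()) {
    pp <- transform_parameters(rnorm(model_spec(m)$k, 0, sqrt(3)), m)
    expect_equal(session_log_likelihood(sess, m, pp),
                 vseigt:::session_log_likelihood_r(sess, m, pp),
                 tolerance = 1e-10)
  }
})
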