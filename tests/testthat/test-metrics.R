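test_that("SE index counts four-distinct-deck windows in both modes", {
  expect_equal(se_index(c(1, 2, 3, 4), "independent"), 1)
  expect_equal(se_index(c(1, 2, 3, 4, 1, 1, 1, 1), "independent"), 0.5)
  expect_equal(se_index(c(1, 2, 3, 4, 1), "sliding"), 1)
  expect_equal(se_index(c(3, 2, 4, 1, 3, 2, 4, 1), "sliding"), 1) # any cycle
  expect_equal(se_index(rep(1, 100), "sliding"), 0)
  expect_error(se_index(c(1, 2, 3)), "at least 4")
  # 25 independent windows for a 100-trial session
  expect_length(se_events(rep_len(1:4, 100), "independent"), 25L)
  expect_length(se_events(rep_len(1:4, 100), "sliding"), 97L)
})

test_that("SE index is invariant under deck relabeling", {
  set.seed(12)
  ch <- sample.int(4L, 100L, replace = TRUE)
  for (i in 1:5) {
    perm <- sample(4L)
    expect_equal(se_index(perm[ch], "independent"), se_index(ch, "independent"))
    expect_equal(perm[ch] |> se_index("sliding"), se_index(ch, "sliding"))
  }
})

test_that("analytic chance level equals the enumeration of all quadruplets", {
  # independent oracle: enumerate all 4^4 equiprobable sequences
  grid <- expand.grid(1:4, 1:4, 1:4, 1:4)
  n_perm <- sum(apply(grid, 1L, function(w) length(unique(w)) == 4L))
  expect_equal(se_chance_probability(), n_perm / nrow(grid))
  expect_equal(se_chance_probability(), 0.09375)
  expect_equal(round(100 * se_chance_probability(), 2), 9.38)
})

test_that("the exact binomial SE test has the right tails", {
  p0 <- se_chance_probability()
  # a cohort-scale event count far above chance gives a vanishing p-value
  expect_lt(binomial_se_test(1400, 12600, p0), 1e-10)
  # a count at the null expectation is unremarkable
  p_mid <- binomial_se_test(round(1000 * p0), 1000, p0)
  expect_gt(p_mid, 0.1); expect_lt(p_mid, 0.9)
  expect_equal(binomial_se_test(0, 50, p0), 1)
  expect_error(binomial_se_test(5, 10, 1.5), "p0")
})

test_that("the permutation null preserves deck multisets and the seed contract", {
  # a perseverator has null SE identically zero
  d1 <- data.frame(subject = "a", trial = 1:20, choice = rep(2L, 20),
                   gain = 100, loss = 0)
  ch1 <- igt_cohort(d1)
  r1 <- permutation_null_se(ch1, n_perm = 50, seed = 4)
  expect_equal(r1$null_distribution, rep(0, 50))
  # balanced deck use raises the pattern odds above the analytic null
  d2 <- data.frame(subject = "b", trial = 1:100,
                   choice = rep(1:4, each = 25L), gain = 50, loss = 0)
  ch2 <- igt_cohort(d2)
  r2 <- permutation_null_se(ch2, n_perm = 1000, seed = 4)
  expect_gt(r2$null_mean, se_chance_probability())
  expect_true(all(r2$null_distribution >= 0 & r2$null_distribution <= 1))
  r2b <- permutation_null_se(ch2, n_perm = 1000, seed = 4)
  expect_identical(r2$null_distribution, r2b$null_distribution)
})

test_that("net score counts advantageous minus disadvantageous choices", {
  expect_equal(net_score(rep(3L, 100)), 100)
  expect_equal(net_score(rep(1:4, each = 25)), 0)
  expect_equal(net_score(c(1L, 2L, 3L)), -1)
  expect_equal(net_score(cyclic_session(100)), 0)
})

make_mix_cohort <- function(ks) {
  # subject i: ks[i] cyclic trials then perseveration on deck 3
  rows <- lapply(seq_along(ks), function(i) {
    k <- ks[i]
    data.frame(subject = sprintf("s%02d", i), trial = 1:100,
               choice = c(rep_len(1:4, k), rep(3L, 100 - k)),
               gain = 50, loss = 0)
  })
  igt_cohort(do.call(rbind, rows))
}

test_that("SE-performance regression recovers constructed relations", {
  # SE falls linearly as net score rises: negative linear, flat quadratic
  ks <- seq(4, 96, by = 4)
  g <- se_performance_glm(make_mix_cohort(ks))
  expect_lt(g$t[g$term == "linear"], -2)
  expect_lt(g$p[g$term == "linear"], 0.01)
  # U-shape in SE vs performance gives a positive quadratic coefficient
  d <- rbind(
    do.call(rbind, lapply(1:8, function(i) {
      data.frame(subject = paste0("lo", i), trial = 1:100,
                 choice = rep_len(1:4, 100), gain = 50,
                 loss = rep(c(0, 60), 50))
    })),
    do.call(rbind, lapply(1:8, function(i) {
      data.frame(subject = paste0("mid", i), trial = 1:100,
                 choice = rep(c(1L, 2L), 50), gain = 100, loss = 0)
    })),
    do.call(rbind, lapply(1:8, function(i) {
      data.frame(subject = paste0("hi", i), trial = 1:100,
                 choice = rep(3L, 100), gain = 50, loss = 0)
    }))
  )
  # lo: net 0 SE 1; mid: net -100 SE 0; hi: net +100 SE 0 -> inverted U
  g2 <- se_performance_glm(igt_cohort(d))
  expect_lt(g2$estimate[g2$term == "quadratic"], 0)
  # a constant regressor is a degenerate design
  expect_error(se_performance_glm(make_mix_cohort(rep(40, 6))), "degenerate")
})

test_that("d-prime separates faithful, independent and inverted simulations", {
  set.seed(20)
  real_rows <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(subject = paste0("s", i), trial = 1:100,
               choice = c(rep_len(1:4, 48), sample.int(4L, 52L, TRUE)),
               gain = 50, loss = 0)
  }))
  real <- igt_cohort(real_rows)
  # identical simulation: every event matched, large positive capped d'
  ident <- se_dprime(real, real)
  expect_gt(ident$dprime, 3)
  # log-linear cap: corrected rates, not exactly 1 and 0
  expect_equal(ident$hit_rate, (ident$n_signal + 0.5) / (ident$n_signal + 1))
  expect_equal(ident$fa_rate, 0.5 / (ident$n_noise + 1))
  # complement-like simulation: perseverators never produce events
  flat_rows <- real_rows; flat_rows$choice <- 1L
  expect_error(se_dprime(real, igt_cohort(flat_rows)), NA)
  flat <- se_dprime(real, igt_cohort(flat_rows))
  expect_lt(flat$dprime, ident$dprime)
  # independent simulation at the same base rate: d' near 0
  shuf_rows <- do.call(rbind, lapply(split(real_rows, real_rows$subject),
    function(s) { s$choice <- sample(s$choice); s }))
  indep <- se_dprime(real, igt_cohort(shuf_rows))
  expect_lt(abs(indep$dprime), 0.75)
  expect_error(se_dprime(real, igt_cohort(real_rows[1:400, ])),
               "subject counts")
})

test_that("group comparisons report rank-sum z and t consistently", {
  set.seed(40)
  v_same <- rnorm(60)
  g <- rep(c("young", "old"), each = 30)
  r_same <- compare_groups(v_same, g)
  expect_lt(abs(r_same$z), 2)
  expect_gt(r_same$p_t, 0.05)
  v_shift <- c(rnorm(50), rnorm(50) + 3)
  r_shift <- compare_groups(v_shift, rep(c("a", "b"), each = 50))
  expect_lt(r_shift$p_ranksum, 0.001)
  expect_lt(r_shift$p_t, 0.001)
  expect_gt(abs(r_shift$z), 3)
  expect_error(compare_groups(c(1, 2, 3), c("a", "a", "b")), ">= 2 subjects")
  expect_error(compare_groups(1:4, rep("a", 4)), "2 groups")
})

test_that("parameter associations flag monotone and degenerate cases", {
  tab <- data.frame(subject = paste0("s", 1:10),
                    a = 1:10 / 10, w = rep(0.5, 10), cons = 10:1 / 10,
                    loglik = -100, AIC = 206, BIC = 213.8,
                    evidence = -106, accuracy = 0.5, converged = TRUE)
  fits <- structure(list(model = "EV", table = tab), class = "igt_cohort_fit")
  beh <- 1:10
  res <- parameter_associations(fits, beh)
  expect_equal(res$rho[res$parameter == "a"], 1)
  expect_equal(res$rho[res$parameter == "cons"], -1)
  expect_true(res$degenerate[res$parameter == "w"])
  expect_error(parameter_associations(fits, 1:9), "length")
})
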