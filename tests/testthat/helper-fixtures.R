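# Small programmatic fixtures shared across test files.

# Cohort with fully known trial content (2 subjects x 4 trials).
tiny_cohort <- function(group = FALSE) {
  d <- data.frame(
    subject = rep(c("s1", "s2"), each = 4L),
    trial = rep(1:4, 2L),
    choice = c(1L, 2L, 3L, 4L, 2L, 2L, 3L, 1L),
    gain = c(100, 100, 50, 50, 100, 100, 50, 100),
    loss = c(0, 1250, 50, 0, 0, 0, 25, 150)
  )
  if (group) d$group <- rep(c("young", "old"), each = 4L)
  igt_cohort(d)
}

# A session with an exactly cyclical deck sequence 1,2,3,4,1,2,...
cyclic_session <- function(n_trials = 100L, subject = "cyc") {
  data.frame(subject = subject, trial = seq_len(n_trials),
             choice = rep_len(1:4, n_trials),
             gain = rep(50, n_trials), loss = rep(0, n_trials))
}

# Natural-scale VSE parameters in the pure directed-exploration regime.
de_params <- function(phi = 2, alpha = 0.3, cons = 5) {
  c(theta = 0, delta = 0.5, alpha = alpha, phi = phi, cons = cons)
}

# A uniform-random agent: any model with zero consistency.
uniform_params <- function() {
  c(theta = 0.5, delta = 0.5, alpha = 0.3, phi = 1, cons = 0)
}

expect_prob_vector <- function(p) {
  expect_length(p, 4L)
  expect_true(all(p > 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
}
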