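se_windows <- function(n_trials, mode) {
  if (mode == "independent") seq(1L, n_trials - 3L, by = 4L) else seq_len(n_trials - 3L)
}

#' Sequential-exploration (SE) index of a choice sequence
#'
#' The frequency of windows of four consecutive trials in which all
#' four decks were chosen — the behavioral signature of directed
#' (sequential) exploration. `independent` windows start at trials
#' 1, 5, 9, ... (25 windows for a 100-trial session) and are used for
#' inference about the presence of sequential exploration; `sliding`
#' windows start at every trial (1--4, 2--5, ...) and maximize
#' sensitivity for interindividual differences.
#'
#' @param choices integer vector of deck choices in 1--4, ordered by
#'   trial; at least 4 trials.
#' @param mode `"independent"` or `"sliding"`.
#' @return frequency in \[0,1\].
#' @export
se_index <- function(choices, mode = c("independent", "sliding")) {
  mode <- match.arg(mode)
  mean(se_events(choices, mode))
}

#' Binary SE event series over windows of four trials
#'
#' @inheritParams se_index
#' @return logical vector, one element per window.
#' @export
se_events <- function(choices, mode = c("independent", "sliding")) {
  mode <- match.arg(mode)
  n <- length(choices)
  if (n < 4L) stop("need at least 4 trials to compute SE")
  starts <- se_windows(n, mode)
  vapply(starts, function(s) {
    w <- choices[s:(s + 3L)]
    length(unique(w)) == 4L
  }, logical(1))
}

#' Chance probability of an SE event under random choice
#'
#' Under uniform random deck selection, the probability that four
#' consecutive choices hit four distinct decks is `4!/4^4 = 24/256 =
#' 0.09375` (9.38%). Exploitation only lowers this, by unbalancing
#' deck probabilities, which makes the analytic null conservative.
#'
#' @return 0.09375 exactly.
#' @export
se_chance_probability <- function() {
  factorial(4) / 4^4
}

#' Exact one-sided binomial test for excess SE events
#'
#' Upper-tail probability of observing at least `k` SE events in `n`
#' windows when each window is an SE event with probability `p0`.
#'
#' @param k observed SE event count.
#' @param n number of windows.
#' @param p0 null event probability (defaults to the analytic chance
#'   level [se_chance_probability()]).
#' @return the exact upper-tail p-value.
#' @export
binomial_se_test <- function(k, n, p0 = se_chance_probability()) {
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0,1)")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Permutation null for the cohort-mean SE index
#'
#' A subject-wise permutation null that respects each subject's deck
#' preferences: on each permutation every subject's choice sequence is
#' shuffled in time (preserving the deck multiset), the SE index over
#' independent windows is recomputed, and the cohort mean recorded.
#' Subjects who never used four distinct decks contribute 0 in every
#' permutation, so this null is lower than the analytic 9.38% for
#' value-driven cohorts.
#'
#' @param cohort an [igt_cohort()].
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list with `null_mean`, the per-permutation cohort means
#'   (`null_distribution`), and the observed cohort mean SE
#'   (`observed`).
#' @export
permutation_null_se <- function(cohort, n_perm = 5000L, seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  sessions <- cohort_sessions(cohort)
  choices <- lapply(sessions, `[[`, "choice")
  observed <- mean(vapply(choices, se_index, numeric(1), mode = "independent"))
  set.seed(seed)
  null_dist <- vapply(seq_len(n_perm), function(i) {
    mean(vapply(choices, function(ch) {
      se_index(sample(ch), mode = "independent")
    }, numeric(1)))
  }, numeric(1))
  list(null_mean = mean(null_dist), null_distribution = null_dist,
       observed = observed, n_perm = n_perm, seed = seed)
}

#' Net score of a session
#'
#' The classical IGT performance measure: number of advantageous
#' (decks C and D, coded 3 and 4) minus disadvantageous (A and B,
#' coded 1 and 2) selections.
#'
#' @param session a per-subject data frame, or an integer choice
#'   vector.
#' @return integer net score.
#' @export
net_score <- function(session) {
  choices <- if (is.data.frame(session)) session$choice else session
  sum(choices %in% c(3L, 4L)) - sum(choices %in% c(1L, 2L))
}

#' Linear and quadratic relation between SE and performance
#'
#' Regresses each subject's SE index on their standardized net score
#' and its square (least squares). High performers need fewer
#' exploratory trials, giving a negative linear trend, while the
#' worst performers persevere and also show little SE — an inverted-U
#' captured by the quadratic term.
#'
#' @param cohort an [igt_cohort()] with at least 4 subjects.
#' @param mode SE window mode; sliding windows maximize sensitivity
#'   for interindividual differences.
#' @return data frame with one row per term (`linear`, `quadratic`):
#'   `estimate`, `t`, `p` (two-sided).
#' @export
se_performance_glm <- function(cohort, mode = "sliding") {
  sessions <- cohort_sessions(cohort)
  if (length(sessions) < 4L) stop("need at least 4 subjects")
  se <- vapply(sessions, function(s) se_index(s$choice, mode), numeric(1))
  ns <- vapply(sessions, net_score, numeric(1))
  if (sd(ns) == 0) stop("degenerate design: net score is constant")
  z <- (ns - mean(ns)) / sd(ns)
  fit <- lm(se ~ z + I(z^2))
  sm <- summary(fit)$coefficients
  data.frame(term = c("linear", "quadratic"),
             estimate = sm[c("z", "I(z^2)"), "Estimate"],
             t = sm[c("z", "I(z^2)"), "t value"],
             p = sm[c("z", "I(z^2)"), "Pr(>|t|)"],
             row.names = NULL)
}

#' d-prime of a model's sensitivity to SE events
#'
#' How well a simulated cohort predicts where the real cohort's SE
#' events fall. Sliding windows are pooled over all subjects; the hit
#' rate is the probability that a simulated window is an SE event
#' given the matching real window is, the false-alarm rate the same
#' given it is not, and `d' = z(hit) - z(fa)`. Rates of exactly 0 or
#' 1 are handled by the log-linear correction (0.5 added to each cell
#' count), which caps the attainable d-prime.
#'
#' @param real,simulated matched [igt_cohort()]s (same subjects in
#'   the same order, same session lengths).
#' @return list with `dprime`, `hit_rate`, `fa_rate`, and the pooled
#'   window counts.
#' @export
se_dprime <- function(real, simulated) {
  rs <- cohort_sessions(real)
  ss <- cohort_sessions(simulated)
  if (length(rs) != length(ss)) stop("cohorts have different subject counts")
  real_ev <- logical(0); sim_ev <- logical(0)
  for (i in seq_along(rs)) {
    if (nrow(rs[[i]]) != nrow(ss[[i]])) stop("session length mismatch")
    real_ev <- c(real_ev, se_events(rs[[i]]$choice, "sliding"))
    sim_ev <- c(sim_ev, se_events(ss[[i]]$choice, "sliding"))
  }
  n_sig <- sum(real_ev); n_noise <- sum(!real_ev)
  if (n_sig == 0L || n_noise == 0L) stop("no windows in one response class")
  # log-linear corrected rates
  hit <- (sum(sim_ev & real_ev) + 0.5) / (n_sig + 1)
  fa <- (sum(sim_ev & !real_ev) + 0.5) / (n_noise + 1)
  list(dprime = qnorm(hit) - qnorm(fa), hit_rate = hit, fa_rate = fa,
       n_signal = n_sig, n_noise = n_noise)
}

#' Total SE events (sliding windows) per cohort
#'
#' Counts sliding-window SE events in a real cohort and in each of a
#' set of model-simulated cohorts; the model family reproducing
#' sequential exploration should approach the real count.
#'
#' @param real an [igt_cohort()].
#' @param simulated named list of [igt_cohort()]s with matching
#'   session lengths.
#' @return named numeric vector of event totals, first element `real`.
#' @export
se_event_counts <- function(real, simulated = list()) {
  count <- function(cohort) {
    sum(vapply(cohort_sessions(cohort), function(s) {
      sum(se_events(s$choice, "sliding"))
    }, numeric(1)))
  }
  n_real <- vapply(cohort_sessions(real), nrow, integer(1))
  for (sim in simulated) {
    n_sim <- vapply(cohort_sessions(sim), nrow, integer(1))
    if (!identical(unname(n_real), unname(n_sim))) {
      stop("simulated cohort session lengths do not match the real cohort")
    }
  }
  c(real = count(real), vapply(simulated, count, numeric(1)))
}

#' Two-group comparison of a per-subject quantity
#'
#' Reports group means and SDs plus both the Wilcoxon rank-sum test
#' (expressed as a normal-approximation z) and the two-sample t-test,
#' the two tests used in the field for parameter and SE-index group
#' contrasts respectively.
#'
#' @param values numeric per-subject values.
#' @param groups group label per subject (exactly 2 distinct values,
#'   each with at least 2 subjects).
#' @return data frame with one row per group pair: group means/SDs,
#'   `z` and `p_ranksum`, `t`, `df`, `p_t`.
#' @export
compare_groups <- function(values, groups) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2L) stop("need at least 2 groups")
  out <- NULL
  for (i in seq_len(length(lv) - 1L)) for (j in seq((i + 1L), length(lv))) {
    x <- values[groups == lv[i]]; y <- values[groups == lv[j]]
    if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 subjects")
    wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
    # z from the normal approximation of the rank-sum statistic
    n1 <- length(x); n2 <- length(y)
    mu <- n1 * n2 / 2
    r <- rank(c(x, y))
    ties <- table(r)
    sigma <- sqrt(n1 * n2 / 12 * (n1 + n2 + 1 -
                    sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1))))
    z <- (wt$statistic - mu) / sigma
    tt <- t.test(x, y)
    out <- rbind(out, data.frame(
      group1 = lv[i], group2 = lv[j],
      mean1 = mean(x), sd1 = sd(x), mean2 = mean(y), sd2 = sd(y),
      z = as.numeric(z), p_ranksum = wt$p.value,
      t = as.numeric(tt$statistic), df = as.numeric(tt$parameter),
      p_t = tt$p.value))
  }
  rownames(out) <- NULL
  out
}

#' Spearman association of fitted parameters with a behavioral metric
#'
#' @param fits an `igt_cohort_fit`.
#' @param behavior numeric per-subject metric, in the fit table's
#'   subject order (e.g. SE index or net score).
#' @return data frame with one row per parameter: `rho`, `p`, and a
#'   `degenerate` flag for constant parameter vectors (undefined rho).
#' @export
parameter_associations <- function(fits, behavior) {
  tab <- fits$table
  if (nrow(tab) < 5L) stop("need at least 5 subjects")
  if (length(behavior) != nrow(tab)) stop("behavior length mismatch")
  pars <- model_spec(fits$model)$params$name
  out <- do.call(rbind, lapply(pars, function(p) {
    v <- tab[[p]]
    if (sd(v) == 0 || sd(behavior) == 0) {
      data.frame(parameter = p, rho = NA_real_, p = NA_real_, degenerate = TRUE)
    } else {
      ct <- suppressWarnings(cor.test(v, behavior, method = "spearman"))
      data.frame(parameter = p, rho = as.numeric(ct$estimate),
                 p = ct$p.value, degenerate = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}
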