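.model_code <- function(name) {
  match(name, c("VSE", "VSE_LA", "EV", "PVL", "PVL_Delta", "VPP", "ORL"))
}

#' Map unconstrained (raw) parameters to their natural scale
#'
#' Fitting is done in an unconstrained raw space where every parameter
#' carries a Gaussian prior of mean 0 and variance 3 — a prior chosen
#' because its sigmoid transform is approximately uniform on \[0,1\].
#' Bounded parameters map through `lower + (upper - lower) *
#' sigmoid(raw)` (so \[-1,1\] is "times 2, minus 1", etc.); unbounded
#' parameters (the exploration bonus `phi`, the ORL weights) pass
#' through identically. The map is strictly monotone and invertible
#' (see [untransform_parameters()]).
#'
#' @param raw numeric vector of unconstrained values, in the model's
#'   parameter order.
#' @param model a [model_spec()] or model name.
#' @return named numeric vector on the natural scale.
#' @export
transform_parameters <- function(raw, model) {
  model <- as_model_spec(model)
  p <- model$params
  if (length(raw) != model$k) stop("expected ", model$k, " raw parameters")
  sig <- 1 / (1 + exp(-raw))
  nat <- ifelse(is.na(p$lower), raw, p$lower + (p$upper - p$lower) * sig)
  setNames(as.numeric(nat), p$name)
}

#' Inverse of [transform_parameters()]
#'
#' @param natural named or ordered numeric vector on the natural scale
#'   (strictly inside the bounds for bounded parameters).
#' @param model a [model_spec()] or model name.
#' @return numeric vector in raw space.
#' @export
untransform_parameters <- function(natural, model) {
  model <- as_model_spec(model)
  p <- model$params
  natural <- as.numeric(natural)
  raw <- ifelse(is.na(p$lower), natural, {
    u <- (natural - p$lower) / (p$upper - p$lower)
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    log(u / (1 - u))
  })
  as.numeric(raw)
}

.log_prior <- function(raw) sum(dnorm(raw, mean = 0, sd = sqrt(3), log = TRUE))

#' Log-likelihood of a session under a model
#'
#' Runs the model's latent-state recursion over the session and sums
#' the log probability of each observed choice (floored at 1e-12 to
#' keep degenerate parameter proposals finite). A model with zero
#' consistency yields exactly `T * log(1/4)`.
#'
#' @param session data frame with columns `choice`, `gain`, `loss`
#'   ordered by trial (one element of [cohort_sessions()]).
#' @param model a [model_spec()] or model name.
#' @param params named natural-scale parameter vector.
#' @param details if `TRUE`, also return the per-trial probability
#'   matrix and the probability of each actually-chosen deck.
#' @return the scalar log-likelihood, or (with `details = TRUE`) a
#'   list `loglik`, `probs` (T x 4), `p_choice`.
#' @export
session_log_likelihood <- function(session, model, params, details = FALSE) {
  model <- as_model_spec(model)
  res <- .session_loglik_cpp(.model_code(model$name),
                             as.integer(session$choice),
                             as.numeric(session$gain),
                             as.numeric(session$loss),
                             as.numeric(params[model$params$name]))
  if (details) res else res$loglik
}

# Reference implementation of the likelihood: steps the exported R
# update functions trial by trial. Used to validate the compiled path.
session_log_likelihood_r <- function(session, model, params) {
  model <- as_model_spec(model)
  state <- init_state(model)
  ll <- 0
  for (t in seq_len(nrow(session))) {
    p <- choice_probabilities(state, params, model, t = t)
    pc <- max(p[session$choice[t]], 1e-12)
    ll <- ll + log(pc)
    state <- competitor_update(model, state, session$choice[t],
                               session$gain[t], session$loss[t], params)
  }
  ll
}

#' Akaike and Bayesian information criteria
#'
#' `AIC = -2 LL + 2 k`; `BIC = -2 LL + k log T`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters (nonnegative).
#' @param n_trials number of trials T.
#' @return named numeric vector `c(AIC, BIC)`.
#' @export
information_criteria <- function(loglik, k, n_trials) {
  if (k < 0) stop("k must be nonnegative")
  if (n_trials < 1) stop("n_trials must be >= 1")
  c(AIC = -2 * loglik + 2 * k, BIC = -2 * loglik + k * log(n_trials))
}

#' Fit one session by MAP with multistart and Laplace evidence
#'
#' Maximizes the log-joint (log-likelihood plus the raw-space Gaussian
#' prior, mean 0, variance 3, on every parameter) over the
#' unconstrained raw space, from `restarts` starting points (the prior
#' mean plus prior draws), with a quasi-Newton polish. The model
#' log-evidence is approximated by the Laplace formula
#' `F = logJoint(MAP) + (k/2) log(2 pi) - 0.5 log det H`, where H is
#' the finite-difference negative Hessian of the log-joint at the MAP;
#' when H is not positive definite the fit falls back to `-BIC/2` with
#' a diagnostic flag.
#'
#' @param session a per-subject data frame (see [cohort_sessions()]).
#' @param model a [model_spec()] or model name.
#' @param restarts number of optimizer starts (>= 1).
#' @param seed integer seed controlling the start points.
#' @param tol convergence tolerance on the objective.
#' @param use_prior if `FALSE`, drop the raw-space prior and return
#'   the maximum-likelihood fit instead of the MAP (the Laplace
#'   evidence is then computed from the bare likelihood surface).
#' @return an object of class `igt_fit`: raw and natural MAP
#'   parameters, `loglik`, `AIC`, `BIC`, `evidence` (Laplace F),
#'   `accuracy`, per-trial `p_choice`, and diagnostics.
#' @export
fit_session <- function(session, model, restarts = 10L, seed = 1L, tol = 1e-6,
                        use_prior = TRUE) {
  model <- as_model_spec(model)
  k <- model$k
  n_t <- nrow(session)
  ch <- as.integer(session$choice)
  gn <- as.numeric(session$gain)
  ls <- as.numeric(session$loss)
  code <- .model_code(model$name)

  neg_log_joint <- function(raw) {
    if (any(!is.finite(raw)) || any(abs(raw) > 50)) return(1e10)
    ll <- .session_loglik_cpp(code, ch, gn, ls,
                              transform_parameters(raw, model))$loglik
    -(ll + if (use_prior) .log_prior(raw) else 0)
  }

  set.seed(seed)
  starts <- rbind(rep(0, k),
                  matrix(rnorm((restarts - 1L) * k, 0, sqrt(3)),
                         ncol = k, nrow = max(restarts - 1L, 0L)))
  best <- NULL
  n_conv <- 0L
  for (i in seq_len(nrow(starts))) {
    opt <- tryCatch(
      optim(starts[i, ], neg_log_joint, method = "BFGS",
            control = list(maxit = 500L, reltol = tol)),
      error = function(e) NULL
    )
    if (is.null(opt)) next
    if (opt$convergence == 0L) n_conv <- n_conv + 1L
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) { # all starts failed; evaluate at the prior mean
    best <- list(par = rep(0, k), value = neg_log_joint(rep(0, k)),
                 convergence = 1L)
  }

  raw_map <- best$par
  nat <- transform_parameters(raw_map, model)
  det_res <- session_log_likelihood(session, model, nat, details = TRUE)
  ll <- det_res$loglik
  ic <- information_criteria(ll, k, n_t)
  log_joint <- -best$value

  # Laplace approximation of the log model evidence
  H <- tryCatch(optimHess(raw_map, neg_log_joint), error = function(e) NULL)
  laplace_ok <- FALSE
  evidence <- -ic[["BIC"]] / 2
  if (!is.null(H)) {
    eh <- eigen(0.5 * (H + t(H)), symmetric = TRUE, only.values = TRUE)$values
    if (all(eh > 0)) {
      evidence <- log_joint + (k / 2) * log(2 * pi) - 0.5 * sum(log(eh))
      laplace_ok <- TRUE
    }
  }
  if (!laplace_ok) {
    warning("Hessian not positive definite; evidence fell back to -BIC/2")
  }

  acc <- mean(vapply(seq_len(n_t), function(t) {
    p <- det_res$probs[t, ]
    as.numeric(sum(p >= max(p) - 1e-12) == 1L && which.max(p) == ch[t])
  }, numeric(1)))

  structure(
    list(model = model$name, raw = raw_map, params = nat,
         loglik = ll, AIC = ic[["AIC"]], BIC = ic[["BIC"]],
         evidence = as.numeric(evidence), laplace_ok = laplace_ok,
         accuracy = acc, p_choice = det_res$p_choice, probs = det_res$probs,
         n_trials = n_t, restarts = nrow(starts), n_converged = n_conv,
         converged = n_conv > 0L, seed = seed),
    class = "igt_fit"
  )
}

#' @export
print.igt_fit <- function(x, ...) {
  cat(sprintf("<igt_fit> %s  LL = %.2f  AIC = %.1f  BIC = %.1f  F = %.2f\n",
              x$model, x$loglik, x$AIC, x$BIC, x$evidence))
  print(round(x$params, 4))
  invisible(x)
}

#' Fit every subject of a cohort under one model
#'
#' @param cohort an [igt_cohort()].
#' @param model a [model_spec()] or model name.
#' @param restarts,seed,tol,use_prior passed to [fit_session()]; each
#'   subject gets a distinct seed derived from `seed`.
#' @return an object of class `igt_cohort_fit`: a list with `fits`
#'   (per-subject `igt_fit`s) and `table` (one row per subject with
#'   natural parameters, LL, AIC, BIC, F, accuracy).
#' @export
fit_cohort <- function(cohort, model, restarts = 10L, seed = 1L, tol = 1e-6,
                       use_prior = TRUE) {
  model <- as_model_spec(model)
  sessions <- cohort_sessions(cohort)
  fits <- vector("list", length(sessions))
  names(fits) <- names(sessions)
  for (i in seq_along(sessions)) {
    fits[[i]] <- fit_session(sessions[[i]], model, restarts = restarts,
                             seed = (seed + i - 1L) %% .Machine$integer.max,
                             tol = tol, use_prior = use_prior)
  }
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(subject = names(fits)[i], t(f$params), loglik = f$loglik,
               AIC = f$AIC, BIC = f$BIC, evidence = f$evidence,
               accuracy = f$accuracy, converged = f$converged,
               check.names = FALSE)
  }))
  rownames(tab) <- NULL
  if ("group" %in% names(cohort)) {
    grp <- cohort$group[!duplicated(cohort$subject)]
    tab$group <- grp[match(tab$subject, unique(cohort$subject))]
  }
  structure(list(model = model$name, fits = fits, table = tab),
            class = "igt_cohort_fit")
}

#' @export
print.igt_cohort_fit <- function(x, ...) {
  cat(sprintf("<igt_cohort_fit> model %s, %d subjects\n",
              x$model, length(x$fits)))
  cat(sprintf("  summed: LL = %.1f  AIC = %.1f  BIC = %.1f  F = %.1f\n",
              sum(x$table$loglik), sum(x$table$AIC), sum(x$table$BIC),
              sum(x$table$evidence)))
  invisible(x)
}

#' Strict-argmax prediction accuracy of a fit
#'
#' The fraction of trials on which the actually-chosen deck carries
#' the strictly highest predicted probability (1 if so, 0 otherwise;
#' chance level for a random guesser is 25%). Trials where the maximum
#' is tied score 0, so a uniform model scores exactly 0.
#'
#' @param fit an `igt_fit` produced on `session`.
#' @param session the same session the fit was produced on.
#' @return fraction in \[0,1\].
#' @export
predictive_accuracy <- function(fit, session) {
  if (fit$n_trials != nrow(session)) stop("session length mismatch")
  ch <- as.integer(session$choice)
  mean(vapply(seq_len(nrow(session)), function(t) {
    p <- fit$probs[t, ]
    as.numeric(sum(p >= max(p) - 1e-12) == 1L && which.max(p) == ch[t])
  }, numeric(1)))
}
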