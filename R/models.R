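#' Model registry for IGT reinforcement-learning architectures
#'
#' Returns the specification of one of the seven supported model
#' architectures:
#'
#' * `VSE` (5 parameters): value sensitivity `theta` \[0,1\] applied
#'   separately to gains and losses, decay `delta` \[0,1\] of
#'   exploitation weights, exploration learning rate `alpha` \[0,1\],
#'   exploration bonus `phi` (unbounded; negative values encode
#'   familiarity preference), and consistency `cons` \[0,5\] entering
#'   the softmax as C = 3^cons - 1.
#' * `VSE_LA` (6): the VSE with the exploitation utility replaced by
#'   the prospect transform of the net outcome (adds loss aversion
#'   `lambda` \[0,5\]).
#' * `EV` (3): delta-rule learning of `(1-w)*gain - w*loss` with
#'   learning rate `a` \[0,1\], attention weight `w` \[0,1\], and a
#'   trial-dependent consistency `cons` \[-2,2\], C(t) = (t/10)^cons.
#' * `PVL` (4): decay-rule learning of the prospect utility (decay
#'   `delta`, sensitivity `nu` \[0,1\], loss aversion `lambda` \[0,5\],
#'   consistency `cons` \[0,5\]).
#' * `PVL_Delta` (4): as PVL but with a delta rule (learning rate `a`).
#' * `VPP` (8): PVL-Delta plus a perseveration module (gain/loss
#'   persistence `eps_gain` \[0,1\], `eps_loss` \[-1,1\], perseveration
#'   decay `delta_pers` \[-1,1\], expectancy weight `w_ev` \[0,1\]).
#' * `ORL` (5): delta-rule value and outcome-frequency tracking with
#'   separate reward/punishment learning rates `a_rew`, `a_pun`
#'   \[0,1\], hyperbolic perseveration decay `K` \[0,242\], and two
#'   unbounded weights `w_f`, `w_p` on frequency and perseveration;
#'   softmax sensitivity is fixed at 1.
#'
#' @param name model name, one of `"VSE"`, `"VSE_LA"`, `"EV"`,
#'   `"PVL"`, `"PVL_Delta"`, `"VPP"`, `"ORL"`.
#' @return a `model_spec` list with elements `name`, `params` (data
#'   frame of name/lower/upper; `NA` bounds mean unbounded), and `k`
#'   (parameter count).
#' @export
model_spec <- function(name) {
  name <- match.arg(name, igt_models())
  par <- function(nm, lo, hi) data.frame(name = nm, lower = lo, upper = hi)
  params <- switch(name,
    VSE = rbind(par("theta", 0, 1), par("delta", 0, 1), par("alpha", 0, 1),
                par("phi", NA, NA), par("cons", 0, 5)),
    VSE_LA = rbind(par("nu", 0, 1), par("lambda", 0, 5), par("delta", 0, 1),
                   par("alpha", 0, 1), par("phi", NA, NA), par("cons", 0, 5)),
    EV = rbind(par("a", 0, 1), par("w", 0, 1), par("cons", -2, 2)),
    PVL = rbind(par("delta", 0, 1), par("nu", 0, 1), par("lambda", 0, 5),
                par("cons", 0, 5)),
    PVL_Delta = rbind(par("a", 0, 1), par("nu", 0, 1), par("lambda", 0, 5),
                      par("cons", 0, 5)),
    VPP = rbind(par("a", 0, 1), par("nu", 0, 1), par("lambda", 0, 5),
                par("cons", 0, 5), par("eps_gain", 0, 1), par("eps_loss", -1, 1),
                par("delta_pers", -1, 1), par("w_ev", 0, 1)),
    ORL = rbind(par("a_rew", 0, 1), par("a_pun", 0, 1), par("K", 0, 242),
                par("w_f", NA, NA), par("w_p", NA, NA))
  )
  rownames(params) <- params$name
  structure(list(name = name, params = params, k = nrow(params)),
            class = "model_spec")
}

#' Names of the supported model architectures
#' @return character vector.
#' @export
igt_models <- function() {
  c("VSE", "VSE_LA", "EV", "PVL", "PVL_Delta", "VPP", "ORL")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%d parameters)\n", x$name, x$k))
  print(x$params, row.names = FALSE)
  invisible(x)
}

#' Initialize the latent state of a model
#'
#' All hidden values start at 0 except the exploration weights, which
#' start at 1: before any deck has been sampled, every deck carries a
#' unit novelty attraction. Initial values are fixed, never estimated.
#'
#' @param model a [model_spec()] or model name.
#' @return a `latent_state` list with numeric 4-vectors `exploit`,
#'   `explore`, `pers`, `freq` and the model name.
#' @export
init_state <- function(model) {
  model <- as_model_spec(model)
  structure(
    list(exploit = numeric(4L), explore = rep(1, 4L),
         pers = numeric(4L), freq = numeric(4L), model = model$name),
    class = "latent_state"
  )
}

as_model_spec <- function(model) {
  if (inherits(model, "model_spec")) model else model_spec(model)
}

#' VSE outcome utility
#'
#' The value-sensitivity transform applied separately to the gain and
#' the loss magnitude: `v = gain^theta - loss^theta`. By convention
#' `0^0 = 0`, so a zero gain or zero loss contributes nothing at any
#' `theta`, including `theta = 0`.
#'
#' @param gain,loss nonnegative amounts (loss as a magnitude).
#' @param theta value sensitivity in \[0,1\].
#' @return finite scalar utility.
#' @export
vse_utility <- function(gain, loss, theta) {
  if (any(gain < 0) || any(loss < 0)) stop("gain and loss must be nonnegative")
  pow0 <- function(x, p) ifelse(x == 0, 0, x^p)
  pow0(gain, theta) - pow0(loss, theta)
}

#' Prospect-theory utility of a net outcome
#'
#' Applied by the PVL family (PVL, PVL-Delta, VPP) and the loss-averse
#' VSE variant to the net outcome `x = gain - loss`:
#' `u = x^nu` for `x >= 0`, `u = -lambda * |x|^nu` otherwise.
#'
#' @param gain,loss nonnegative amounts.
#' @param nu value sensitivity in \[0,1\].
#' @param lambda loss aversion in \[0,5\].
#' @return scalar utility.
#' @export
prospect_utility <- function(gain, loss, nu, lambda) {
  x <- gain - loss
  ifelse(x >= 0, ifelse(x == 0, 0, x^nu), -lambda * abs(x)^nu)
}

#' Consistency (softmax gain) of a model
#'
#' For VSE, VSE_LA, PVL, PVL-Delta and VPP the raw consistency
#' parameter `c` in \[0,5\] maps to `C = 3^c - 1`, so `c = 0` gives
#' uniform random choice and `c = 5` gives `C = 242`. The EV model
#' instead uses a trial-dependent consistency `C(t) = (t/10)^c` with
#' `c` in \[-2,2\]. The ORL has no consistency parameter; its softmax
#' sensitivity is fixed at 1.
#'
#' @param beta the model's consistency parameter on its natural scale.
#' @param model a [model_spec()] or model name.
#' @param t 1-based trial index (required for EV).
#' @return nonnegative scalar consistency.
#' @export
consistency_from_beta <- function(beta, model, t = NULL) {
  model <- as_model_spec(model)
  switch(model$name,
    EV = {
      if (is.null(t)) stop("EV consistency requires the trial index t")
      (t / 10)^beta
    },
    ORL = 1,
    3^beta - 1
  )
}

#' Per-deck composite value entering the softmax
#'
#' @param state a `latent_state`.
#' @param params named natural-scale parameter vector.
#' @param model a [model_spec()] or model name.
#' @return numeric 4-vector.
#' @export
deck_values <- function(state, params, model) {
  model <- as_model_spec(model)
  switch(model$name,
    VSE = ,
    VSE_LA = state$exploit + state$explore,
    VPP = params[["w_ev"]] * state$exploit + (1 - params[["w_ev"]]) * state$pers,
    ORL = state$exploit + params[["w_f"]] * state$freq + params[["w_p"]] * state$pers,
    state$exploit
  )
}

#' Softmax choice probabilities over the four decks
#'
#' `P(d) = exp(V_d * C) / sum_i exp(V_i * C)` with the composite value
#' V given by [deck_values()] and the consistency C by
#' [consistency_from_beta()]. Computed with max-subtraction so the
#' extreme `C = 242` regime cannot overflow.
#'
#' @inheritParams deck_values
#' @param t 1-based trial index (the EV consistency depends on it).
#' @return numeric 4-vector of probabilities summing to 1.
#' @export
choice_probabilities <- function(state, params, model, t = 1L) {
  model <- as_model_spec(model)
  v <- deck_values(state, params, model)
  if (any(!is.finite(v))) stop("non-finite latent state")
  cons_par <- if (model$name == "ORL") 0 else params[["cons"]]
  C <- consistency_from_beta(cons_par, model, t)
  z <- v * C
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' One VSE learning step
#'
#' The chosen deck's exploitation weight decays and absorbs the
#' experienced utility, and its exploration weight collapses to zero;
#' unchosen decks decay toward zero while their exploration weights
#' relax toward the exploration bonus `phi` at rate `alpha`.
#'
#' @param state a `latent_state`.
#' @param choice deck index 1--4.
#' @param gain,loss observed nonnegative amounts.
#' @param params named vector with `theta`, `delta`, `alpha`, `phi`
#'   (VSE) or `nu`, `lambda`, `delta`, `alpha`, `phi` (VSE_LA).
#' @param utility the scalar utility of the outcome; computed from the
#'   model's own transform when `NULL`.
#' @return the updated `latent_state`.
#' @export
vse_update <- function(state, choice, gain, loss, params, utility = NULL) {
  if (!(choice %in% 1:4)) stop("invalid deck: ", choice)
  if (is.null(utility)) {
    utility <- if (!is.null(state$model) && state$model == "VSE_LA") {
      prospect_utility(gain, loss, params[["nu"]], params[["lambda"]])
    } else {
      vse_utility(gain, loss, params[["theta"]])
    }
  }
  state$exploit <- state$exploit * params[["delta"]]
  state$exploit[choice] <- state$exploit[choice] + utility
  unchosen <- setdiff(1:4, choice)
  state$explore[unchosen] <- state$explore[unchosen] +
    params[["alpha"]] * (params[["phi"]] - state$explore[unchosen])
  state$explore[choice] <- 0
  state
}

#' One learning step of a competitor model
#'
#' Dispatches on the model name and applies its update rule: the EV
#' delta rule on the attention-weighted outcome; the PVL decay rule or
#' PVL-Delta delta rule on the prospect utility; the VPP rule (PVL-
#' Delta plus discounted perseveration with gain/loss increments); or
#' the ORL rule (sign-dependent learning rates for value and outcome
#' frequency, fictive updating of unchosen decks, hyperbolically
#' decayed perseveration). `VSE`/`VSE_LA` delegate to [vse_update()].
#'
#' @inheritParams vse_update
#' @param model a [model_spec()] or model name.
#' @return the updated `latent_state`.
#' @export
competitor_update <- function(model, state, choice, gain, loss, params) {
  model <- as_model_spec(model)
  if (!(choice %in% 1:4)) stop("invalid deck: ", choice)
  x <- gain - loss
  switch(model$name,
    VSE = ,
    VSE_LA = vse_update(state, choice, gain, loss, params),
    EV = {
      u <- (1 - params[["w"]]) * gain - params[["w"]] * loss
      state$exploit[choice] <- state$exploit[choice] +
        params[["a"]] * (u - state$exploit[choice])
      state
    },
    PVL = {
      u <- prospect_utility(gain, loss, params[["nu"]], params[["lambda"]])
      state$exploit <- state$exploit * params[["delta"]]
      state$exploit[choice] <- state$exploit[choice] + u
      state
    },
    PVL_Delta = {
      u <- prospect_utility(gain, loss, params[["nu"]], params[["lambda"]])
      state$exploit[choice] <- state$exploit[choice] +
        params[["a"]] * (u - state$exploit[choice])
      state
    },
    VPP = {
      u <- prospect_utility(gain, loss, params[["nu"]], params[["lambda"]])
      state$exploit[choice] <- state$exploit[choice] +
        params[["a"]] * (u - state$exploit[choice])
      state$pers <- state$pers * params[["delta_pers"]]
      inc <- if (x >= 0) params[["eps_gain"]] else params[["eps_loss"]]
      state$pers[choice] <- state$pers[choice] + inc
      state
    },
    ORL = {
      s <- sign(x)
      if (x >= 0) {
        state$exploit[choice] <- state$exploit[choice] +
          params[["a_rew"]] * (x - state$exploit[choice])
        state$freq[choice] <- state$freq[choice] +
          params[["a_rew"]] * (s - state$freq[choice])
        unchosen <- setdiff(1:4, choice)
        state$freq[unchosen] <- state$freq[unchosen] +
          params[["a_pun"]] * (-s / 3 - state$freq[unchosen])
      } else {
        state$exploit[choice] <- state$exploit[choice] +
          params[["a_pun"]] * (x - state$exploit[choice])
        state$freq[choice] <- state$freq[choice] +
          params[["a_pun"]] * (s - state$freq[choice])
        unchosen <- setdiff(1:4, choice)
        state$freq[unchosen] <- state$freq[unchosen] +
          params[["a_rew"]] * (-s / 3 - state$freq[unchosen])
      }
      state$pers[choice] <- 1
      state$pers <- state$pers / (1 + params[["K"]])
      state
    }
  )
}
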