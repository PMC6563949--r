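---
title: "Methods: models, estimation and sequential-exploration metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimation and sequential-exploration metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vseigt)
```

This vignette documents the mathematical content of the package: the seven
choice models, the estimation machinery, the model-comparison tools, the
model-free sequential-exploration (SE) metrics, and the numerical and design
decisions behind them.

## The task and its data

The Iowa Gambling Task presents four decks. On each trial the subject draws
one card and receives a gain and (sometimes) a loss. Decks 1 and 2 are
"disadvantageous" (high gains, larger expected losses), decks 3 and 4
"advantageous". A session is a sequence of `(choice, gain, loss)` triples;
a cohort stacks sessions over subjects, optionally with a group label.
`igt_cohort()` validates this layout, `read_cohort()` /`write_cohort()` read
and write it in a long CSV dialect (one row per trial) or a wide dialect
(one row per subject with `choice_*`, `wins_*`, `losses_*` blocks).

## The VSE model

VSE (Value plus Sequential Exploration) holds two value systems per deck.

**Exploitation.** The outcome of a draw is collapsed to a utility
$$v_t = \mathrm{gain}_t^{\,\theta} - \mathrm{loss}_t^{\,\theta},
\qquad \theta \in [0, 1],$$
with the convention $0^0 = 0$ so that an absent gain or loss contributes
nothing even at $\theta = 0$. Exploit values decay every trial and the chosen
deck absorbs the utility:
$$\mathrm{Exploit}_{d,t+1} =
  \begin{cases}
  \mathrm{Exploit}_{d,t}\,\Delta + v_t & d \text{ chosen}\\
  \mathrm{Exploit}_{d,t}\,\Delta & \text{otherwise,}
  \end{cases}
\qquad \Delta \in [0,1].$$

**Directed exploration.** Each deck carries an exploration bonus that resets
on sampling and relaxes toward an asymptote $\varphi$ while unvisited:
$$\mathrm{Explore}_{d,t+1} =
  \begin{cases}
  0 & d \text{ chosen}\\
  \mathrm{Explore}_{d,t} + \alpha\,(\varphi - \mathrm{Explore}_{d,t})
    & \text{otherwise,}
  \end{cases}
\qquad \alpha \in [0,1],\ \varphi \in \mathbb{R}.$$
A positive $\varphi$ makes recently unsampled decks attractive and produces
systematic deck cycling; a negative $\varphi$ produces perseveration.
All states start at zero except the exploration bonuses, which start at 1,
so all four decks are equally attractive before the first draw.

**Choice rule.** Both systems sum and enter a softmax,
$$P(d) \propto \exp\!\big[(\mathrm{Explore}_d + \mathrm{Exploit}_d)\,C\big],
\qquad C = 3^{\beta} - 1,\ \beta \in [0, 5],$$
so consistency $C$ ranges over $[0, 242]$; $\beta = 0$ gives uniform random
choice regardless of values.

## Competitor models

| Model | k | Parameters (range) | Sketch |
|---|---|---|---|
| EV | 3 | $a\in[0,1]$, $w\in[0,1]$, $c\in[-2,2]$ | utility $(1-w)\,\mathrm{gain} - w\,\mathrm{loss}$; delta rule with rate $a$; trial-dependent consistency $C(t) = (t/10)^c$ |
| PVL | 4 | $\Delta, \nu \in[0,1]$, $\lambda\in[0,5]$, $\beta\in[0,5]$ | prospect utility $u(x)=x^\nu$ for $x \ge 0$, $-\lambda\lvert x\rvert^\nu$ otherwise, applied to the net outcome; decay rule |
| PVL-Delta | 4 | as PVL with learning rate $a$ | prospect utility; delta rule |
| VPP | 8 | PVL-Delta $+\ \epsilon_{gain},\epsilon_{loss}\in[-1,1]$, $\Delta_{pers}\in[0,1]$, $\omega_{Ev}\in[0,1]$ | adds a perseveration trace that decays by $\Delta_{pers}$ and is bumped by $\epsilon_{gain}$ or $\epsilon_{loss}$ on the chosen deck; value $=\omega_{Ev}\,\mathrm{Ev} + (1-\omega_{Ev})\,\mathrm{pers}$ |
| ORL | 5 | $a_{rew}, a_{pun}\in[0,1]$, $K\in[0,242]$, $w_f, w_p\in\mathbb{R}$ | sign-switched learning rates update expected value and a fictive outcome-frequency signal (chosen deck toward the outcome sign $s$, unchosen toward $-s/3$); perseveration sets the chosen deck to 1 then divides all decks by $1+K$; softmax sensitivity fixed at 1 |
| VSE_LA | 6 | VSE with $\theta$ replaced by $\nu\in[0,1]$, $\lambda\in[0,5]$ | loss-averse VSE: prospect utility $\mathrm{gain}^\nu - \lambda\,\mathrm{loss}^\nu$ |

ORL uses no free consistency parameter: its value, frequency and
perseveration weights already set the scale of the softmax argument, so the
sensitivity is fixed at 1 and the model has five parameters. `model_spec()`
returns each model's parameter table (name, lower, upper; `NA` = unbounded)
and is the single source of parameter order everywhere, including the
compiled likelihood.

## Likelihood and estimation

`session_log_likelihood()` runs the exact state recursion of a model over an
observed session and sums `log P(choice_t)`. The recursion is implemented
once in C++ (`src/likelihood.cpp`) for speed and once in plain R; the test
suite checks the two agree to machine precision for every model.

**Numerical choices.**

* Choice probabilities use a max-subtracted softmax and are floored at
  `1e-12` before taking logs, so a single surprising choice cannot produce
  `-Inf` and destroy the optimization surface.
* Bounded parameters are optimized in an unconstrained *raw* space via
  `natural = lower + (upper - lower) / (1 + exp(-raw))`; unbounded
  parameters ($\varphi$, ORL's $w_f$, $w_p$) pass through the identity.
  `transform_parameters()` / `untransform_parameters()` are exact inverses.
* Each raw coordinate has a Gaussian prior with mean 0 and variance 3. Under
  the sigmoid map this is close to uniform on the natural interval (checked
  by a histogram test), so the prior mostly regularizes the tails.
* `fit_session()` maximizes the log joint with multistart BFGS: one start at
  the raw origin plus `restarts` draws from the prior, seeded
  deterministically. Raw values beyond $\pm 50$ are rejected with a large
  penalty to keep the sigmoid out of its flat asymptotes.
* Model evidence uses the Laplace approximation
  $F = \log p(y, \hat\vartheta) + \tfrac{k}{2}\log 2\pi
     - \tfrac12 \log\det H$ with $H$ the negative Hessian from
  `optimHess()`. If $H$ is not positive definite, the fit falls back to
  $-\mathrm{BIC}/2$ and warns (`laplace_ok = FALSE`).
* `information_criteria()` is plain arithmetic:
  $\mathrm{AIC} = -2\ell + 2k$, $\mathrm{BIC} = -2\ell + k\log T$.
* `predictive_accuracy()` scores one-step-ahead predictions by strict
  argmax: a trial whose predicted maximum is tied across decks scores 0,
  so a zero-consistency fit earns 0, not 25%.

## Model comparison

`evidence_matrix()` assembles subject-by-model evidences as $-\mathrm{AIC}/2$,
$-\mathrm{BIC}/2$ or the Laplace $F$. Two regimes:

* **Fixed effect** (`fixed_effect_table()`): criteria are summed over
  subjects; differences above 100 on the criterion scale ($-2F$ for the
  evidence metric) are flagged "decisive".
* **Random effects** (`rfx_bms()`): the variational Bayes scheme for group
  model comparison — responsibilities
  $u_{nk} \propto \exp[E_{nk} + \psi(\alpha_k) - \psi(\sum_j \alpha_j)]$,
  Dirichlet update $\alpha_k = 1 + \sum_n u_{nk}$, iterated to a $10^{-6}$
  tolerance. Exceedance probabilities are estimated by Monte Carlo: draw
  from the posterior Dirichlet via normalized Gamma variates and count how
  often each model's frequency is the largest.

## Sequential-exploration metrics

An *SE event* is a window of four consecutive trials visiting four distinct
decks. `se_index()` reports the fraction of event windows, with two window
schemes: `"independent"` (starts 1, 5, 9, …; 25 windows in a 100-trial
session) and `"sliding"` (starts 1…T−3; 97 windows). Under uniform random
choice a window is an event with probability $4!/4^4 = 24/256 = 9.375\%$
(`se_chance_probability()`, verified in the tests by enumerating all 256
quadruplets).

* `binomial_se_test()` — exact binomial upper-tail p-value for a pooled
  event count against a chance level.
* `permutation_null_se()` — per-subject shuffles of the observed choice
  sequence, preserving each subject's deck multiset; this is the right null
  when deck use is unbalanced (a perseverator has null SE identically 0).
* `se_performance_glm()` — linear model of per-subject SE on the
  standardized net score (advantageous minus disadvantageous picks,
  `net_score()`) and its square, to detect the inverted-U relation between
  exploration and performance.
* `se_dprime()` — signal detection on sliding windows pooled over subjects:
  a hit is a real-data event window matched by an event in the paired
  simulated session. Rates use the log-linear correction (add 0.5 to each
  cell) so perfect and empty cells give finite $d'$.
* `compare_groups()` — rank-sum z (with tie correction) plus Welch t-test;
  `parameter_associations()` — Spearman correlations between fitted
  parameters and a behavioral covariate, flagging degenerate (constant)
  columns.

## Simulation and recovery

`simulate_agent()` runs a model generatively against a payoff schedule.
Two schedules are provided:

* `canonical_schedule()` — the classic deck structure: gains of 100 per
  draw on decks 1–2 and 50 on decks 3–4; per block of ten draws, deck 1
  loses 5 × {150…350} (total 1250), deck 2 one single 1250, deck 3 loses
  {25, 50, 50, 50, 75} (total 250), deck 4 one single 250. Loss positions
  are shuffled within each block, so expected values are −25 per draw on
  decks 1–2 and +25 on decks 3–4.
* `empirical_schedule()` — resamples observed `(gain, loss)` pairs per deck
  from a cohort, for simulating against realistic payoff noise.

`simulate_cohort()` derives per-agent seeds as
`(seed + 7919 * i) mod .Machine$integer.max`, so a cohort is reproducible
and each agent's stream is independent. `draw_prior_parameters()` samples
natural parameters through the fitting prior, with a `fixed` argument to
pin a subset.

**Parameter recovery** (`parameter_recovery()`): simulate from known
parameters, fit, and correlate truth with estimates (Pearson and Spearman
per parameter). With `two_pass = TRUE` the design is instead: fit the
first-pass simulations, re-simulate from those *fitted* parameters, refit,
and correlate first-pass against second-pass estimates. The two-pass design
is the honest one for a model with structural non-identifiability pockets:
when $\alpha \approx 0$ freezes the exploration bonus, or exploitation
dwarfs $\varphi$, no optimizer can recover the generative $\varphi$ — the
data simply do not constrain it — whereas fits of refitted data measure the
reliability of the estimator on its own support. The acceptance-level
recovery test uses 50 prior-drawn subjects at consistency 4 (chosen a
priori as a clearly supra-random regime), 100 trials, and requires Spearman
$\rho \ge 0.8$ for $\varphi$.

**Model recovery** (`model_recovery()`): simulate cohorts under several
generators, fit every cohort with every model, and report confusion
matrices of the fixed-effect winner under AIC, BIC and $F$, plus
random-effects BMS on the AIC evidences.

## Problem sizes used in the package's own checks

The test suite runs at the study scale: 100-trial sessions, cohorts of
20–50 simulated subjects for recovery, one 504-agent uniform cohort for the
chance-level check, $10^5$ Monte Carlo samples for exceedance
probabilities, and a recovery curve over $T \in \{50, 100, 400\}$ that
must improve monotonically with session length.

## Limitations

* Estimation is MAP with a Laplace evidence, not full variational or MCMC
  posteriors; parameter uncertainty within subject is summarized only
  through the local curvature, and the evidence is exact only to second
  order around the mode.
* The raw-space prior is a pragmatic regularizer, not an elicited prior;
  for unbounded parameters it is a genuine (if weak) shrinkage toward 0.
* Recovery of the exploration parameters degrades at low consistency or
  $\alpha \approx 0$; this is a property of the model class, not of the
  optimizer, and is why the recovery contract is stated in the two-pass
  design.
* The ORL variant implemented here fixes softmax sensitivity at 1 and
  carries five parameters; other formulations in the literature add a free
  sensitivity.
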