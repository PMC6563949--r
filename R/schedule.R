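#' Canonical IGT payoff schedule
#'
#' The classical four-deck schedule: decks A and B (1, 2) pay a 100
#' gain on every draw but lose 1250 per block of 10 draws (deck A as
#' five graded losses of 150--350, deck B as a single 1250 loss); decks
#' C and D (3, 4) pay 50 per draw and lose only 250 per block (deck C
#' as five small losses of 25--75, deck D as a single 250 loss). Every
#' draw yields a gain, so A and B are net -250 per block and C and D
#' net +250 per block. Loss positions (and, for A and C, loss
#' magnitudes) are shuffled within each 10-draw block using the R
#' random number generator, so draws are reproducible under
#' [set.seed()].
#'
#' @return an object of class `payoff_schedule`.
#' @examples
#' sched <- canonical_schedule()
#' inst <- schedule_instance(sched)
#' draw_payoff(inst, deck = 4)
#' @export
canonical_schedule <- function() {
  structure(
    list(
      kind = "canonical",
      gains = c(100, 100, 50, 50),
      block_losses = list(
        c(150, 200, 250, 300, 350),
        1250,
        c(25, 50, 50, 50, 75),
        250
      )
    ),
    class = "payoff_schedule"
  )
}

#' Empirical-resampling payoff schedule
#'
#' Draws for deck d are uniform resamples, with replacement, of the
#' (gain, loss) pairs actually observed for deck d in the source
#' cohort. This keeps reward contingencies of simulated agents matched
#' to the data the cohort came from.
#'
#' @param cohort an [igt_cohort()] in which every deck was sampled at
#'   least once.
#' @return an object of class `payoff_schedule`.
#' @export
empirical_schedule <- function(cohort) {
  if (!inherits(cohort, "igt_cohort")) cohort <- igt_cohort(cohort)
  pools <- lapply(1:4, function(d) {
    rows <- cohort[cohort$choice == d, c("gain", "loss")]
    if (nrow(rows) == 0L) {
      stop(sprintf("deck %d was never sampled in the source cohort", d))
    }
    as.matrix(rows)
  })
  structure(list(kind = "empirical", pools = pools), class = "payoff_schedule")
}

#' @export
print.payoff_schedule <- function(x, ...) {
  cat(sprintf("<payoff_schedule> kind: %s\n", x$kind))
  invisible(x)
}

#' Instantiate a payoff schedule for sequential drawing
#'
#' A schedule instance carries mutable per-deck draw state (block
#' queues for the canonical schedule). Randomness comes from the R
#' RNG, so the caller controls reproducibility with [set.seed()].
#'
#' @param schedule a `payoff_schedule`.
#' @return an environment of class `schedule_instance`.
#' @export
schedule_instance <- function(schedule) {
  stopifnot(inherits(schedule, "payoff_schedule"))
  env <- new.env(parent = emptyenv())
  env$schedule <- schedule
  if (schedule$kind == "canonical") env$queues <- vector("list", 4L)
  class(env) <- "schedule_instance"
  env
}

#' Draw one (gain, loss) outcome from a schedule instance
#'
#' @param instance a [schedule_instance()].
#' @param deck deck index in 1--4.
#' @return numeric vector `c(gain, loss)`, both nonnegative.
#' @export
draw_payoff <- function(instance, deck) {
  stopifnot(inherits(instance, "schedule_instance"), deck %in% 1:4)
  sched <- instance$schedule
  if (sched$kind == "canonical") {
    q <- instance$queues[[deck]]
    if (is.null(q) || length(q) == 0L) {
      losses <- sched$block_losses[[deck]]
      block <- numeric(10L)
      block[sample.int(10L, length(losses))] <- losses[sample.int(length(losses))]
      q <- block
    }
    loss <- q[1L]
    instance$queues[[deck]] <- q[-1L]
    c(gain = sched$gains[deck], loss = loss)
  } else {
    pool <- sched$pools[[deck]]
    row <- pool[sample.int(nrow(pool), 1L), ]
    c(gain = row[["gain"]], loss = row[["loss"]])
  }
}
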