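#' Construct an IGT cohort from long-format trial data
#'
#' An `igt_cohort` is the universal input container of the package: a
#' data frame with one row per trial and columns `subject`, `trial`,
#' `choice`, `gain`, `loss` and optionally `group`. Decks are coded
#' 1--4 (A=1, B=2, C=3, D=4), so the advantageous decks C and D are
#' `{3, 4}`. Losses are stored as nonnegative magnitudes; the net
#' outcome of a trial is `gain - loss`.
#'
#' @param data data frame with columns `subject`, `trial`, `choice`,
#'   `gain`, `loss`, and optionally `group`.
#' @return an object of class `igt_cohort` (a validated data frame).
#' @examples
#' d <- data.frame(subject = "s1", trial = 1:4, choice = c(1, 2, 3, 4),
#'                 gain = c(100, 100, 50, 50), loss = c(0, 0, 50, 0))
#' igt_cohort(d)
#' @export
igt_cohort <- function(data) {
  required <- c("subject", "trial", "choice", "gain", "loss")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(data) == 0L) stop("cohort has no trials")
  keep <- c(required, if ("group" %in% names(data)) "group")
  data <- as.data.frame(data)[keep]
  data$subject <- as.character(data$subject)
  data <- data[order(match(data$subject, unique(data$subject)), data$trial), ,
               drop = FALSE]
  rownames(data) <- NULL
  # losses may arrive as negative amounts; store magnitudes
  data$loss <- abs(data$loss)
  validate_cohort(data)
  class(data) <- c("igt_cohort", "data.frame")
  data
}

validate_cohort <- function(data) {
  bad <- !(data$choice %in% 1:4)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("invalid deck choice %s for subject '%s', trial %d (must be 1-4)",
                 data$choice[i], data$subject[i], data$trial[i]))
  }
  if (any(data$gain < 0)) stop("gains must be nonnegative")
  for (s in split(data$trial, data$subject)) {
    if (!identical(as.integer(sort(s)), seq_len(length(s)))) {
      stop("trial indices must be contiguous 1..T within each subject")
    }
  }
  invisible(data)
}

#' @export
print.igt_cohort <- function(x, ...) {
  ns <- length(unique(x$subject))
  cat(sprintf("<igt_cohort> %d subject(s), %d trials total\n", ns, nrow(x)))
  if ("group" %in% names(x)) {
    g <- table(x$group[!duplicated(x$subject)])
    cat("  groups:", paste(sprintf("%s (n=%d)", names(g), g), collapse = ", "), "\n")
  }
  NextMethod()
}

#' Split a cohort into per-subject sessions
#'
#' @param cohort an [igt_cohort()].
#' @return named list of data frames, one per subject, ordered by trial.
#' @export
cohort_sessions <- function(cohort) {
  split(as.data.frame(cohort), factor(cohort$subject, levels = unique(cohort$subject)))
}

#' Number of subjects in a cohort
#' @param cohort an [igt_cohort()].
#' @return integer count.
#' @export
n_subjects <- function(cohort) length(unique(cohort$subject))

#' Read an IGT cohort from CSV
#'
#' Two dialects are supported. The long dialect has one row per trial
#' with header `subject,trial,choice,gain,loss` (optional `group`). The
#' wide dialect mirrors the layout of the open many-labs IGT data
#' tables: one row per subject with columns `choice_1..choice_T`,
#' `wins_1..wins_T`, `losses_1..losses_T`, plus `subject` and optional
#' `group`. Losses encoded as negative amounts are converted to
#' magnitudes on read.
#'
#' @param path CSV file path.
#' @param dialect `"long"` or `"wide"`.
#' @return an [igt_cohort()].
#' @export
read_cohort <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty file: ", path)
  if (dialect == "long") return(igt_cohort(raw))

  pick <- function(prefix) {
    cols <- grep(paste0("^", prefix, "_[0-9]+$"), names(raw), value = TRUE)
    if (length(cols) == 0L) stop("missing column block '", prefix, "_*' in wide file")
    cols[order(as.integer(sub(paste0("^", prefix, "_"), "", cols)))]
  }
  if (!"subject" %in% names(raw)) stop("missing column(s): subject")
  ch <- pick("choice"); wi <- pick("wins"); lo <- pick("losses")
  n_t <- length(ch)
  if (length(wi) != n_t || length(lo) != n_t) {
    stop("wide file blocks have unequal trial counts")
  }
  long <- data.frame(
    subject = rep(raw$subject, each = n_t),
    trial   = rep(seq_len(n_t), times = nrow(raw)),
    choice  = as.vector(t(as.matrix(raw[ch]))),
    gain    = as.vector(t(as.matrix(raw[wi]))),
    loss    = as.vector(t(as.matrix(raw[lo])))
  )
  if ("group" %in% names(raw)) long$group <- rep(raw$group, each = n_t)
  igt_cohort(long)
}

#' Write an IGT cohort to CSV (long dialect)
#'
#' The written file round-trips: `read_cohort(write_cohort(x, f))`
#' reproduces `x` exactly, including group labels.
#'
#' @param cohort an [igt_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (!inherits(cohort, "igt_cohort")) cohort <- igt_cohort(cohort)
  write.csv(as.data.frame(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
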