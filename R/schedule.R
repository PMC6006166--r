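#' Generate a probabilistic monetary learning task schedule
#'
#' Builds the trial schedule for the three-pair probabilistic learning task:
#' reward pairs (one stimulus wins \eqn{\pounds}1 with probability 0.8, the
#' other with probability 0.2, otherwise neutral feedback), bivalent pairs
#' (either stimulus wins or loses \eqn{\pounds}1 with probability 0.5 each)
#' and neutral pairs (two kinds of neutral feedback with 80/20 probabilities).
#' Each pair type appears \code{n_per_pair} times; with the default of 30
#' trials per pair the schedule has the standard 90 trials.
#'
#' Trial order is pseudo-randomised: a full shuffle constrained so that no
#' more than \code{max_run} consecutive trials share a pair type. The side of
#' the high-probability (or arbitrarily designated "correct") stimulus is
#' exactly counterbalanced within pair type, which is why \code{n_per_pair}
#' must be even. For bivalent pairs the two stimuli are equivalent; one is
#' designated "correct" at random (per seed) so that choice preferences can
#' be scored consistently.
#'
#' @param n_per_pair Positive even integer; trials per pair type (default 30).
#' @param seed Integer seed; schedules are reproducible from
#'   \code{(n_per_pair, seed)}.
#' @param max_run Maximum allowed run length of a single pair type.
#' @return An object of class \code{task_schedule}: a data frame with one row
#'   per trial and columns \code{trial}, \code{pair_type} (factor:
#'   reward/bivalent/neutral), \code{high_prob_side} ("left"/"right"),
#'   \code{correct_stimulus} ("s1"/"s2", the high-probability or designated
#'   stimulus within its pair). Attributes \code{n_per_pair} and \code{seed}
#'   record the generating parameters.
#' @examples
#' sch <- generate_schedule(30, seed = 1)
#' table(sch$pair_type)
#' @export
generate_schedule <- function(n_per_pair = 30L, seed = 1L, max_run = 4L) {
  if (length(n_per_pair) != 1L || !is.finite(n_per_pair) ||
      n_per_pair <= 0 || n_per_pair %% 2 != 0) {
    stop("`n_per_pair` must be a positive even integer (left/right counterbalancing)")
  }
  n_per_pair <- as.integer(n_per_pair)
  seed <- as.integer(seed)
  types <- c("reward", "bivalent", "neutral")

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)

  order <- shuffle_max_run(rep(types, each = n_per_pair), max_run)

  # exact counterbalancing of the correct stimulus side within each pair type
  side <- character(length(order))
  for (tp in types) {
    idx <- which(order == tp)
    s <- sample(rep(c("left", "right"), n_per_pair / 2L))
    side[idx] <- s
  }
  # which physical stimulus is "correct" (high-prob; arbitrary for bivalent)
  correct_stim <- vapply(types, function(tp) sample(c("s1", "s2"), 1L), "")

  sch <- data.frame(
    trial = seq_along(order),
    pair_type = factor(order, levels = types),
    high_prob_side = side,
    correct_stimulus = unname(correct_stim[order]),
    stringsAsFactors = FALSE
  )
  attr(sch, "n_per_pair") <- n_per_pair
  attr(sch, "seed") <- seed
  class(sch) <- c("task_schedule", "data.frame")
  sch
}

# random order with no run of identical labels longer than max_run:
# sequential sampling proportional to remaining counts, excluding the label
# that would extend a maximal run; restart on dead ends (rare for balanced
# labels)
shuffle_max_run <- function(labels, max_run) {
  ulab <- unique(labels)
  counts0 <- table(factor(labels, ulab))
  n <- length(labels)
  for (attempt in 1:1000) {
    counts <- as.vector(counts0)
    out <- character(n)
    run_lab <- ""; run_len <- 0L
    ok <- TRUE
    for (i in seq_len(n)) {
      avail <- which(counts > 0L)
      if (run_len >= max_run) avail <- avail[ulab[avail] != run_lab]
      if (!length(avail)) { ok <- FALSE; break }
      pick <- if (length(avail) == 1L) avail else
        sample(avail, 1L, prob = counts[avail])
      lab <- ulab[pick]
      out[i] <- lab
      counts[pick] <- counts[pick] - 1L
      if (lab == run_lab) run_len <- run_len + 1L else {
        run_lab <- lab; run_len <- 1L
      }
    }
    if (ok) return(out)
  }
  stop("could not satisfy the run-length constraint")
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.task_schedule <- function(x, ...) {
  cat("Task schedule:", nrow(x), "trials (",
      attr(x, "n_per_pair"), "per pair type ), seed", attr(x, "seed"), "\n")
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more trials\n")
  invisible(x)
}

#' Sample trial outcomes from the task contingencies
#'
#' Draws feedback for one trial type given which stimulus was chosen, using
#' the stated contingencies: reward pairs win \eqn{\pounds}1 with probability
#' 0.8 (high-probability stimulus) or 0.2 (low), otherwise neutral feedback;
#' bivalent pairs win or lose \eqn{\pounds}1 with probability 0.5 each;
#' neutral pairs give feedback kind A with probability 0.8 (high) or 0.2
#' (low), otherwise kind B. Neutral feedback carries no monetary value.
#'
#' Uses the session RNG; seed with \code{set.seed()} for reproducibility.
#'
#' @param pair_type One of "reward", "bivalent", "neutral" (recycled).
#' @param chose_high_prob Logical; whether the chosen stimulus is the
#'   high-probability (designated) one. Ignored for bivalent pairs, whose
#'   stimuli share one contingency.
#' @param n Number of draws (defaults to the common length of the inputs).
#' @return A data frame with columns \code{value} (+1, 0 or -1 pounds) and
#'   \code{feedback_kind} ("win", "loss", "neutral_A", "neutral_B").
#' @examples
#' set.seed(1)
#' mean(sample_outcome("reward", TRUE, n = 1000)$value)  # about 0.8
#' @export
sample_outcome <- function(pair_type, chose_high_prob = TRUE, n = NULL) {
  if (is.null(n)) n <- max(length(pair_type), length(chose_high_prob))
  pair_type <- rep_len(as.character(pair_type), n)
  chose_high_prob <- rep_len(as.logical(chose_high_prob), n)
  bad <- !pair_type %in% c("reward", "bivalent", "neutral")
  if (any(bad)) stop("unknown pair type: ", pair_type[which(bad)[1L]])

  u <- stats::runif(n)
  kind <- character(n)
  p_hi <- ifelse(chose_high_prob, 0.8, 0.2)

  r <- pair_type == "reward"
  kind[r] <- ifelse(u[r] < p_hi[r], "win", "neutral_A")
  b <- pair_type == "bivalent"
  kind[b] <- ifelse(u[b] < 0.5, "win", "loss")
  ne <- pair_type == "neutral"
  kind[ne] <- ifelse(u[ne] < p_hi[ne], "neutral_A", "neutral_B")

  value <- ifelse(kind == "win", 1, ifelse(kind == "loss", -1, 0))
  data.frame(value = value, feedback_kind = kind, stringsAsFactors = FALSE)
}

#' Write or read a task schedule as a tab-separated events table
#'
#' One row per trial with columns \code{trial}, \code{pair_type},
#' \code{high_prob_side}, \code{correct_stimulus} (BIDS-events-like layout).
#'
#' @param schedule A \code{task_schedule}.
#' @param path Output (or input) file path.
#' @return \code{write_schedule_tsv} returns \code{path} invisibly;
#'   \code{read_schedule_tsv} returns a \code{task_schedule}.
#' @export
write_schedule_tsv <- function(schedule, path) {
  stopifnot(inherits(schedule, "task_schedule"))
  df <- as.data.frame(schedule)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_tsv
#' @export
read_schedule_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$pair_type <- factor(df$pair_type,
                         levels = c("reward", "bivalent", "neutral"))
  n_per_pair <- as.integer(table(df$pair_type)[1L])
  attr(df, "n_per_pair") <- n_per_pair
  class(df) <- c("task_schedule", "data.frame")
  df
}
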