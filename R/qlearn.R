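#' Q-learning parameters
#'
#' Container for the Rescorla-Wagner / softmax agent: learning rate
#' \code{alpha} in [0,1], inverse temperature \code{beta} >= 0, initial
#' action value \code{q0} (default 0) and \code{neutral_value}, an internal
#' value the agent assigns to the colour-matching neutral feedback kind
#' (default 0: only monetary value enters the update; nonzero values are
#' used by the synthetic-cohort generator to emulate the weak preference
#' humans show on neutral pairs).
#'
#' @param alpha Learning rate in [0, 1].
#' @param beta Softmax inverse temperature, >= 0.
#' @param q0 Initial action value.
#' @param neutral_value Internal value of feedback kind A on neutral pairs.
#' @param stickiness Choice-perseveration bonus added to the previously
#'   chosen stimulus of a pair inside the softmax (default 0; used by the
#'   cohort generator, not by the fitted model).
#' @return A list of class \code{q_params}.
#' @export
q_params <- function(alpha, beta, q0 = 0, neutral_value = 0,
                     stickiness = 0) {
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("`alpha` must lie in [0, 1]")
  if (!is.finite(beta) || beta < 0)
    stop("`beta` must be >= 0")
  structure(list(alpha = alpha, beta = beta, q0 = q0,
                 neutral_value = neutral_value, stickiness = stickiness),
            class = "q_params")
}

#' Rescorla-Wagner value update
#'
#' One prediction-error update of the chosen stimulus:
#' \eqn{\delta = r - Q} and \eqn{Q' = Q + \alpha \delta}. The caller is
#' responsible for leaving unchosen stimulus values untouched.
#'
#' @param q Current value of the chosen stimulus.
#' @param outcome_value Received reward r.
#' @param alpha Learning rate in [0, 1].
#' @return List with \code{delta} (prediction error) and \code{q_new}.
#' @examples
#' update_q(0, 1, 0.5)  # delta 1, q_new 0.5
#' @export
update_q <- function(q, outcome_value, alpha) {
  if (any(!is.finite(alpha)) || any(alpha < 0) || any(alpha > 1))
    stop("`alpha` must lie in [0, 1]")
  delta <- outcome_value - q
  list(delta = delta, q_new = q + alpha * delta)
}

#' Softmax choice probability
#'
#' Probability of choosing a stimulus given the value difference:
#' \eqn{p = 1 / (1 + e^{-\beta (Q_c - Q_o)})}. Overflow-safe for large
#' \code{beta} (computed via the logistic CDF).
#'
#' @param q_chosen,q_other Action values.
#' @param beta Inverse temperature >= 0.
#' @return Choice probability in (0, 1).
#' @export
choice_prob <- function(q_chosen, q_other, beta) {
  if (any(!is.finite(beta)) || any(beta < 0)) stop("`beta` must be >= 0")
  stats::plogis(beta * (q_chosen - q_other))
}

# internal reward used by the generative agent: monetary value, plus the
# configured pseudo-value of colour-matching feedback on neutral pairs
internal_reward <- function(pair_type, value, feedback_kind, neutral_value) {
  value + neutral_value * (pair_type == "neutral" & feedback_kind == "neutral_A")
}

#' Simulate a Q-learning agent on a task schedule
#'
#' Plays the schedule trial by trial: choice probabilities come from a
#' softmax over the pair's two action values (maintained independently per
#' pair), outcomes are drawn from the task contingencies, and values of the
#' chosen stimulus are updated by the Rescorla-Wagner rule. The prediction
#' error at every outcome is recorded.
#'
#' Uses the session RNG; seed with \code{set.seed()} for reproducibility.
#'
#' @param params A \code{q_params} object (or list with alpha/beta).
#' @param schedule A \code{task_schedule}.
#' @return A \code{subject_behaviour} object: a list with the \code{schedule}
#'   and a per-trial data frame \code{trials} (columns \code{trial},
#'   \code{pair_type}, \code{choice}, \code{chose_correct},
#'   \code{outcome_value}, \code{feedback_kind}, \code{rt_ms},
#'   \code{delta}).
#' @examples
#' sch <- generate_schedule(4, seed = 2)
#' set.seed(9)
#' beh <- simulate_agent(q_params(0.3, 3), sch)
#' @export
simulate_agent <- function(params, schedule) {
  stopifnot(inherits(schedule, "task_schedule"))
  if (!inherits(params, "q_params"))
    params <- do.call(q_params, as.list(params))
  n <- nrow(schedule)
  types <- levels(schedule$pair_type)
  Q <- matrix(params$q0, nrow = 3L, ncol = 2L,
              dimnames = list(types, c("s1", "s2")))

  choice <- character(n); kind <- character(n)
  value <- numeric(n); delta <- numeric(n); chose_correct <- logical(n)
  u_choice <- stats::runif(n)
  prev <- c(reward = 0L, bivalent = 0L, neutral = 0L)  # last choice per pair
  stick <- if (is.null(params$stickiness)) 0 else params$stickiness

  for (t in seq_len(n)) {
    tp <- as.character(schedule$pair_type[t])
    bonus <- if (prev[tp] == 1L) stick else if (prev[tp] == 2L) -stick else 0
    p1 <- stats::plogis(params$beta * (Q[tp, 1L] - Q[tp, 2L]) + bonus)
    ch <- if (u_choice[t] < p1) 1L else 2L
    prev[tp] <- ch
    stim <- c("s1", "s2")[ch]
    hi <- stim == schedule$correct_stimulus[t]
    out <- sample_outcome(tp, hi, n = 1L)
    r <- internal_reward(tp, out$value, out$feedback_kind,
                         params$neutral_value)
    up <- update_q(Q[tp, ch], r, params$alpha)
    Q[tp, ch] <- up$q_new
    choice[t] <- stim; chose_correct[t] <- hi
    value[t] <- out$value; kind[t] <- out$feedback_kind
    delta[t] <- up$delta
  }

  trials <- data.frame(
    trial = schedule$trial,
    pair_type = schedule$pair_type,
    choice = choice,
    chose_correct = chose_correct,
    outcome_value = value,
    feedback_kind = kind,
    rt_ms = NA_real_,
    delta = delta,
    stringsAsFactors = FALSE
  )
  structure(list(schedule = schedule, trials = trials, params = params),
            class = "subject_behaviour")
}

#' @export
print.subject_behaviour <- function(x, ...) {
  cat("Subject behaviour:", nrow(x$trials), "trials;",
      "correct rate", round(mean(x$trials$chose_correct), 3), "\n")
  invisible(x)
}

# negative log-likelihood of observed choices under (alpha, beta); replays
# the recorded choices/outcomes with monetary value only (neutral r = 0)
qlearn_nll <- function(alpha, beta, trials, q0 = 0) {
  n <- nrow(trials)
  Q <- matrix(q0, nrow = 3L, ncol = 2L)
  rownames(Q) <- c("reward", "bivalent", "neutral")
  nll <- 0
  tp_i <- match(as.character(trials$pair_type), rownames(Q))
  ch_i <- ifelse(trials$choice == "s1", 1L, 2L)
  r <- trials$outcome_value
  for (t in seq_len(n)) {
    i <- tp_i[t]; c1 <- ch_i[t]; c2 <- 3L - c1
    dq <- beta * (Q[i, c1] - Q[i, c2])
    # log(plogis) computed stably
    nll <- nll - stats::plogis(dq, log.p = TRUE)
    Q[i, c1] <- Q[i, c1] + alpha * (r[t] - Q[i, c1])
  }
  unname(nll)
}

#' Fit the Q-learning model to choice data by maximum likelihood
#'
#' Maximises the softmax choice log-likelihood over the learning rate and
#' inverse temperature by bounded multi-start optimisation (Nelder-Mead on a
#' logit/log-scaled parameterisation, so the optimiser is gradient-free and
#' the bounds are respected exactly). Only monetary outcome value enters the
#' value update; neutral feedback is worth 0. Ties between restarts are
#' broken by lowest negative log-likelihood, then lowest beta.
#'
#' @param behaviour A \code{subject_behaviour} (or a list with a
#'   \code{trials} data frame with columns \code{pair_type}, \code{choice},
#'   \code{outcome_value}).
#' @param bounds List with elements \code{alpha} and \code{beta}, each a
#'   length-2 numeric range.
#' @param n_restarts Number of random restarts.
#' @param seed Optional seed for the restart draws.
#' @return An object of class \code{qlearn_fit} with components
#'   \code{params} (\code{q_params}), \code{nll}, \code{converged},
#'   \code{n_restarts_used}, \code{n_trials} and the data it was fitted to.
#' @examples
#' sch <- generate_schedule(10, seed = 3)
#' set.seed(1); beh <- simulate_agent(q_params(0.4, 4), sch)
#' fit <- fit_q_model(beh, n_restarts = 4, seed = 1)
#' coef(fit)
#' @export
fit_q_model <- function(behaviour,
                        bounds = list(alpha = c(0.001, 0.999),
                                      beta = c(0.01, 20)),
                        n_restarts = 10L, seed = NULL) {
  trials <- behaviour$trials
  if (is.null(trials) || nrow(trials) < 1L)
    stop("behaviour must contain at least one trial with a recorded choice")
  lo <- c(bounds$alpha[1L], bounds$beta[1L])
  hi <- c(bounds$alpha[2L], bounds$beta[2L])

  # map (-inf, inf) -> bounds through a scaled logistic
  to_nat <- function(z) lo + (hi - lo) * stats::plogis(z)
  obj <- function(z) {
    p <- to_nat(z)
    qlearn_nll(p[1L], p[2L], trials)
  }

  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  starts <- matrix(stats::rnorm(2L * n_restarts, sd = 1.5), ncol = 2L)
  best <- NULL
  for (k in seq_len(n_restarts)) {
    o <- stats::optim(starts[k, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 500L, reltol = 1e-10))
    cand <- list(z = o$par, nll = o$value, code = o$convergence)
    if (is.null(best) || cand$nll < best$nll - 1e-9 ||
        (abs(cand$nll - best$nll) <= 1e-9 &&
         to_nat(cand$z)[2L] < to_nat(best$z)[2L])) {
      best <- cand
    }
  }
  par <- to_nat(best$z)
  tol <- 1e-4 * (hi - lo)
  at_bound <- any(par <= lo + tol | par >= hi - tol)
  structure(list(
    params = q_params(par[1L], par[2L]),
    nll = best$nll,
    converged = best$code == 0L && !at_bound,
    n_restarts_used = n_restarts,
    n_trials = nrow(trials),
    behaviour = behaviour,
    bounds = bounds
  ), class = "qlearn_fit")
}

#' @export
print.qlearn_fit <- function(x, digits = 3, ...) {
  cat("Q-learning fit (", x$n_trials, " trials)\n", sep = "")
  cat("  alpha =", format(x$params$alpha, digits = digits),
      " beta =", format(x$params$beta, digits = digits), "\n")
  cat("  -logLik =", format(x$nll, digits = digits + 2),
      if (x$converged) "(converged)" else "(at bounds / not converged)", "\n")
  invisible(x)
}

#' @export
coef.qlearn_fit <- function(object, ...) {
  c(alpha = object$params$alpha, beta = object$params$beta)
}

#' @export
logLik.qlearn_fit <- function(object, ...) {
  structure(-object$nll, df = 2L, nobs = object$n_trials, class = "logLik")
}

#' @export
summary.qlearn_fit <- function(object, ...) {
  base_nll <- object$n_trials * log(2)  # beta = 0 random-choice model
  out <- list(coef = coef(object), nll = object$nll,
              random_choice_nll = base_nll,
              converged = object$converged,
              n_trials = object$n_trials)
  class(out) <- "summary.qlearn_fit"
  out
}

#' @export
print.summary.qlearn_fit <- function(x, ...) {
  cat("Q-learning model fit\n")
  print(round(x$coef, 4))
  cat("-logLik:", format(x$nll, digits = 6),
      "(random-choice baseline:", format(x$random_choice_nll, digits = 6),
      ")\n")
  invisible(x)
}

#' @export
predict.qlearn_fit <- function(object, newdata = NULL, ...) {
  beh <- if (is.null(newdata)) object$behaviour else newdata
  replay_q(beh$trials, object$params)$p_choice
}

#' @export
residuals.qlearn_fit <- function(object, ...) {
  pe_series(object$behaviour, object$params)
}

#' @export
simulate.qlearn_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- replicate(nsim,
                   simulate_agent(object$params, object$behaviour$schedule),
                   simplify = FALSE)
  if (nsim == 1L) out[[1L]] else out
}

# deterministic replay of recorded choices/outcomes under given params;
# returns per-trial PE and the probability of the recorded choice
replay_q <- function(trials, params, use_internal = FALSE) {
  n <- nrow(trials)
  Q <- matrix(params$q0, nrow = 3L, ncol = 2L)
  rownames(Q) <- c("reward", "bivalent", "neutral")
  tp_i <- match(as.character(trials$pair_type), rownames(Q))
  ch_i <- ifelse(trials$choice == "s1", 1L, 2L)
  r <- if (use_internal) {
    internal_reward(as.character(trials$pair_type), trials$outcome_value,
                    trials$feedback_kind, params$neutral_value)
  } else trials$outcome_value
  delta <- numeric(n); p_choice <- numeric(n)
  for (t in seq_len(n)) {
    i <- tp_i[t]; c1 <- ch_i[t]; c2 <- 3L - c1
    p_choice[t] <- stats::plogis(params$beta * (Q[i, c1] - Q[i, c2]))
    delta[t] <- r[t] - Q[i, c1]
    Q[i, c1] <- Q[i, c1] + params$alpha * delta[t]
  }
  list(delta = delta, p_choice = p_choice)
}

#' Trial-wise prediction-error series under given parameters
#'
#' Replays the recorded choices and outcomes under \code{params} and returns
#' the prediction error at every outcome, aligned to outcome onsets. This is
#' the model-based regressor path: with a fitted \code{q_params} the series
#' is the parametric PE modulator; with \code{alpha = 0} it degenerates to
#' the raw outcome values.
#'
#' @param behaviour A \code{subject_behaviour}.
#' @param params A \code{q_params}.
#' @return Numeric vector of per-trial prediction errors.
#' @export
pe_series <- function(behaviour, params) {
  trials <- behaviour$trials
  if (length(trials$choice) != length(trials$outcome_value))
    stop("choices and outcomes differ in length")
  if (!inherits(params, "q_params"))
    params <- do.call(q_params, as.list(params))
  replay_q(trials, params)$delta
}

#' Write / read behaviour tables
#'
#' Tab-separated per-trial behaviour (columns \code{trial},
#' \code{pair_type}, \code{choice}, \code{outcome_value},
#' \code{feedback_kind}, \code{rt_ms}, \code{delta}, \code{chose_correct}).
#'
#' @param behaviour A \code{subject_behaviour}.
#' @param path File path.
#' @export
write_behaviour_tsv <- function(behaviour, path) {
  utils::write.table(behaviour$trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_behaviour_tsv
#' @param schedule Optional \code{task_schedule} to attach on read.
#' @export
read_behaviour_tsv <- function(path, schedule = NULL) {
  trials <- utils::read.table(path, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  trials$pair_type <- factor(trials$pair_type,
                             levels = c("reward", "bivalent", "neutral"))
  structure(list(schedule = schedule, trials = trials, params = NULL),
            class = "subject_behaviour")
}
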