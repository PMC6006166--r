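# hand-built subject_behaviour for deterministic behavioural tests
make_behaviour <- function(pair_type, choice, feedback_kind,
                           outcome_value = NULL, rt_ms = NA_real_,
                           delta = 0) {
  n <- length(pair_type)
  if (is.null(outcome_value))
    outcome_value <- ifelse(feedback_kind == "win", 1,
                            ifelse(feedback_kind == "loss", -1, 0))
  # minimal schedule: every choice of "s1" counts as correct
  sch <- data.frame(
    trial = seq_len(n),
    pair_type = factor(pair_type, levels = c("reward", "bivalent", "neutral")),
    high_prob_side = "left",
    correct_stimulus = "s1",
    stringsAsFactors = FALSE
  )
  class(sch) <- c("task_schedule", "data.frame")
  trials <- data.frame(
    trial = seq_len(n),
    pair_type = sch$pair_type,
    choice = choice,
    chose_correct = choice == "s1",
    outcome_value = outcome_value,
    feedback_kind = feedback_kind,
    rt_ms = rep_len(rt_ms, n),
    delta = rep_len(delta, n),
    stringsAsFactors = FALSE
  )
  structure(list(schedule = sch, trials = trials, params = NULL),
            class = "subject_behaviour")
}

# long-format data for the mixed ANOVA from a subjects x conditions matrix
anova_long <- function(Y, group, conditions = colnames(Y)) {
  if (is.null(conditions)) conditions <- paste0("c", seq_len(ncol(Y)))
  data.frame(
    value = as.vector(Y),
    group = rep(group, times = ncol(Y)),
    subject = rep(sprintf("s%02d", seq_len(nrow(Y))), times = ncol(Y)),
    condition = rep(conditions, each = nrow(Y)),
    stringsAsFactors = FALSE
  )
}
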