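#' Proportion of "correct" choices per pair type
#'
#' "Correct" means choosing the stimulus designated correct in the schedule:
#' the high-probability stimulus on reward and neutral pairs, and an
#' arbitrary fixed stimulus on bivalent pairs (where the assignment only
#' serves to detect preference for one stimulus over the other).
#'
#' @param behaviour A \code{subject_behaviour}.
#' @return Named numeric vector of proportions for reward, bivalent and
#'   neutral pairs.
#' @export
correct_rate <- function(behaviour) {
  tr <- behaviour$trials
  out <- tapply(tr$chose_correct, tr$pair_type, mean)
  out[is.nan(out)] <- NA_real_
  c(out)
}

#' Learning curve: correct rate per trial bin
#'
#' @param behaviour A \code{subject_behaviour}.
#' @param n_bins Number of equal bins of within-pair trial position.
#' @return Matrix (pair type x bin) of correct proportions.
#' @export
learning_curve <- function(behaviour, n_bins = 5L) {
  tr <- behaviour$trials
  types <- levels(tr$pair_type)
  out <- matrix(NA_real_, length(types), n_bins,
                dimnames = list(types, paste0("bin", seq_len(n_bins))))
  for (tp in types) {
    idx <- which(tr$pair_type == tp)
    if (!length(idx)) next
    pos <- seq_along(idx)
    bin <- ceiling(pos / (length(idx) / n_bins))
    bin[bin > n_bins] <- n_bins
    out[tp, ] <- tapply(tr$chose_correct[idx], factor(bin, seq_len(n_bins)),
                        mean)
  }
  out
}

#' Win-stay / lose-shift probabilities
#'
#' For each pair type, transitions between consecutive presentations of that
#' pair are classified by the outcome of the earlier trial: a "win" is a
#' \eqn{\pounds}1 win on reward and bivalent pairs, and the colour-matching
#' feedback (kind A) on neutral pairs. \code{win_stay} is the probability of
#' repeating the choice after a win; \code{lose_shift} the probability of
#' switching after a non-win. Intervening trials of other pairs do not break
#' the chain. Undefined rates (zero eligible transitions) are \code{NA},
#' never 0.
#'
#' @param behaviour A \code{subject_behaviour}.
#' @return Data frame with rows reward, bivalent, neutral and overall, and
#'   columns \code{win_stay}, \code{lose_shift}, \code{n_win}, \code{n_lose}
#'   (transition denominators).
#' @export
wsls <- function(behaviour) {
  tr <- behaviour$trials
  types <- levels(tr$pair_type)
  if (nrow(tr) < 2L) stop("need at least 2 trials")
  rn <- c(types, "overall")
  res <- data.frame(win_stay = rep(NA_real_, 4L),
                    lose_shift = rep(NA_real_, 4L),
                    n_win = rep(0L, 4L), n_lose = rep(0L, 4L),
                    row.names = rn)
  tot <- c(ws = 0L, nw = 0L, ls = 0L, nl = 0L)
  for (tp in types) {
    idx <- which(tr$pair_type == tp)
    if (length(idx) < 2L) next
    prev <- idx[-length(idx)]; nxt <- idx[-1L]
    win <- tr$feedback_kind[prev] == "win" |
      (tp == "neutral" & tr$feedback_kind[prev] == "neutral_A")
    stay <- tr$choice[nxt] == tr$choice[prev]
    nw <- sum(win); nl <- sum(!win)
    res[tp, "n_win"] <- nw; res[tp, "n_lose"] <- nl
    if (nw > 0) res[tp, "win_stay"] <- mean(stay[win])
    if (nl > 0) res[tp, "lose_shift"] <- mean(!stay[!win])
    tot["ws"] <- tot["ws"] + sum(stay[win]); tot["nw"] <- tot["nw"] + nw
    tot["ls"] <- tot["ls"] + sum(!stay[!win]); tot["nl"] <- tot["nl"] + nl
  }
  res["overall", "n_win"] <- tot["nw"]; res["overall", "n_lose"] <- tot["nl"]
  if (tot["nw"] > 0) res["overall", "win_stay"] <- tot["ws"] / tot["nw"]
  if (tot["nl"] > 0) res["overall", "lose_shift"] <- tot["ls"] / tot["nl"]
  res
}

#' Per-subject behavioural summary
#'
#' @param behaviour A \code{subject_behaviour}.
#' @param n_bins Learning-curve bins.
#' @return List with \code{correct_rate}, \code{wsls}, \code{mean_rt}
#'   (per pair type) and \code{learning_curve}.
#' @export
behaviour_summary <- function(behaviour, n_bins = 5L) {
  tr <- behaviour$trials
  list(
    correct_rate = correct_rate(behaviour),
    wsls = wsls(behaviour),
    mean_rt = c(tapply(tr$rt_ms, tr$pair_type, mean)),
    learning_curve = learning_curve(behaviour, n_bins)
  )
}

# split-plot sums of squares for a group (between) x condition (within)
# design; Y is subjects x conditions, balanced within subject. Sequential
# (aov-equivalent) decomposition, valid for unequal group sizes.
splitplot_F <- function(Y, group) {
  group <- droplevels(as.factor(group))
  N <- nrow(Y); J <- ncol(Y); G <- nlevels(group)
  m <- rowMeans(Y)
  mg <- tapply(m, group, mean)
  ng <- tabulate(group)
  ss_group <- J * sum(ng * (mg - mean(Y))^2)
  ss_subj <- J * sum((m - mg[group])^2)
  D <- Y - m
  dbar_j <- colMeans(D)
  cell <- apply(D, 2L, function(col) tapply(col, group, mean))  # G x J
  ss_cond <- N * sum(dbar_j^2)
  ss_inter <- sum(ng * (cell - rep(dbar_j, each = G))^2)
  ss_res <- sum(D^2) - ss_cond - ss_inter
  df <- c(group = G - 1L, subj = N - G, cond = J - 1L,
          inter = (G - 1L) * (J - 1L), res = (N - G) * (J - 1L))
  ms_subj <- ss_subj / df["subj"]; ms_res <- ss_res / df["res"]
  F_group <- if (ms_subj > 0) (ss_group / df["group"]) / ms_subj else 0
  F_cond <- if (ms_res > 0) (ss_cond / df["cond"]) / ms_res else 0
  F_inter <- if (ms_res > 0) (ss_inter / df["inter"]) / ms_res else 0
  list(F = c(group = unname(F_group), condition = unname(F_cond),
             interaction = unname(F_inter)),
       df = df,
       ss = c(group = ss_group, subj = ss_subj, cond = ss_cond,
              inter = ss_inter, res = ss_res))
}

#' Mixed (split-plot) ANOVA with permutation p-values
#'
#' Group x trial-type analysis of variance for a between-subject grouping
#' factor crossed with a balanced within-subject factor, as used for
#' correct-choice and reaction-time analyses. Parametric F statistics come
#' from the classical split-plot decomposition (the group effect is tested
#' against between-subject variation, the trial-type and interaction effects
#' against the within-subject residual). Permutation p-values are primary:
#' the group and interaction effects are assessed by shuffling group labels
#' across subjects; the trial-type effect by shuffling condition labels
#' within each subject. Bonferroni-corrected paired follow-ups compare the
#' within-subject levels.
#'
#' @param data Long data frame with columns \code{value}, \code{group},
#'   \code{subject}, \code{condition}.
#' @param n_perm Number of permutations (>= 1000 recommended).
#' @param seed Optional RNG seed.
#' @return An object of class \code{mixed_anova}: a data frame with one row
#'   per effect (group, condition, interaction) and columns \code{F},
#'   \code{df1}, \code{df2}, \code{p_param}, \code{p_perm}, plus an attribute
#'   \code{pairwise} with Bonferroni-corrected paired comparisons of the
#'   within-subject levels.
#' @export
mixed_anova <- function(data, n_perm = 1000L, seed = NULL) {
  need <- c("value", "group", "subject", "condition")
  if (!all(need %in% names(data)))
    stop("data must have columns value, group, subject, condition")
  data$subject <- as.factor(data$subject)
  data$condition <- as.factor(data$condition)
  tab <- table(data$subject, data$condition)
  if (any(tab != 1L))
    stop("unbalanced within-subject data: every subject needs each condition exactly once")

  subj <- levels(data$subject)
  cond <- levels(data$condition)
  Y <- matrix(NA_real_, length(subj), length(cond),
              dimnames = list(subj, cond))
  Y[cbind(match(data$subject, subj), match(data$condition, cond))] <- data$value
  if (any(tapply(as.character(data$group), data$subject,
                 function(g) length(unique(g))) != 1L))
    stop("each subject must belong to exactly one group")
  grp <- droplevels(as.factor(data$group[match(subj, data$subject)]))

  obs <- splitplot_F(Y, grp)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  exceed <- c(group = 0L, condition = 0L, interaction = 0L)
  for (b in seq_len(n_perm)) {
    Fb <- splitplot_F(Y, sample(grp))$F   # between shuffle
    if (Fb["group"] >= obs$F["group"]) exceed["group"] <- exceed["group"] + 1L
    if (Fb["interaction"] >= obs$F["interaction"])
      exceed["interaction"] <- exceed["interaction"] + 1L
    Yw <- t(apply(Y, 1L, sample))         # within-subject label shuffle
    Fw <- splitplot_F(Yw, grp)$F
    if (Fw["condition"] >= obs$F["condition"])
      exceed["condition"] <- exceed["condition"] + 1L
  }
  p_perm <- (exceed + 1L) / (n_perm + 1L)

  df <- obs$df
  tab_out <- data.frame(
    effect = c("group", "condition", "interaction"),
    F = unname(obs$F),
    df1 = unname(c(df["group"], df["cond"], df["inter"])),
    df2 = unname(c(df["subj"], df["res"], df["res"])),
    stringsAsFactors = FALSE
  )
  tab_out$p_param <- stats::pf(tab_out$F, tab_out$df1, tab_out$df2,
                               lower.tail = FALSE)
  tab_out$p_perm <- unname(p_perm[tab_out$effect])

  # Bonferroni-corrected paired follow-ups on the within-subject factor
  pairs <- utils::combn(cond, 2L)
  pw <- apply(pairs, 2L, function(pr) {
    tt <- stats::t.test(Y[, pr[1L]], Y[, pr[2L]], paired = TRUE)
    c(estimate = unname(tt$estimate), p = tt$p.value)
  })
  pairwise <- data.frame(
    level1 = pairs[1L, ], level2 = pairs[2L, ],
    mean_diff = pw["estimate", ],
    p_bonferroni = pmin(1, pw["p", ] * ncol(pairs)),
    stringsAsFactors = FALSE
  )
  structure(tab_out, pairwise = pairwise, n_perm = n_perm,
            class = c("mixed_anova", "data.frame"))
}

#' @export
print.mixed_anova <- function(x, digits = 4, ...) {
  cat("Mixed (split-plot) ANOVA, permutation p from",
      attr(x, "n_perm"), "permutations\n")
  print(format(as.data.frame(x), digits = digits), row.names = FALSE)
  cat("\nPairwise within-subject follow-ups (Bonferroni):\n")
  print(format(attr(x, "pairwise"), digits = digits), row.names = FALSE)
  invisible(x)
}
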