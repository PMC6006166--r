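#' Synthetic cohort configuration
#'
#' Study conditions for the synthetic cohort: group sizes (39 controls, 30
#' at-risk, 14 first-episode psychosis), Q-learning parameter distributions
#' per group, per-ROI per-group prediction-error coupling moments in COPE
#' units (defaults are the published cluster means and SDs for midbrain and
#' right DLPFC; zero mean in striatum), the BOLD noise model, reaction-time
#' model, symptom-score distributions (CAARMS totals for the two patient
#' groups) and the scan timing.
#'
#' @param groups Named integer vector of group sizes, in hypothesised
#'   decreasing order of PE signalling.
#' @param n_per_pair Trials per pair type (30 gives the 90-trial task).
#' @param agent Per-group Q-parameter distributions: for each group a list
#'   with \code{alpha_mean}, \code{alpha_conc} (beta-distribution mean and
#'   concentration), \code{beta_meanlog}, \code{beta_sdlog} (log-normal).
#' @param neutral_value Internal value agents assign to colour-matching
#'   neutral feedback (behavioural calibration; monetary value stays 0).
#' @param stickiness Choice-perseveration bonus of the generative agents
#'   (behavioural calibration; the fitted model has none).
#' @param coupling Per-ROI list with \code{mean} and \code{sd} vectors over
#'   groups (COPE units).
#' @param noise List: \code{ar1} (AR(1) coefficient), \code{sd} (stationary
#'   noise SD), \code{baseline_amp} (common task response amplitude),
#'   \code{drift_amp}, \code{drift_period} (s).
#' @param rt List: \code{mean_ms} per pair type, \code{between_sdlog},
#'   \code{within_sdlog}.
#' @param symptoms Per-group list with \code{mean} and \code{sd} of the
#'   symptom score (NA for groups without one).
#' @param design List: \code{tr}, \code{trial_duration},
#'   \code{outcome_delay} (s); \code{n_volumes} is derived if NULL.
#' @param seed Master seed for the cohort.
#' @return List of class \code{cohort_config}.
#' @export
cohort_config <- function(groups = c(controls = 39L, at_risk = 30L, fep = 14L),
                          n_per_pair = 30L,
                          agent = NULL,
                          neutral_value = 0.2,
                          stickiness = 0.33,
                          coupling = NULL,
                          noise = NULL,
                          rt = NULL,
                          symptoms = NULL,
                          design = NULL,
                          seed = 1L) {
  gnames <- names(groups)
  if (is.null(gnames) || any(gnames == "")) stop("groups must be named")
  if (any(groups <= 0)) stop("group sizes must be positive")
  if (is.null(agent)) {
    agent <- list(
      controls = list(alpha_mean = 0.20, alpha_conc = 12,
                      beta_meanlog = log(2.5), beta_sdlog = 0.35),
      at_risk = list(alpha_mean = 0.20, alpha_conc = 12,
                     beta_meanlog = log(2.5), beta_sdlog = 0.35),
      fep = list(alpha_mean = 0.18, alpha_conc = 12,
                 beta_meanlog = log(2.5) - 0.25, beta_sdlog = 0.35)
    )[gnames]
    if (any(vapply(agent, is.null, TRUE))) {
      agent[vapply(agent, is.null, TRUE)] <-
        list(list(alpha_mean = 0.20, alpha_conc = 12,
                  beta_meanlog = log(2.5), beta_sdlog = 0.35))
    }
    names(agent) <- gnames
  }
  if (is.null(coupling)) {
    coupling <- list(
      midbrain = list(mean = c(24.44, 0.66, -55.03),
                      sd = c(50.12, 54.86, 50.70)),
      striatum = list(mean = c(0, 0, 0), sd = c(40, 40, 40)),
      dlpfc = list(mean = c(32.90, 36.29, -45.13),
                   sd = c(62.82, 53.03, 48.40))
    )
  }
  if (is.null(noise)) {
    noise <- list(ar1 = 0.3, sd = 120, baseline_amp = 5,
                  drift_amp = 3, drift_period = 128)
  }
  if (is.null(rt)) {
    rt <- list(mean_ms = c(reward = 1122.83, bivalent = 1358.99,
                           neutral = 1329.30),
               between_sdlog = 0.18, within_sdlog = 0.3)
  }
  if (is.null(symptoms)) {
    symptoms <- list(controls = list(mean = NA_real_, sd = NA_real_),
                     at_risk = list(mean = 15.10, sd = 6.75),
                     fep = list(mean = 23.86, sd = 6.48))[gnames]
    names(symptoms) <- gnames
  }
  if (is.null(design)) design <- list(tr = 2, trial_duration = 10,
                                      outcome_delay = 4, n_volumes = NULL)
  if (is.null(design$n_volumes)) {
    design$n_volumes <- ceiling((3 * n_per_pair * design$trial_duration + 16) /
                                  design$tr)
  }
  for (r in names(coupling)) {
    if (length(coupling[[r]]$mean) != length(groups) ||
        length(coupling[[r]]$sd) != length(groups))
      stop("coupling moments for ", r, " must have one entry per group")
    if (any(coupling[[r]]$sd <= 0)) stop("coupling SDs must be positive")
  }
  if (abs(noise$ar1) >= 1) stop("AR(1) coefficient must lie in (-1, 1)")
  if (noise$sd <= 0) stop("noise SD must be positive")
  structure(list(groups = groups, n_per_pair = as.integer(n_per_pair),
                 agent = agent, neutral_value = neutral_value,
                 stickiness = stickiness,
                 coupling = coupling, noise = noise, rt = rt,
                 symptoms = symptoms, design = design,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Sample per-trial reaction times
#'
#' Log-normal reaction times with pair-type-specific expected values, a
#' between-subject log-scale effect drawn once per call, and within-subject
#' trial noise. The log-mean is offset by half the total log variance so the
#' expectation equals the configured mean exactly; a zero-variance model
#' returns the configured means.
#'
#' @param behaviour A \code{subject_behaviour}.
#' @param rt_model List with \code{mean_ms} (named by pair type),
#'   \code{between_sdlog}, \code{within_sdlog}.
#' @return Numeric vector of RTs (ms), positive.
#' @export
generate_rts <- function(behaviour, rt_model) {
  tr <- behaviour$trials
  mu <- rt_model$mean_ms[as.character(tr$pair_type)]
  if (any(is.na(mu))) stop("rt_model$mean_ms must name every pair type")
  b <- rt_model$between_sdlog; w <- rt_model$within_sdlog
  if (b < 0 || w < 0) stop("RT sdlog parameters must be >= 0")
  subj_eff <- stats::rnorm(1L, 0, b)
  eps <- stats::rnorm(nrow(tr), 0, w)
  unname(exp(log(mu) - (b^2 + w^2) / 2 + subj_eff + eps))
}

#' Simulate masked BOLD time series for one subject
#'
#' Forward model for the analysis chain: every voxel in the ROI masks
#' carries a common task response (all task events at a fixed amplitude), a
#' prediction-error signal in the coupled ROIs (win events scaled by the
#' trial's PE and a per-ROI gain), a slow cosine drift with random phase,
#' and stationary AR(1) Gaussian noise. The per-ROI gain is chosen so the
#' expected bivalent-win minus reward-win contrast equals \code{coupling}
#' for that ROI (gain = coupling / (mean PE on bivalent wins - mean PE on
#' reward wins)).
#'
#' @param behaviour A \code{subject_behaviour} (with recorded deltas).
#' @param design An \code{fmri_design} for the session.
#' @param masks An \code{roi_mask_set}.
#' @param coupling Named numeric: target COPE per ROI (names must match
#'   \code{masks}).
#' @param noise List with \code{ar1}, \code{sd}, \code{baseline_amp},
#'   \code{drift_amp}, \code{drift_period}.
#' @param pe_amplitudes "trialwise" (win events scaled by their own PE) or
#'   "classmean" (each win event scaled by its regressor-class mean PE,
#'   which puts the signal exactly in the design span).
#' @return V x n_volumes matrix (rows: voxels of the concatenated masks,
#'   in \code{which(mask)} order per ROI) with attribute \code{roi}, a
#'   factor giving each row's ROI.
#' @export
simulate_bold <- function(behaviour, design, masks, coupling,
                          noise = list(ar1 = 0.3, sd = 1, baseline_amp = 0,
                                       drift_amp = 0, drift_period = 128),
                          pe_amplitudes = c("trialwise", "classmean")) {
  pe_amplitudes <- match.arg(pe_amplitudes)
  if (!all(names(masks) %in% names(coupling)))
    stop("coupling must be named for every ROI in masks")
  if (any(!is.finite(unlist(coupling)))) stop("coupling must be finite")
  if (abs(noise$ar1) >= 1) stop("AR(1) coefficient must lie in (-1, 1)")
  nv <- design$n_volumes
  tr <- design$tr

  # common task response: every task event, fixed amplitude
  conv_cols <- design$X[, design$task_labels, drop = FALSE]
  base_sig <- rowSums(conv_cols) * noise$baseline_amp

  # prediction-error signal: win events scaled by PE
  ev <- design$events
  win <- ev$trial_type %in% c("bivalent_win", "reward_win")
  amp <- ev$modulation[win]
  if (pe_amplitudes == "classmean") {
    cls <- ev$trial_type[win]
    amp <- stats::ave(amp, cls, FUN = mean)
  }
  pe_sig <- convolved_regressor(ev$onset[win], ev$duration[win], amp,
                                nv, tr)
  d_biv <- mean(ev$modulation[ev$trial_type == "bivalent_win"])
  d_rew <- mean(ev$modulation[ev$trial_type == "reward_win"])
  d_sub <- d_biv - d_rew
  if (!is.finite(d_sub) || d_sub <= 0.05) {
    # short sessions can leave the subject-specific PE difference ill
    # defined; fall back to the asymptotic contingency value (1.0 - 0.2)
    d_sub <- 0.8
  }
  pe_scale <- 1 / d_sub

  nvox <- vapply(masks, sum, 0L)
  V <- sum(nvox)
  roi <- factor(rep(names(masks), nvox), levels = names(masks))

  Y <- matrix(0, V, nv)
  gains <- unlist(coupling[names(masks)]) * pe_scale
  for (r in names(masks)) {
    rows <- which(roi == r)
    sig <- base_sig + gains[r] * pe_sig
    Y[rows, ] <- matrix(sig, length(rows), nv, byrow = TRUE)
  }
  if (noise$drift_amp > 0) {
    tsec <- (seq_len(nv) - 1) * tr
    phase <- stats::runif(V, 0, 2 * pi)
    Y <- Y + noise$drift_amp *
      cos(outer(phase, 2 * pi * tsec / noise$drift_period, `+`))
  }
  if (noise$sd > 0) {
    innov_sd <- noise$sd * sqrt(1 - noise$ar1^2)
    eps <- matrix(stats::rnorm(V * nv, 0, innov_sd), nv, V)
    ns <- stats::filter(eps, noise$ar1, method = "recursive")
    Y <- Y + t(ns)
  }
  attr(Y, "roi") <- roi
  Y
}

#' Expand a masked voxel-by-time matrix to a 4D array
#' @param Y Matrix from \code{\link{simulate_bold}}.
#' @param masks The \code{roi_mask_set} used to simulate it.
#' @return 4D array (grid dims x time), zero outside the masks.
#' @export
bold_to_4d <- function(Y, masks) {
  dims <- dim(masks[[1L]])
  arr <- array(0, c(dims, ncol(Y)))
  roi <- attr(Y, "roi")
  flat <- matrix(arr, prod(dims), ncol(Y))
  for (r in names(masks)) {
    flat[which(masks[[r]]), ] <- Y[roi == r, , drop = FALSE]
  }
  array(flat, c(dims, ncol(Y)))
}

# smooth random-walk motion nuisance columns
motion_nuisance <- function(n_volumes, n_par = 6L, step_sd = 0.02) {
  rw <- apply(matrix(stats::rnorm(n_volumes * n_par, 0, step_sd),
                     n_volumes, n_par), 2L, cumsum)
  # light smoothing to mimic slow head drift
  k <- rep(1 / 5, 5)
  apply(rw, 2L, function(x) stats::filter(x, k, sides = 2L,
                                          circular = TRUE))
}

#' Generate a full synthetic cohort
#'
#' Draws each subject's group, Q-learning parameters, task schedule,
#' simulated behaviour, reaction times, per-ROI prediction-error coupling
#' and symptom score. BOLD data are not held in memory; they are
#' regenerated deterministically per subject (from recorded seeds) by
#' \code{\link{first_level_copes}}.
#'
#' @param config A \code{cohort_config}.
#' @return Object of class \code{pe_cohort}: list with \code{config} and
#'   \code{subjects} (each with id, group, alpha, beta, behaviour,
#'   coupling, symptom, seed).
#' @export
generate_cohort <- function(config = cohort_config()) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(config$seed)
  n_total <- sum(config$groups)
  subj_seeds <- sample.int(.Machine$integer.max %/% 2L, n_total)
  group <- factor(rep(names(config$groups), config$groups),
                  levels = names(config$groups))

  subjects <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    g <- as.character(group[i])
    gi <- match(g, names(config$groups))
    set.seed(subj_seeds[i])
    ag <- config$agent[[g]]
    a <- ag$alpha_mean; k <- ag$alpha_conc
    alpha <- stats::rbeta(1L, a * k, (1 - a) * k)
    beta <- min(20, max(0.01, stats::rlnorm(1L, ag$beta_meanlog,
                                            ag$beta_sdlog)))
    sch <- generate_schedule(config$n_per_pair, seed = subj_seeds[i])
    beh <- simulate_agent(q_params(alpha, beta,
                                   neutral_value = config$neutral_value,
                                   stickiness = config$stickiness),
                          sch)
    beh$trials$rt_ms <- generate_rts(beh, config$rt)
    coupling <- vapply(config$coupling, function(cp) {
      stats::rnorm(1L, cp$mean[gi], cp$sd[gi])
    }, numeric(1L))
    sy <- config$symptoms[[g]]
    symptom <- if (is.na(sy$mean)) NA_real_ else {
      repeat {
        s <- stats::rnorm(1L, sy$mean, sy$sd)
        if (s >= 0) break
      }
      s
    }
    subjects[[i]] <- list(id = sprintf("sub-%03d", i), group = g,
                          alpha = alpha, beta = beta, behaviour = beh,
                          coupling = coupling, symptom = symptom,
                          seed = subj_seeds[i])
  }
  structure(list(config = config, subjects = subjects, group = group),
            class = "pe_cohort")
}

#' @export
print.pe_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$subjects), "subjects (",
      paste(names(x$config$groups), x$config$groups, collapse = ", "),
      ")\n")
  invisible(x)
}

#' First-level analysis of a synthetic cohort
#'
#' For every subject: regenerate the BOLD data (deterministic from the
#' subject's seed), build the 7-regressor design with temporal derivatives
#' and motion nuisance, fit the voxelwise GLM and form the bivalent-win
#' minus reward-win contrast.
#'
#' @param cohort A \code{pe_cohort}.
#' @param masks An \code{roi_mask_set}; restrict to the ROIs of interest to
#'   save time.
#' @return List of class \code{cope_set}: per ROI a V x N matrix of COPEs,
#'   plus \code{group} (factor) and \code{masks}.
#' @export
first_level_copes <- function(cohort, masks = default_roi_masks()) {
  cfg <- cohort$config
  nv <- cfg$design$n_volumes; tr <- cfg$design$tr
  nvox <- vapply(masks, sum, 0L)
  copes <- lapply(nvox, function(v) matrix(NA_real_, v,
                                           length(cohort$subjects)))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    set.seed(s$seed + 1L)
    ev <- events_from_behaviour(s$behaviour, cfg$design$trial_duration,
                                cfg$design$outcome_delay)
    mo <- motion_nuisance(nv)
    des <- suppressWarnings(
      build_design_matrix(ev, nv, tr, nuisance = mo))
    Y <- simulate_bold(s$behaviour, des, masks,
                       coupling = as.list(s$coupling), noise = cfg$noise)
    fit <- fit_glm(t(Y), des)
    cv <- pe_contrast(fit)
    roi <- attr(Y, "roi")
    for (r in names(masks)) copes[[r]][, i] <- cv[roi == r]
  }
  structure(list(copes = copes, group = cohort$group, masks = masks),
            class = "cope_set")
}

#' Per-subject behavioural summary table for a cohort
#'
#' @param cohort A \code{pe_cohort}.
#' @return Data frame with one row per subject: group, true parameters,
#'   per-pair-type correct rates and mean RTs, overall win-stay/lose-shift,
#'   symptom score.
#' @export
summarise_cohort <- function(cohort) {
  rows <- lapply(cohort$subjects, function(s) {
    cr <- correct_rate(s$behaviour)
    w <- wsls(s$behaviour)
    rt <- tapply(s$behaviour$trials$rt_ms, s$behaviour$trials$pair_type,
                 mean)
    data.frame(id = s$id, group = s$group, alpha = s$alpha, beta = s$beta,
               correct_reward = cr["reward"], correct_bivalent = cr["bivalent"],
               correct_neutral = cr["neutral"],
               win_stay = w["overall", "win_stay"],
               lose_shift = w["overall", "lose_shift"],
               rt_reward = rt["reward"], rt_bivalent = rt["bivalent"],
               rt_neutral = rt["neutral"], symptom = s$symptom,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = names(cohort$config$groups))
  out
}

#' Long-format behavioural data for the mixed ANOVA
#'
#' @param cohort A \code{pe_cohort}.
#' @param measure "correct" (correct-choice proportion) or "rt" (mean RT).
#' @return Data frame with columns value, group, subject, condition.
#' @export
cohort_behaviour_long <- function(cohort, measure = c("correct", "rt")) {
  measure <- match.arg(measure)
  sm <- summarise_cohort(cohort)
  cols <- if (measure == "correct") {
    c(reward = "correct_reward", bivalent = "correct_bivalent",
      neutral = "correct_neutral")
  } else {
    c(reward = "rt_reward", bivalent = "rt_bivalent",
      neutral = "rt_neutral")
  }
  do.call(rbind, lapply(names(cols), function(cn) {
    data.frame(value = sm[[cols[[cn]]]], group = sm$group,
               subject = sm$id, condition = cn, stringsAsFactors = FALSE)
  }))
}
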