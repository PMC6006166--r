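EVENT_LABELS <- c("bivalent_cue", "neutral_cue", "reward_cue",
                  "neutral_outcome", "reward_win", "bivalent_win",
                  "bivalent_loss")

#' Canonical double-gamma haemodynamic response function
#'
#' Difference of two gamma densities (response minus undershoot), peak
#' normalised to 1. Defaults are the widely used canonical settings: peak
#' delay 6 s, undershoot delay 16 s, unit dispersions, undershoot ratio 1/6;
#' with these the kernel peaks near 5 s and has a negative undershoot
#' between roughly 8 and 20 s.
#'
#' @param t Time grid in seconds (values < 0 map to 0).
#' @param peak_delay,undershoot_delay Gamma delays (shape x dispersion), s.
#' @param peak_disp,undershoot_disp Dispersions (gamma scale), s.
#' @param ratio Relative amplitude of the undershoot gamma.
#' @return Kernel values on \code{t}, max 1.
#' @examples
#' h <- double_gamma_hrf(seq(0, 30, 0.1))
#' @export
double_gamma_hrf <- function(t, peak_delay = 6, undershoot_delay = 16,
                             peak_disp = 1, undershoot_disp = 1,
                             ratio = 1 / 6) {
  if (peak_delay <= 0 || undershoot_delay <= 0 || peak_disp <= 0 ||
      undershoot_disp <= 0)
    stop("HRF delays and dispersions must be positive")
  h <- stats::dgamma(pmax(t, 0), shape = peak_delay / peak_disp,
                     scale = peak_disp) -
    ratio * stats::dgamma(pmax(t, 0), shape = undershoot_delay / undershoot_disp,
                          scale = undershoot_disp)
  h[t < 0] <- 0
  h / max(h)
}

#' Build a BIDS-style event table from simulated behaviour
#'
#' Maps each trial to a cue event (labelled by pair type) and an outcome
#' event labelled by one of the seven regressor classes: bivalent, neutral
#' and reward cues; neutral outcomes (neutral feedback on both neutral and
#' reward trials); reward wins; bivalent wins; bivalent losses. All events
#' last 2 s. The \code{modulation} column carries the trial's prediction
#' error for outcome events (1 for cues); it is ignored by the standard
#' design matrix and used by the forward BOLD model and the parametric
#' modulator path.
#'
#' @param behaviour A \code{subject_behaviour}.
#' @param trial_duration Seconds between consecutive cue onsets.
#' @param outcome_delay Seconds from cue onset to outcome onset.
#' @param event_duration Event duration in seconds (2 s).
#' @return Data frame with columns \code{onset}, \code{duration},
#'   \code{trial_type}, \code{modulation}.
#' @export
events_from_behaviour <- function(behaviour, trial_duration = 10,
                                  outcome_delay = 4, event_duration = 2) {
  tr <- behaviour$trials
  n <- nrow(tr)
  cue_on <- (seq_len(n) - 1) * trial_duration
  out_on <- cue_on + outcome_delay
  cue_lab <- paste0(as.character(tr$pair_type), "_cue")
  out_lab <- character(n)
  tp <- as.character(tr$pair_type); fk <- tr$feedback_kind
  out_lab[tp == "neutral"] <- "neutral_outcome"
  out_lab[tp == "reward" & fk == "win"] <- "reward_win"
  out_lab[tp == "reward" & fk != "win"] <- "neutral_outcome"
  out_lab[tp == "bivalent" & fk == "win"] <- "bivalent_win"
  out_lab[tp == "bivalent" & fk == "loss"] <- "bivalent_loss"
  ev <- data.frame(
    onset = c(cue_on, out_on),
    duration = event_duration,
    trial_type = c(cue_lab, out_lab),
    modulation = c(rep(1, n), tr$delta),
    stringsAsFactors = FALSE
  )
  ev <- ev[order(ev$onset), ]
  rownames(ev) <- NULL
  ev
}

validate_events <- function(events, scan_end) {
  need <- c("onset", "duration", "trial_type")
  if (!all(need %in% names(events)))
    stop("events need columns onset, duration, trial_type")
  bad <- setdiff(unique(events$trial_type), EVENT_LABELS)
  if (length(bad)) stop("unknown regressor label(s): ",
                        paste(bad, collapse = ", "))
  if (any(events$onset < 0)) stop("negative event onsets")
  if (any(events$onset + events$duration > scan_end))
    stop("events extend beyond the end of the scan")
  for (lab in unique(events$trial_type)) {
    on <- events$onset[events$trial_type == lab]
    if (is.unsorted(on, strictly = TRUE))
      stop("onsets must be strictly increasing within regressor ", lab)
  }
  invisible(events)
}

#' Build a first-level design matrix
#'
#' Each regressor's 2 s events are represented as boxcars on a fine time
#' grid, convolved with the canonical double-gamma HRF, and sampled at the
#' volume acquisition times; a temporal-derivative column (convolution with
#' the finite-difference kernel) accompanies every task regressor. Nuisance
#' columns (e.g. motion parameters) are appended unconvolved, followed by an
#' intercept. Regressors with zero events yield all-zero columns and are
#' dropped with a warning.
#'
#' @param events Event table (see \code{\link{events_from_behaviour}}).
#' @param n_volumes Number of volumes.
#' @param tr Repetition time, seconds.
#' @param nuisance Optional matrix (\code{n_volumes} rows) of nuisance
#'   regressors.
#' @param dt Microtime resolution for the convolution, seconds.
#' @param pe_modulator If TRUE, append one extra convolved column
#'   ("pe_modulator") holding all outcome events modulated by their
#'   mean-centred \code{modulation} value — the model-based prediction-error
#'   regressor path.
#' @return Object of class \code{fmri_design}: list with the matrix \code{X}
#'   (named columns), \code{tr}, \code{n_volumes}, \code{task_labels}.
#' @export
build_design_matrix <- function(events, n_volumes, tr = 2, nuisance = NULL,
                                dt = 0.1, pe_modulator = FALSE) {
  scan_end <- n_volumes * tr
  validate_events(events, scan_end)
  fine_n <- ceiling(scan_end / dt) + 1L
  fine_t <- (seq_len(fine_n) - 1) * dt
  hrf <- double_gamma_hrf(seq(0, 32, by = dt))
  dhrf <- c(diff(hrf), 0) / dt
  vol_idx <- round((seq_len(n_volumes) - 1) * tr / dt) + 1L

  conv_sample <- function(stim, kernel) {
    full <- stats::convolve(stim, rev(kernel), type = "open") * dt
    full[vol_idx]
  }
  stim_fun <- function(onsets, durations, amp) {
    s <- numeric(fine_n)
    for (k in seq_along(onsets)) {
      i0 <- floor(onsets[k] / dt) + 1L
      i1 <- min(fine_n, floor((onsets[k] + durations[k]) / dt))
      s[i0:i1] <- s[i0:i1] + amp[k]
    }
    s
  }

  present <- EVENT_LABELS[EVENT_LABELS %in% unique(events$trial_type)]
  dropped <- setdiff(EVENT_LABELS, present)
  if (length(dropped))
    warning("regressor(s) with zero events dropped: ",
            paste(dropped, collapse = ", "))

  cols <- list()
  for (lab in present) {
    ev <- events[events$trial_type == lab, ]
    s <- stim_fun(ev$onset, ev$duration, rep(1, nrow(ev)))
    cols[[lab]] <- conv_sample(s, hrf)
    cols[[paste0(lab, "_deriv")]] <- conv_sample(s, dhrf)
  }
  if (pe_modulator) {
    idx <- grepl("_outcome$|_win$|_loss$", events$trial_type)
    ev <- events[idx, ]
    amp <- ev$modulation - mean(ev$modulation)
    s <- stim_fun(ev$onset, ev$duration, amp)
    cols[["pe_modulator"]] <- conv_sample(s, hrf)
  }
  X <- do.call(cbind, cols)
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_volumes)
      stop("nuisance must have n_volumes rows")
    if (is.null(colnames(nuisance)))
      colnames(nuisance) <- paste0("nuisance", seq_len(ncol(nuisance)))
    X <- cbind(X, scale(nuisance, scale = FALSE))
  }
  X <- cbind(X, intercept = 1)
  structure(list(X = X, tr = tr, n_volumes = n_volumes,
                 task_labels = present, events = events),
            class = "fmri_design")
}

#' @export
print.fmri_design <- function(x, ...) {
  cat("First-level design:", x$n_volumes, "volumes, TR", x$tr, "s,",
      ncol(x$X), "columns (", length(x$task_labels), "task regressors +",
      "derivatives + nuisance + intercept )\n")
  invisible(x)
}

# HRF-convolved time course of a set of events with given amplitudes,
# sampled at the volume grid (shared microtime machinery with
# build_design_matrix)
convolved_regressor <- function(onsets, durations, amplitudes, n_volumes,
                                tr = 2, dt = 0.1) {
  scan_end <- n_volumes * tr
  fine_n <- ceiling(scan_end / dt) + 1L
  hrf <- double_gamma_hrf(seq(0, 32, by = dt))
  vol_idx <- round((seq_len(n_volumes) - 1) * tr / dt) + 1L
  s <- numeric(fine_n)
  for (k in seq_along(onsets)) {
    i0 <- floor(onsets[k] / dt) + 1L
    i1 <- min(fine_n, floor((onsets[k] + durations[k]) / dt))
    s[i0:i1] <- s[i0:i1] + amplitudes[k]
  }
  full <- stats::convolve(s, rev(hrf), type = "open") * dt
  full[vol_idx]
}

#' Voxelwise ordinary least squares GLM
#'
#' Fits \code{y = X b + e} per voxel by OLS with a shared design, returning
#' coefficient estimates, residual variance with the correct degrees of
#' freedom, and residuals. Rank-deficient designs are rejected with the
#' offending columns named.
#'
#' @param Y Numeric vector (one voxel) or matrix \code{n_volumes x V}.
#' @param design An \code{fmri_design} (or a plain numeric matrix).
#' @return Object of class \code{fmri_glm}: \code{betas} (p x V),
#'   \code{sigma2} (length V), \code{dof}, \code{labels},
#'   \code{residuals}.
#' @export
fit_glm <- function(Y, design) {
  X <- if (inherits(design, "fmri_design")) design$X else as.matrix(design)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X))
    stop("time series length (", nrow(Y), ") != design rows (", nrow(X), ")")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  betas <- qr.coef(qrX, Y)
  res <- Y - X %*% betas
  dof <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / dof
  structure(list(betas = betas, sigma2 = sigma2, dof = dof,
                 labels = colnames(X), residuals = res),
            class = "fmri_glm")
}

#' Prediction-error contrast (COPE)
#'
#' The value-balanced positive prediction-error contrast: winning
#' \eqn{\pounds}1 in bivalent trials minus winning \eqn{\pounds}1 in reward
#' trials. Both contrasted events are identical \eqn{\pounds}1 wins, so
#' outcome value cancels and the contrast isolates high versus low
#' prediction error. Derivative, cue, loss and nuisance columns carry zero
#' weight.
#'
#' @param fit An \code{fmri_glm} (or a beta matrix with \code{labels}).
#' @param labels Column labels if \code{fit} is a plain matrix.
#' @return Numeric vector of per-voxel contrast values (COPEs).
#' @export
pe_contrast <- function(fit, labels = NULL) {
  if (inherits(fit, "fmri_glm")) {
    betas <- fit$betas; labels <- fit$labels
  } else {
    betas <- as.matrix(fit)
  }
  if (!all(c("bivalent_win", "reward_win") %in% labels))
    stop("design must contain both bivalent_win and reward_win regressors")
  w <- numeric(length(labels))
  w[labels == "bivalent_win"] <- 1
  w[labels == "reward_win"] <- -1
  drop(crossprod(w, betas))
}

#' Write / read a design matrix as CSV
#' @param design An \code{fmri_design}.
#' @param path File path.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design$X), path, row.names = FALSE)
  invisible(path)
}

#' Write events as a BIDS-style TSV
#' @param events Event table.
#' @param path File path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
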