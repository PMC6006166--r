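make_test_behaviour <- function(seed = 2, n_per_pair = 30L) {
  sch <- generate_schedule(n_per_pair, seed = seed)
  set.seed(seed + 500)
  simulate_agent(q_params(0.3, 3), sch)
}

test_that("the double-gamma kernel has the canonical shape", {
  t <- seq(0, 30, 0.1)
  h <- double_gamma_hrf(t)
  expect_equal(h[1], 0)                       # vanishes at the origin
  expect_equal(max(h), 1)                     # peak normalised
  expect_lt(abs(t[which.max(h)] - 5), 0.5)    # peak near 5 s
  late <- t > 8 & t < 20
  expect_lt(min(h[late]), 0)                  # undershoot
  expect_error(double_gamma_hrf(t, peak_delay = -1), "positive")
  expect_error(double_gamma_hrf(t, peak_disp = 0), "positive")
})

test_that("events carry the seven regressor classes with 2 s durations", {
  beh <- make_test_behaviour()
  ev <- events_from_behaviour(beh)
  expect_true(all(ev$duration == 2))
  expect_setequal(unique(ev$trial_type),
                  c("bivalent_cue", "neutral_cue", "reward_cue",
                    "neutral_outcome", "reward_win", "bivalent_win",
                    "bivalent_loss"))
  # neutral feedback on reward trials maps to the shared neutral regressor
  tr <- beh$trials
  n_neutral_ev <- sum(tr$pair_type == "neutral") +
    sum(tr$pair_type == "reward" & tr$feedback_kind != "win")
  expect_equal(sum(ev$trial_type == "neutral_outcome"), n_neutral_ev)
})

test_that("design matrices have one convolved and one derivative column per regressor", {
  beh <- make_test_behaviour()
  ev <- events_from_behaviour(beh)
  d <- build_design_matrix(ev, n_volumes = 458, tr = 2,
                           nuisance = matrix(rnorm(458 * 6), 458))
  expect_equal(length(d$task_labels), 7L)
  expect_equal(sum(grepl("_deriv$", colnames(d$X))), 7L)
  expect_equal(ncol(d$X), 7L + 7L + 6L + 1L)
  expect_equal(qr(d$X)$rank, ncol(d$X))
})

test_that("zero-event regressors are dropped with a warning", {
  beh <- make_test_behaviour()
  ev <- events_from_behaviour(beh)
  ev <- ev[ev$trial_type != "bivalent_loss", ]
  expect_warning(d <- build_design_matrix(ev, 458, 2), "bivalent_loss")
  expect_false("bivalent_loss" %in% colnames(d$X))
})

test_that("bad event tables are rejected", {
  ev <- data.frame(onset = 10, duration = 2, trial_type = "surprise")
  expect_error(build_design_matrix(ev, 100, 2), "unknown regressor")
  ev2 <- data.frame(onset = 300, duration = 2, trial_type = "reward_win")
  expect_error(build_design_matrix(ev2, 100, 2), "beyond the end")
})

test_that("a single event reproduces the boxcar-HRF convolution", {
  ev <- data.frame(onset = 0, duration = 2, trial_type = "reward_win",
                   modulation = 1)
  d <- suppressWarnings(build_design_matrix(ev, 40, 2, dt = 0.1))
  col <- d$X[, "reward_win"]
  # independent direct-sum convolution oracle on the fine grid
  dt <- 0.1
  tfine <- seq(0, 80, by = dt)
  hrf <- double_gamma_hrf(seq(0, 32, by = dt))
  box <- as.numeric(tfine >= 0 & tfine < 2)
  manual <- sapply(seq(1, length(tfine), by = 20), function(i) {
    j <- seq_len(min(i, length(hrf)))
    sum(box[i - j + 1] * hrf[j]) * dt
  })
  expect_equal(unname(col), manual[seq_len(40)], tolerance = 1e-8)
})

test_that("OLS recovers exact coefficients and orthogonal residuals", {
  beh <- make_test_behaviour()
  ev <- events_from_behaviour(beh)
  d <- build_design_matrix(ev, 458, 2)
  b_true <- rnorm(ncol(d$X))
  y <- d$X %*% b_true
  fit <- fit_glm(y, d)
  expect_equal(drop(fit$betas), b_true, tolerance = 1e-9,
               ignore_attr = TRUE)
  set.seed(1)
  y2 <- y + rnorm(458)
  fit2 <- fit_glm(y2, d)
  expect_lt(max(abs(crossprod(d$X, fit2$residuals))), 1e-8)
  expect_equal(fit2$dof, 458L - ncol(d$X))
})

test_that("a tiny worked GLM matches the normal-equation oracle", {
  X <- cbind(reward_win = c(1, 0, 1, 0, 1, 0),
             bivalent_win = c(0, 1, 0, 1, 0, 1))
  y <- c(2, 5, 1.5, 4.5, 2.5, 5.5)
  fit <- fit_glm(y, X)
  oracle <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(drop(fit$betas), drop(oracle), ignore_attr = TRUE)
  expect_equal(pe_contrast(fit$betas, colnames(X)),
               oracle["bivalent_win", ] - oracle["reward_win", ],
               ignore_attr = TRUE)
})

test_that("rank-deficient designs are rejected with the offending column named", {
  X <- cbind(a = rnorm(20), b = 1:20)
  X <- cbind(X, dup = X[, "a"])
  expect_error(fit_glm(rnorm(20), X), "dup|a")
})

test_that("the contrast requires both win regressors", {
  b <- matrix(c(2, 0.5), 2, 1, dimnames = list(NULL, NULL))
  expect_equal(pe_contrast(b, c("bivalent_win", "reward_win")), 1.5)
  expect_error(pe_contrast(b, c("bivalent_win", "reward_cue")),
               "reward_win")
})

test_that("the contrast is balanced for outcome value but sensitive to PE", {
  beh <- make_test_behaviour(seed = 3)
  ev <- events_from_behaviour(beh)
  d <- build_design_matrix(ev, 458, 2)
  # value-only response: every win, either kind, at identical amplitude
  win <- ev$trial_type %in% c("bivalent_win", "reward_win")
  y_val <- 3 * pefmri:::convolved_regressor(ev$onset[win], ev$duration[win],
                                            rep(1, sum(win)), 458, 2)
  expect_equal(pe_contrast(fit_glm(y_val, d)), 0, tolerance = 1e-8)
  # PE-scaled response: bivalent wins carry larger PE, so the COPE is positive
  y_pe <- 3 * pefmri:::convolved_regressor(ev$onset[win], ev$duration[win],
                                           ev$modulation[win], 458, 2)
  expect_gt(pe_contrast(fit_glm(y_pe, d)), 0.5)
})

test_that("null data yield contrasts centred on zero", {
  beh <- make_test_behaviour(seed = 4)
  ev <- events_from_behaviour(beh)
  d <- build_design_matrix(ev, 458, 2)
  set.seed(9)
  copes <- pe_contrast(fit_glm(matrix(rnorm(458 * 200), 458), d))
  expect_lt(abs(mean(copes)) / (sd(copes) / sqrt(200)), 4)
})

test_that("the parametric-modulator path agrees in sign with the contrast path", {
  for (seed in 5:8) {
    beh <- make_test_behaviour(seed = seed)
    ev <- events_from_behaviour(beh)
    d_con <- build_design_matrix(ev, 458, 2)
    d_mod <- build_design_matrix(ev, 458, 2, pe_modulator = TRUE)
    win <- ev$trial_type %in% c("bivalent_win", "reward_win")
    set.seed(seed)
    y <- 2 * pefmri:::convolved_regressor(ev$onset[win], ev$duration[win],
                                          ev$modulation[win], 458, 2) +
      rnorm(458, sd = 0.5)
    cope <- pe_contrast(fit_glm(y, d_con))
    b_mod <- unname(fit_glm(y, d_mod)$betas["pe_modulator", ])
    expect_equal(sign(unname(cope)), sign(b_mod))
    expect_gt(cope, 0)
  }
})
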