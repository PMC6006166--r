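test_that("sphere masks match an exhaustive lattice enumeration", {
  # 10 mm sphere on a 2 mm grid, centred on a voxel: count lattice points
  # with i^2 + j^2 + k^2 <= 25 (in voxel units)
  cnt <- 0L
  for (i in -5:5) for (j in -5:5) for (k in -5:5)
    if (i^2 + j^2 + k^2 <= 25) cnt <- cnt + 1L
  m <- make_roi_masks(c(15, 15, 15), 2, c(-14, -14, -14),
                      list(s = list(type = "sphere", center = c(0, 0, 0),
                                    radius = 10)))
  expect_equal(sum(m$s), cnt)
  expect_equal(cnt, 515L)
})

test_that("a tiny radius keeps only the centre voxel; off-grid centres fail", {
  m <- make_roi_masks(c(5, 5, 5), 2, c(-4, -4, -4),
                      list(s = list(type = "sphere", center = c(0, 0, 0),
                                    radius = 0.1)))
  expect_equal(sum(m$s), 1L)
  expect_error(
    make_roi_masks(c(5, 5, 5), 2, c(-4, -4, -4),
                   list(s = list(type = "sphere", center = c(1, 1, 1),
                                 radius = 0.1))),
    "empty")
  expect_error(
    make_roi_masks(c(5, 5, 5), 2, c(0, 0, 0),
                   list(a = list(type = "sphere", center = c(2, 2, 2),
                                 radius = 1),
                        a = list(type = "sphere", center = c(4, 4, 4),
                                 radius = 1))),
    "duplicate")
})

test_that("default ROIs include the 10 mm DLPFC sphere at (50, 30, 28)", {
  masks <- default_roi_masks()
  expect_named(masks, c("midbrain", "striatum", "dlpfc"))
  # independent check: recompute membership from mm coordinates
  co <- pefmri:::voxel_coords(masks$dlpfc)
  d <- sqrt(colSums((t(co) - c(50, 30, 28))^2))
  expect_true(all(d <= 10))
  expect_equal(sum(masks$dlpfc), 515L)  # full sphere inside the grid
  # non-empty and pairwise disjoint
  expect_true(all(vapply(masks, sum, 0L) > 0))
  expect_lte(max(masks$midbrain + masks$striatum + masks$dlpfc), 1L)
})

test_that("masks survive a NIfTI round trip", {
  masks <- default_roi_masks()
  path <- tempfile(fileext = ".nii.gz")
  write_nifti_image(masks$midbrain, path)
  back <- read_nifti_mask(path)
  expect_equal(array(back, dim(back)), array(masks$midbrain > 0,
                                             dim(masks$midbrain)))
  expect_equal(attr(back, "voxel_mm"), 2)
})

test_that("configuration bounds are enforced", {
  expect_error(cohort_config(groups = c(a = 0L, b = 3L)), "positive")
  expect_error(cohort_config(noise = list(ar1 = 1.2, sd = 1)), "AR")
  expect_error(cohort_config(noise = list(ar1 = 0.3, sd = -1)), "noise SD")
  expect_error(cohort_config(
    coupling = list(midbrain = list(mean = c(1, 2), sd = c(1, 1)))),
    "one entry per group")
})

test_that("cohorts have the configured group structure and are reproducible", {
  cfg <- cohort_config(seed = 3)
  co <- generate_cohort(cfg)
  expect_equal(unname(table(co$group)), array(c(39L, 30L, 14L)))
  expect_length(co$subjects, 83L)
  co2 <- generate_cohort(cfg)
  expect_identical(summarise_cohort(co), summarise_cohort(co2))
  # symptom scores only in the patient groups, truncated at zero
  sy <- vapply(co$subjects, function(s) s$symptom, numeric(1))
  expect_true(all(is.na(sy[co$group == "controls"])))
  expect_true(all(sy[co$group != "controls"] >= 0))
})

test_that("cohort behaviour reproduces the reported group statistics", {
  co <- generate_cohort(cohort_config(seed = 11))
  sm <- summarise_cohort(co)
  expect_equal(mean(sm$correct_reward), 0.75, tolerance = 0.06 / 0.75)
  expect_equal(mean(sm$correct_neutral), 0.55, tolerance = 0.08 / 0.55)
  expect_lt(abs(mean(sm$correct_bivalent) - 0.5), 0.06)
  expect_equal(mean(sm$win_stay), 0.69, tolerance = 0.09 / 0.69)
  expect_equal(mean(sm$lose_shift), 0.44, tolerance = 0.09 / 0.44)
  expect_equal(mean(sm$rt_reward), 1122.83, tolerance = 40 / 1122.83)
  expect_equal(mean(sm$rt_bivalent), 1358.99, tolerance = 45 / 1358.99)
  expect_equal(mean(sm$rt_neutral), 1329.30, tolerance = 45 / 1329.30)
})

test_that("reaction-time generation honours its moments and support", {
  sch <- generate_schedule(30, seed = 4)
  set.seed(4)
  beh <- simulate_agent(q_params(0.3, 3), sch)
  # zero-variance model returns the configured means exactly
  rt0 <- generate_rts(beh, list(mean_ms = c(reward = 1000, bivalent = 1200,
                                            neutral = 1100),
                                between_sdlog = 0, within_sdlog = 0))
  expect_equal(unique(rt0[beh$trials$pair_type == "reward"]), 1000)
  expect_equal(unique(rt0[beh$trials$pair_type == "bivalent"]), 1200)
  for (seed in 1:5) {
    set.seed(seed)
    rt <- generate_rts(beh, list(mean_ms = c(reward = 1000, bivalent = 1200,
                                             neutral = 1100),
                                 between_sdlog = 0.2, within_sdlog = 0.3))
    expect_true(all(rt > 0))
  }
})

test_that("simulated noise has the configured AR(1) autocorrelation", {
  sch <- generate_schedule(6, seed = 5)
  set.seed(5)
  beh <- simulate_agent(q_params(0.3, 3), sch)
  ev <- events_from_behaviour(beh)
  des <- build_design_matrix(ev, 500, 2)
  masks <- make_roi_masks(c(6, 6, 6), 2, c(-5, -5, -5),
                          list(r = list(type = "box", center = c(0, 0, 0),
                                        halfsize = c(5, 5, 5))))
  set.seed(6)
  Y <- simulate_bold(beh, des, masks, coupling = list(r = 0),
                     noise = list(ar1 = 0.3, sd = 1, baseline_amp = 0,
                                  drift_amp = 0, drift_period = 128))
  ac1 <- mean(apply(Y, 1L, function(x) cor(x[-1], x[-length(x)])))
  expect_equal(ac1, 0.3, tolerance = 0.05 / 0.3)
  sds <- apply(Y, 1L, sd)
  expect_equal(mean(sds), 1, tolerance = 0.05)
})

test_that("zero-noise class-mean coupling is recovered to machine precision", {
  sch <- generate_schedule(30, seed = 7)
  set.seed(7)
  beh <- simulate_agent(q_params(0.3, 3), sch)
  ev <- events_from_behaviour(beh)
  mo <- matrix(rnorm(458 * 6, sd = 0.01), 458)
  des <- build_design_matrix(ev, 458, 2, nuisance = mo)
  masks <- make_roi_masks(c(4, 4, 4), 2, c(-3, -3, -3),
                          list(r = list(type = "box", center = c(0, 0, 0),
                                        halfsize = c(3, 3, 3))))
  Y <- simulate_bold(beh, des, masks, coupling = list(r = 42),
                     noise = list(ar1 = 0, sd = 0, baseline_amp = 5,
                                  drift_amp = 0, drift_period = 128),
                     pe_amplitudes = "classmean")
  copes <- pe_contrast(fit_glm(t(Y), des))
  expect_equal(unname(copes), rep(42, sum(masks$r)), tolerance = 1e-6)
})

test_that("null coupling yields group-mean contrasts near zero", {
  cfg <- cohort_config(
    groups = c(controls = 10L, at_risk = 8L, fep = 6L),
    coupling = list(midbrain = list(mean = c(0, 0, 0), sd = c(5, 5, 5))),
    seed = 8)
  co <- generate_cohort(cfg)
  masks <- default_roi_masks()["midbrain"]
  class(masks) <- "roi_mask_set"
  cs <- first_level_copes(co, masks)
  gm <- mean(colMeans(cs$copes$midbrain))
  se <- sd(colMeans(cs$copes$midbrain)) / sqrt(24)
  expect_lt(abs(gm) / se, 4)
})

test_that("first-level contrasts track each subject's configured coupling", {
  cfg <- cohort_config(
    groups = c(controls = 8L, fep = 6L),
    coupling = list(midbrain = list(mean = c(24.44, -55.03),
                                    sd = c(50.12, 50.70)),
                    dlpfc = list(mean = c(32.90, -45.13),
                                 sd = c(62.82, 48.40))),
    seed = 9)
  co <- generate_cohort(cfg)
  masks <- default_roi_masks()[c("midbrain", "dlpfc")]
  class(masks) <- "roi_mask_set"
  cs <- first_level_copes(co, masks)
  for (r in c("midbrain", "dlpfc")) {
    est <- colMeans(cs$copes[[r]])
    true <- vapply(co$subjects, function(s) s$coupling[[r]], numeric(1))
    expect_gt(cor(est, true), 0.95)
    expect_lt(mean(abs(est - true)), 12)
  }
})
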