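small_mask <- function(dims = c(4, 4, 3)) {
  m <- array(TRUE, dims)
  attr(m, "voxel_mm") <- 2
  m
}

test_that("the unsmoothed voxelwise F matches a classical ANOVA oracle", {
  set.seed(1)
  copes <- matrix(rnorm(3 * 12), 3, 12)  # 3 voxels, 12 subjects
  grp <- factor(rep(c("a", "b", "c"), each = 4))
  f <- voxelwise_stat(copes, grp, smooth = NULL)
  for (v in 1:3) {
    oracle <- summary(stats::aov(copes[v, ] ~ grp))[[1]]["grp", "F value"]
    expect_equal(f[v], oracle, tolerance = 1e-10)
  }
  # identical subjects: no between-group variance anywhere
  same <- matrix(rep(rnorm(3), 12), 3, 12)
  expect_equal(voxelwise_stat(same, grp), rep(0, 3))
})

test_that("the pairwise pseudo-t at zero smoothing equals the pooled t statistic", {
  set.seed(2)
  x <- matrix(rnorm(2 * 20), 2, 20)
  grp <- factor(rep(c("a", "b"), each = 10), levels = c("a", "b"))
  t_pkg <- voxelwise_stat(x, grp, mode = "pairwise",
                          levels_pair = c("a", "b"))
  for (v in 1:2) {
    oracle <- stats::t.test(x[v, 1:10], x[v, 11:20],
                            var.equal = TRUE)$statistic
    expect_equal(t_pkg[v], unname(oracle), tolerance = 1e-10)
  }
})

test_that("variance smoothing pools variance over neighbouring voxels", {
  coords <- cbind(c(0, 2, 40), 0, 0)
  W <- smoothing_weights(coords, fwhm = 3)
  expect_equal(unname(rowSums(W)), rep(1, 3))
  expect_gt(W[1, 2], W[1, 3])  # near voxel weighted far above the distant one
  expect_equal(smoothing_weights(coords, 0), diag(3))
})

test_that("TFCE matches the single-voxel closed form and is monotone", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  s <- array(0, c(5, 5, 5)); s[3, 3, 3] <- 2.5
  # closed form: integral of h^H dh = h^(H+1)/(H+1) for an isolated voxel
  tv <- tfce(s, mask = NULL, E = 0.5, H = 2, dh = 2.5 / 1000)
  expect_equal(tv[3, 3, 3], 2.5^3 / 3, tolerance = 0.01)
  expect_equal(tfce(array(0, c(3, 3, 3))), array(0, c(3, 3, 3)))
  # raising one voxel never decreases TFCE anywhere
  set.seed(3)
  base <- array(abs(rnorm(27)), c(3, 3, 3))
  t0 <- tfce(base, dh = max(base) / 200)
  up <- base; up[2, 2, 2] <- up[2, 2, 2] + 1
  t1 <- tfce(up, dh = max(base) / 200)
  expect_true(all(t1 - t0 > -1e-12))
  expect_error(tfce(array(c(NA, rep(1, 26)), c(3, 3, 3))), "non-finite")
})

test_that("TFCE extent term follows a two-voxel cluster oracle", {
  s <- array(0, c(4, 1, 1)); s[1:2, 1, 1] <- 3
  tv <- tfce(s, E = 0.5, H = 2, dh = 3 / 2000)
  # both voxels sit in a size-2 cluster at every threshold
  expect_equal(tv[1, 1, 1], sqrt(2) * 3^3 / 3, tolerance = 0.01)
  expect_equal(tv[2, 1, 1], tv[1, 1, 1])
})

test_that("corrected p-values respect the permutation floor and the alpha rule", {
  set.seed(4)
  m <- small_mask()
  V <- sum(m)
  grp <- factor(rep(c("a", "b", "c"), each = 8))
  copes <- matrix(rnorm(V * 24), V, 24)
  copes[, grp == "a"] <- copes[, grp == "a"] + 4  # strong group effect
  res <- permutation_fwe(copes, grp, m, n_perm = 199, seed = 5)
  expect_true(all(res$p_corrected >= 1 / 200))
  expect_true(all(res$p_corrected <= 1))
  expect_equal(res$significant, res$p_corrected <= 0.05)
  expect_equal(res$n_perm_used, 199L)
  # determinism
  res2 <- permutation_fwe(copes, grp, m, n_perm = 199, seed = 5)
  expect_identical(res$p_corrected, res2$p_corrected)
})

test_that("a single-voxel mask reduces FWE correction to the uncorrected test", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  attr(m, "voxel_mm") <- 2
  set.seed(6)
  grp <- factor(rep(c("a", "b"), each = 10), levels = c("a", "b"))
  copes <- matrix(rnorm(20), 1, 20)
  copes[, 1:10] <- copes[, 1:10] + 1.5
  res <- permutation_fwe(copes, grp, m, n_perm = 499, seed = 7,
                         mode = "pairwise", levels_pair = c("a", "b"))
  # with one voxel the max statistic IS the voxel statistic
  manual <- (1 + sum(res$max_null >= res$tfce)) / (res$n_perm_used + 1)
  expect_equal(res$p_corrected, manual)
})

test_that("small designs are enumerated exhaustively", {
  m <- array(FALSE, c(3, 1, 1)); m[1:2, 1, 1] <- TRUE
  attr(m, "voxel_mm") <- 2
  grp <- factor(rep(c("a", "b"), each = 3), levels = c("a", "b"))
  copes <- rbind(c(5, 6, 7, 1, 2, 3), c(1, 1, 2, 1, 2, 1))
  res <- permutation_fwe(copes, grp, m, n_perm = 100, seed = 8,
                         mode = "pairwise", levels_pair = c("a", "b"))
  expect_true(res$exhaustive)
  expect_equal(res$n_perm_used, choose(6, 3))
  # the observed extreme labelling achieves the minimum attainable p
  expect_equal(min(res$p_corrected), 1 / choose(6, 3))
})

test_that("corrected p dominates the uncorrected permutation p at every voxel", {
  # exhaustive two-group case, cross-checked against an enumeration oracle
  # written out in the test
  m <- array(TRUE, c(2, 2, 1)); attr(m, "voxel_mm") <- 2
  set.seed(11)
  grp <- factor(rep(c("a", "b"), each = 4), levels = c("a", "b"))
  copes <- matrix(rnorm(4 * 8), 4, 8)
  copes[1, 1:4] <- copes[1, 1:4] + 3
  res <- permutation_fwe(copes, grp, m, n_perm = 100, seed = 12,
                         mode = "pairwise", fwhm = 0, dh = 0.01)
  expect_true(res$exhaustive)
  # oracle: enumerate all 70 labelings directly
  combos <- utils::combn(8, 4)
  tf <- matrix(NA_real_, ncol(combos), 4)
  for (k in seq_len(ncol(combos))) {
    g <- factor(rep("b", 8), levels = c("a", "b"))
    g[combos[, k]] <- "a"
    s <- voxelwise_stat(copes, g, mode = "pairwise",
                        levels_pair = c("a", "b"))
    tf[k, ] <- tfce(s, m, dh = 0.01)
  }
  obs <- which(apply(combos, 2L, function(ix) all(ix == 1:4)))
  p_unc <- sapply(1:4, function(v) mean(tf[, v] >= tf[obs, v]))
  p_cor <- sapply(1:4, function(v) mean(apply(tf, 1L, max) >= tf[obs, v]))
  expect_equal(res$p_corrected, p_cor, tolerance = 1e-12)
  expect_true(all(p_cor >= p_unc))
})

test_that("restricting to a voxel subset restricts the correction", {
  set.seed(9)
  m <- small_mask()
  V <- sum(m)
  grp <- factor(rep(c("a", "b"), each = 10))
  copes <- matrix(rnorm(V * 20), V, 20)
  res <- permutation_fwe(copes, grp, m, n_perm = 199, seed = 10,
                         mode = "pairwise", voxel_subset = 1:5)
  expect_length(res$p_corrected, 5L)
  expect_equal(sum(res$mask), 5L)
})

test_that("cluster means are exact averages and empty sets are flagged", {
  copes <- rbind(c(1, 3), c(1, 3), c(1, 3))
  grp <- factor(c("a", "b"))
  cs <- extract_cluster_means(copes, c(TRUE, TRUE, FALSE), grp,
                              planned = NULL)
  expect_equal(unname(cs$subject_means), c(1, 3))
  expect_equal(cs$n_voxels, 2L)
  empty <- extract_cluster_means(copes, logical(3), grp)
  expect_true(empty$no_significant_voxels)
  expect_equal(empty$n_voxels, 0L)
})

test_that("planned comparisons recover the reported midbrain and DLPFC patterns", {
  # groups drawn from Gaussians with the reported cluster-mean moments
  draw <- function(mom, n, seed) {
    set.seed(seed); rnorm(n, mom[1], mom[2])
  }
  grp <- factor(rep(c("controls", "at_risk", "fep"), c(39, 30, 14)),
                levels = c("controls", "at_risk", "fep"))
  hits_cf <- 0; p_ca_dlpfc <- numeric(6)
  for (r in 1:6) {
    mb <- c(draw(c(24.44, 50.12), 39, 100 + r),
            draw(c(0.66, 54.86), 30, 200 + r),
            draw(c(-55.03, 50.70), 14, 300 + r))
    copes <- matrix(mb, 1, 83)  # cluster already averaged: one "voxel"
    cs <- extract_cluster_means(copes, 1L, grp,
                                planned = c("controls", "at_risk", "fep"),
                                n_perm = 2000, seed = r)
    p_cf <- cs$pairwise$p_one_tailed[cs$pairwise$greater == "controls" &
                                       cs$pairwise$lesser == "fep"]
    if (p_cf < 0.001) hits_cf <- hits_cf + 1
    dl <- c(draw(c(32.90, 62.82), 39, 400 + r),
            draw(c(36.29, 53.03), 30, 500 + r),
            draw(c(-45.13, 48.40), 14, 600 + r))
    cs2 <- extract_cluster_means(matrix(dl, 1, 83), 1L, grp,
                                 planned = c("controls", "at_risk", "fep"),
                                 n_perm = 2000, seed = 50 + r)
    p_ca_dlpfc[r] <- cs2$pairwise$p_one_tailed[
      cs2$pairwise$greater == "controls" & cs2$pairwise$lesser == "at_risk"]
  }
  expect_gte(hits_cf, 4)               # controls > FEP: p < 0.001 in most runs
  expect_gt(mean(p_ca_dlpfc), 0.3)     # controls vs at-risk: clearly null
})

test_that("Spearman correlations handle monotone, tied and constant input", {
  expect_equal(symptom_correlation(1:10, (1:10)^2)$rho, 1)
  expect_equal(symptom_correlation(1:10, -(1:10))$rho, -1)
  x <- c(1, 2, 2, 3, 5, 5, 7)
  y <- c(2, 1, 4, 4, 6, 8, 9)
  # oracle: Pearson on midranks
  expect_equal(symptom_correlation(x, y)$rho,
               unname(cor(rank(x), rank(y))), tolerance = 1e-12)
  const <- symptom_correlation(rep(3, 5), 1:5)
  expect_true(const$undefined)
  expect_true(is.na(const$rho))
  expect_error(symptom_correlation(1:2, 1:2), "at least 3")
})
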