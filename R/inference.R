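#' Gaussian smoothing weights within a mask
#'
#' Row-normalised Gaussian kernel weights between mask voxels, used to
#' smooth variance images before forming pseudo-t/F statistics. The
#' normalisation per row renormalises the kernel at mask edges, so no signal
#' leaks outside the mask.
#'
#' @param coords V x 3 matrix of voxel centre coordinates in mm.
#' @param fwhm Kernel full width at half maximum in mm; 0 gives identity.
#' @return V x V weight matrix with unit row sums.
#' @export
smoothing_weights <- function(coords, fwhm) {
  v <- nrow(coords)
  if (fwhm <= 0) return(diag(v))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  d2 <- as.matrix(stats::dist(coords))^2
  W <- exp(-d2 / (2 * sigma^2))
  W / rowSums(W)
}

# per-voxel one-way ANOVA pieces given copes (V x N) and a group indicator
# matrix Gind (N x G, columns one-hot); returns between mean square and the
# pooled within-group variance (per voxel)
anova_pieces <- function(copes, Gind, ng) {
  N <- sum(ng); G <- length(ng)
  means <- sweep(copes %*% Gind, 2L, ng, "/")  # V x G group means
  grand <- rowSums(copes) / N
  sum_ng_m2 <- drop((means^2) %*% ng)
  ssb <- sum_ng_m2 - N * grand^2
  ssw <- rowSums(copes^2) - sum_ng_m2
  list(msb = ssb / (G - 1L), varw = ssw / (N - G))
}

#' Voxelwise group statistic with variance smoothing
#'
#' One-way ANOVA F (mode "anova") or two-sample t (mode "pairwise") per
#' voxel, with the pooled within-group variance image Gaussian-smoothed at
#' the given FWHM before the statistic is formed (a pseudo-F/t, as
#' recommended for modest sample sizes). FWHM 0 reproduces the classical
#' statistic.
#'
#' @param copes V x N matrix of per-subject contrast values (rows: voxels).
#' @param groups Factor of length N.
#' @param smooth Either a precomputed V x V weight matrix
#'   (\code{\link{smoothing_weights}}) or NULL for no smoothing.
#' @param mode "anova" or "pairwise".
#' @param levels_pair For pairwise mode, character vector c(a, b); the
#'   statistic is positive when group a exceeds group b.
#' @return Numeric vector of per-voxel statistics.
#' @export
voxelwise_stat <- function(copes, groups, smooth = NULL,
                           mode = c("anova", "pairwise"),
                           levels_pair = NULL) {
  mode <- match.arg(mode)
  groups <- droplevels(as.factor(groups))
  ng <- tabulate(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(ng < 2L)) stop("every group needs at least 2 subjects")
  copes <- as.matrix(copes)
  if (ncol(copes) != length(groups))
    stop("copes columns must match the number of subjects")
  Gind <- stats::model.matrix(~ groups - 1)
  pieces <- anova_pieces(copes, Gind, ng)
  varw <- pieces$varw
  if (!is.null(smooth)) varw <- drop(smooth %*% varw)
  varw <- pmax(varw, .Machine$double.eps)
  if (mode == "anova") {
    pieces$msb / varw
  } else {
    if (is.null(levels_pair)) levels_pair <- levels(groups)[1:2]
    i1 <- groups == levels_pair[1L]; i2 <- groups == levels_pair[2L]
    m1 <- rowMeans(copes[, i1, drop = FALSE])
    m2 <- rowMeans(copes[, i2, drop = FALSE])
    (m1 - m2) / sqrt(varw * (1 / sum(i1) + 1 / sum(i2)))
  }
}

#' Threshold-free cluster enhancement
#'
#' Integrates cluster extent and height over all thresholds:
#' \deqn{TFCE(v) = \sum_h e(h, v)^E h^H \, dh} over \eqn{0 < h \le stat(v)},
#' where \eqn{e(h,v)} is the size of the 6-connected supra-threshold cluster
#' containing v at height h. Defaults E = 0.5, H = 2 and dh = max/100 are
#' the standard published settings. Negative statistic values contribute
#' nothing (one-tailed enhancement).
#'
#' @param stat_map Numeric vector over mask voxels, or a full 3D array.
#' @param mask 3D logical array (required when \code{stat_map} is a vector).
#' @param E,H TFCE exponents (extent, height).
#' @param dh Threshold step; default max(stat)/100.
#' @return TFCE values in the same shape as the input (vector over mask
#'   voxels, or 3D array).
#' @export
tfce <- function(stat_map, mask = NULL, E = 0.5, H = 2, dh = NULL) {
  if (any(!is.finite(stat_map))) stop("non-finite statistic values")
  if (E < 0 || H < 0) stop("E and H must be >= 0")
  vec_in <- is.null(dim(stat_map)) || length(dim(stat_map)) != 3L
  if (vec_in) {
    if (is.null(mask)) stop("mask required for vector input")
    arr <- array(0, dim(mask))
    arr[mask] <- pmax(stat_map, 0)
  } else {
    arr <- pmax(stat_map, 0)
    if (!is.null(mask)) arr[!mask] <- 0
  }
  mx <- max(arr)
  if (is.null(dh)) dh <- if (mx > 0) mx / 100 else 1
  if (dh <= 0) stop("dh must be positive")
  out <- tfce_cpp(as.numeric(arr), dim(arr), E, H, dh)
  out <- array(out, dim(arr))
  if (vec_in) out[mask] else out
}

# enumerate all distinct assignments of N items to groups of sizes ng
# (as a list of integer label vectors); used for exhaustive permutation
enumerate_assignments <- function(ng) {
  N <- sum(ng)
  rec <- function(avail, sizes) {
    if (length(sizes) == 1L) return(list(list(avail)))
    out <- list()
    cmb <- utils::combn(avail, sizes[1L], simplify = FALSE)
    for (g1 in cmb) {
      rest <- rec(setdiff(avail, g1), sizes[-1L])
      for (r in rest) out[[length(out) + 1L]] <- c(list(g1), r)
    }
    out
  }
  parts <- rec(seq_len(N), ng)
  lapply(parts, function(p) {
    lab <- integer(N)
    for (g in seq_along(p)) lab[p[[g]]] <- g
    lab
  })
}

n_distinct_assignments <- function(ng) {
  exp(lgamma(sum(ng) + 1) - sum(lgamma(ng + 1)))
}

#' Permutation inference with TFCE and max-statistic FWE correction
#'
#' Group-level permutation test on per-subject contrast maps within an ROI
#' mask. Each permutation shuffles group labels, recomputes the
#' variance-smoothed voxelwise statistic (ANOVA F across groups, or a
#' one-tailed two-sample t in pairwise mode), applies TFCE, and records the
#' image-wide maximum. The FWE-corrected p at a voxel is the proportion of
#' the null set (observed labelling included) whose maximum TFCE reaches
#' that voxel's observed TFCE. When the number of distinct labelings does
#' not exceed \code{n_perm} the null set is enumerated exhaustively and
#' flagged. Voxels with corrected p <= alpha form the significant set
#' (p equal to alpha counts as significant).
#'
#' @param copes V x N matrix of contrast values over the mask voxels
#'   (row order = \code{which(mask)}).
#' @param groups Factor of length N.
#' @param mask 3D logical array; \code{sum(mask)} must equal \code{nrow(copes)}.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed for the permutation draws.
#' @param mode "anova" (F across all groups) or "pairwise".
#' @param levels_pair Pairwise mode: c(a, b) tests a > b one-tailed.
#' @param voxel_subset Optional logical/integer subset of mask voxels over
#'   which to test (e.g. voxels significant in a previous ANOVA); the
#'   max statistic and correction are restricted to that subset.
#' @param fwhm Variance-smoothing FWHM in mm.
#' @param voxel_mm Voxel size in mm (isotropic) used for smoothing distances.
#' @param E,H,dh TFCE parameters; \code{dh} defaults to the observed
#'   maximum / 100 and is held fixed across permutations.
#' @param alpha Significance level (default 0.05).
#' @return Object of class \code{pe_inference}: list with \code{stat},
#'   \code{tfce}, \code{p_corrected}, \code{significant} (all over the
#'   tested voxels), \code{max_null} (null distribution of maxima),
#'   \code{n_perm_used}, \code{exhaustive}, \code{mode}, \code{seed}.
#' @export
permutation_fwe <- function(copes, groups, mask, n_perm = 1000L, seed = 1L,
                            mode = c("anova", "pairwise"),
                            levels_pair = NULL, voxel_subset = NULL,
                            fwhm = 3, voxel_mm = 2, E = 0.5, H = 2,
                            dh = NULL, alpha = 0.05) {
  mode <- match.arg(mode)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  groups <- droplevels(as.factor(groups))
  copes <- as.matrix(copes)
  if (sum(mask) != nrow(copes))
    stop("copes rows must equal the number of mask voxels")

  if (mode == "pairwise") {
    if (is.null(levels_pair)) levels_pair <- levels(groups)[1:2]
    keep <- groups %in% levels_pair
    copes <- copes[, keep, drop = FALSE]
    groups <- droplevels(groups[keep])
    groups <- factor(groups, levels = levels_pair)
  }

  test_mask <- mask
  if (!is.null(voxel_subset)) {
    idx_all <- which(mask)
    sub <- if (is.logical(voxel_subset)) which(voxel_subset) else voxel_subset
    test_mask <- array(FALSE, dim(mask))
    test_mask[idx_all[sub]] <- TRUE
    copes <- copes[sub, , drop = FALSE]
  }

  coords <- voxel_coords(test_mask, voxel_mm)
  W <- smoothing_weights(coords, fwhm)

  stat_obs <- voxelwise_stat(copes, groups, smooth = W, mode = mode,
                             levels_pair = levels_pair)
  if (is.null(dh)) {
    mx <- max(c(stat_obs, 0))
    dh <- if (mx > 0) mx / 100 else 1
  }
  tfce_obs <- tfce(stat_obs, test_mask, E = E, H = H, dh = dh)

  ng <- tabulate(groups)
  exhaustive <- n_distinct_assignments(ng) <= n_perm
  if (exhaustive) {
    labs <- enumerate_assignments(ng)
    # map enumerated integer labels onto the observed label multiset
    perms <- lapply(labs, function(l) factor(levels(groups)[l],
                                             levels = levels(groups)))
  } else {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
    perms <- replicate(n_perm, sample(groups), simplify = FALSE)
  }

  max_null <- vapply(perms, function(g) {
    s <- voxelwise_stat(copes, g, smooth = W, mode = mode,
                        levels_pair = levels(groups)[1:2])
    max(tfce(s, test_mask, E = E, H = H, dh = dh))
  }, numeric(1L))

  if (exhaustive) {
    p_corr <- vapply(tfce_obs, function(t0) mean(max_null >= t0), numeric(1L))
  } else {
    p_corr <- vapply(tfce_obs, function(t0) {
      (1 + sum(max_null >= t0)) / (n_perm + 1)
    }, numeric(1L))
  }
  structure(list(
    stat = stat_obs, tfce = tfce_obs, p_corrected = p_corr,
    significant = p_corr <= alpha, mask = test_mask,
    max_null = max_null, n_perm_used = length(perms),
    exhaustive = exhaustive, mode = mode, seed = seed,
    alpha = alpha, params = list(E = E, H = H, dh = dh, fwhm = fwhm)
  ), class = "pe_inference")
}

#' @export
print.pe_inference <- function(x, ...) {
  cat("Permutation TFCE inference (", x$mode, " mode, ",
      x$n_perm_used, if (x$exhaustive) " exhaustive" else "", " permutations)\n",
      sep = "")
  cat("  voxels tested:", length(x$stat),
      " significant (p <=", x$alpha, "):", sum(x$significant), "\n")
  cat("  min corrected p:", format(min(x$p_corrected), digits = 4), "\n")
  invisible(x)
}

# scalar one-tailed two-sample permutation test (mean(x) > mean(y))
perm_test_greater <- function(x, y, n_perm = 10000L, seed = 1L) {
  obs <- mean(x) - mean(y)
  pool <- c(x, y); n1 <- length(x)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  null <- replicate(n_perm, {
    idx <- sample.int(length(pool), n1)
    mean(pool[idx]) - mean(pool[-idx])
  })
  (1 + sum(null >= obs)) / (n_perm + 1)
}

#' Extract cluster-mean contrast values and planned comparisons
#'
#' Averages each subject's contrast values over the significant voxel set
#' and performs the planned one-tailed pairwise comparisons of the group
#' means (two-sample permutation tests on the per-subject cluster means),
#' following the directional hypothesis given by the ordering of
#' \code{planned} (each earlier group is tested as greater than each later
#' one).
#'
#' @param copes V x N matrix over mask voxels.
#' @param significant Logical vector over the V voxels (a
#'   \code{pe_inference} significant set), or integer indices.
#' @param groups Factor of length N.
#' @param planned Character vector of group levels in hypothesised
#'   decreasing order (default: the factor's level order).
#' @param n_perm Permutations for the scalar pairwise tests.
#' @param seed RNG seed.
#' @return Object of class \code{cluster_summary}: per-subject means, group
#'   means/SDs/n, the pairwise one-tailed p-values, and the voxel count.
#'   With an empty significant set, a summary flagged
#'   \code{no_significant_voxels = TRUE} (not an error).
#' @export
extract_cluster_means <- function(copes, significant, groups,
                                  planned = NULL, n_perm = 10000L,
                                  seed = 1L) {
  copes <- as.matrix(copes)
  groups <- droplevels(as.factor(groups))
  if (is.logical(significant)) significant <- which(significant)
  if (length(significant) == 0L) {
    return(structure(list(no_significant_voxels = TRUE, n_voxels = 0L,
                          subject_means = NULL, group_stats = NULL,
                          pairwise = NULL),
                     class = "cluster_summary"))
  }
  sm <- colMeans(copes[significant, , drop = FALSE])
  gs <- data.frame(
    group = levels(groups),
    n = as.integer(table(groups)),
    mean = as.numeric(tapply(sm, groups, mean)),
    sd = as.numeric(tapply(sm, groups, stats::sd)),
    stringsAsFactors = FALSE
  )
  if (is.null(planned)) planned <- levels(groups)
  pw <- NULL
  if (length(planned) >= 2L) {
    cmb <- utils::combn(planned, 2L)
    pw <- data.frame(greater = cmb[1L, ], lesser = cmb[2L, ],
                     p_one_tailed = NA_real_, stringsAsFactors = FALSE)
    for (k in seq_len(ncol(cmb))) {
      x <- sm[groups == cmb[1L, k]]; y <- sm[groups == cmb[2L, k]]
      pw$p_one_tailed[k] <- perm_test_greater(x, y, n_perm, seed + k)
    }
  }
  structure(list(no_significant_voxels = FALSE,
                 n_voxels = length(significant),
                 subject_means = sm, group_stats = gs, pairwise = pw),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, ...) {
  if (x$no_significant_voxels) {
    cat("Cluster summary: no significant voxels\n")
    return(invisible(x))
  }
  cat("Cluster summary over", x$n_voxels, "significant voxels\n")
  print(format(x$group_stats, digits = 4), row.names = FALSE)
  cat("Planned one-tailed comparisons:\n")
  print(format(x$pairwise, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Spearman correlation between cluster means and symptom scores
#'
#' Rank correlation with tie-corrected ranks and a two-sided p-value
#' (t approximation, as appropriate in the presence of ties). Pairs with
#' missing values are dropped; constant input yields an NA estimate with
#' \code{undefined = TRUE} rather than an error.
#'
#' @param cluster_means Numeric vector (per-subject cluster-mean COPEs).
#' @param symptom_scores Numeric vector, same length.
#' @return List with \code{rho}, \code{p}, \code{n}, \code{undefined}.
#' @export
symptom_correlation <- function(cluster_means, symptom_scores) {
  ok <- is.finite(cluster_means) & is.finite(symptom_scores)
  x <- cluster_means[ok]; y <- symptom_scores[ok]
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = length(x),
                undefined = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       undefined = FALSE)
}
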