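run_config_defaults <- function() {
  list(
    output_dir = NULL,
    seed = 42L,
    cohort = list(groups = c(controls = 39L, at_risk = 30L, fep = 14L),
                  n_per_pair = 30L),
    design = list(tr = 2, trial_duration = 10, outcome_delay = 4),
    inference = list(n_perm = 1000L, fwhm = 3, tfce_e = 0.5, tfce_h = 2,
                     alpha = 0.05),
    rois = c("midbrain", "striatum", "dlpfc"),
    write_nifti = FALSE
  )
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), checks every field, fills defaults
#' (39/30/14 subjects, 30 trials per pair, TR 2 s, 1000 permutations, 3 mm
#' variance smoothing, TFCE E = 0.5 / H = 2, alpha 0.05) and materialises
#' the derived stage seeds from the master seed. All validation errors are
#' collected and reported together.
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return Object of class \code{pe_run_config}.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  defs <- run_config_defaults()
  errs <- character()

  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  for (sec in c("cohort", "design", "inference")) {
    if (!is.null(config[[sec]])) {
      u <- setdiff(names(config[[sec]]), names(defs[[sec]]))
      if (length(u))
        errs <- c(errs, paste0("unknown key(s) in ", sec, ": ",
                               paste(u, collapse = ", ")))
    }
  }

  cfg <- utils::modifyList(defs, config)
  if (!is.null(config$cohort$groups)) {
    cfg$cohort$groups <- unlist(config$cohort$groups)
  }

  if (is.null(cfg$output_dir))
    errs <- c(errs, "output_dir is required")
  g <- cfg$cohort$groups
  if (is.null(names(g)) || any(names(g) == "") || any(g <= 0))
    errs <- c(errs, "cohort$groups must be a named vector of positive sizes")
  np <- cfg$cohort$n_per_pair
  if (!is.numeric(np) || np <= 0 || np %% 2 != 0)
    errs <- c(errs, "cohort$n_per_pair must be a positive even integer")
  a <- cfg$inference$alpha
  if (!is.numeric(a) || a <= 0 || a >= 1)
    errs <- c(errs, "inference$alpha must lie in (0, 1)")
  if (cfg$inference$n_perm < 100)
    errs <- c(errs, "inference$n_perm must be >= 100")
  if (cfg$design$tr <= 0) errs <- c(errs, "design$tr must be positive")
  if (anyDuplicated(cfg$rois))
    errs <- c(errs, "duplicate ROI names in rois")
  if (!all(cfg$rois %in% c("midbrain", "striatum", "dlpfc")))
    errs <- c(errs, "rois must be a subset of midbrain, striatum, dlpfc")

  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))

  cfg$seed <- as.integer(cfg$seed)
  # derived stage seeds, deterministic in the master seed
  cfg$stage_seeds <- list(cohort = cfg$seed,
                          inference = cfg$seed + 1000L,
                          cluster = cfg$seed + 2000L)
  class(cfg) <- "pe_run_config"
  cfg
}

#' Run the full simulation-to-inference pipeline
#'
#' Stages, in order: \emph{simulate} (synthetic cohort), \emph{behave}
#' (per-subject summaries and group x trial-type mixed ANOVAs for correct
#' choices and RTs), \emph{firstlevel} (voxelwise GLM and prediction-error
#' COPEs per ROI), \emph{grouplevel} (permutation ANOVA with variance
#' smoothing, TFCE and FWE correction per ROI, planned pairwise
#' comparisons, cluster means, symptom correlations), \emph{report}.
#' Re-running with the same master seed reproduces the behavioural tables
#' and permutation p-values exactly.
#'
#' @param config A \code{pe_run_config} (see \code{\link{validate_config}}),
#'   or a path/list accepted by it.
#' @return Object of class \code{pe_run_report} (invisibly written as JSON
#'   to the output directory together with CSV/TSV/NIfTI artifacts).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pe_run_config")) config <- validate_config(config)
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  report <- list(stages = list(), seed = config$seed)
  t_all <- proc.time()[3L]

  stage <- function(name, expr) {
    t0 <- proc.time()[3L]
    res <- tryCatch(force(expr), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$stages[[name]] <<- list(status = "ok",
                                   seconds = round(proc.time()[3L] - t0, 2))
    res
  }

  # -- simulate ---------------------------------------------------------
  cohort <- stage("simulate", {
    cc <- cohort_config(groups = config$cohort$groups,
                        n_per_pair = config$cohort$n_per_pair,
                        design = c(config$design, list(n_volumes = NULL)),
                        seed = config$stage_seeds$cohort)
    generate_cohort(cc)
  })
  masks <- default_roi_masks()[config$rois]
  class(masks) <- "roi_mask_set"

  # -- behave -----------------------------------------------------------
  behav <- stage("behave", {
    sm <- summarise_cohort(cohort)
    utils::write.csv(sm, file.path(out_dir, "behaviour_summary.csv"),
                     row.names = FALSE)
    beh_dir <- file.path(out_dir, "behaviour")
    if (!dir.exists(beh_dir)) dir.create(beh_dir)
    for (s in cohort$subjects)
      write_behaviour_tsv(s$behaviour,
                          file.path(beh_dir, paste0(s$id, "_events.tsv")))
    an <- list(
      correct = mixed_anova(cohort_behaviour_long(cohort, "correct"),
                            n_perm = 1000L, seed = config$seed + 11L),
      rt = mixed_anova(cohort_behaviour_long(cohort, "rt"),
                       n_perm = 1000L, seed = config$seed + 12L)
    )
    for (nm in names(an))
      utils::write.csv(as.data.frame(an[[nm]]),
                       file.path(out_dir, paste0("anova_", nm, ".csv")),
                       row.names = FALSE)
    list(summary = sm, anova = an)
  })

  # -- firstlevel -------------------------------------------------------
  copes <- stage("firstlevel", {
    cs <- first_level_copes(cohort, masks)
    for (r in names(cs$copes))
      utils::write.csv(cs$copes[[r]],
                       file.path(out_dir, paste0("copes_", r, ".csv")),
                       row.names = FALSE)
    if (isTRUE(config$write_nifti)) {
      for (r in names(masks))
        write_nifti_image(masks[[r]],
                          file.path(out_dir, paste0("mask_", r, ".nii.gz")))
    }
    cs
  })

  # -- grouplevel -------------------------------------------------------
  inf <- stage("grouplevel", {
    planned <- names(config$cohort$groups)
    res <- list()
    for (r in names(copes$copes)) {
      pr <- permutation_fwe(copes$copes[[r]], copes$group, masks[[r]],
                            n_perm = config$inference$n_perm,
                            seed = config$stage_seeds$inference,
                            mode = "anova",
                            fwhm = config$inference$fwhm,
                            E = config$inference$tfce_e,
                            H = config$inference$tfce_h,
                            alpha = config$inference$alpha)
      cs <- extract_cluster_means(copes$copes[[r]], pr$significant,
                                  copes$group, planned = planned,
                                  seed = config$stage_seeds$cluster)
      sy <- vapply(cohort$subjects, function(s) s$symptom, numeric(1L))
      sym <- NULL
      if (!cs$no_significant_voxels) {
        sym <- lapply(split(seq_along(sy), copes$group), function(idx) {
          if (all(is.na(sy[idx]))) return(NULL)
          symptom_correlation(cs$subject_means[idx], sy[idx])
        })
        sym <- sym[!vapply(sym, is.null, TRUE)]
      }
      res[[r]] <- list(inference = pr, clusters = cs, symptoms = sym)
      if (!cs$no_significant_voxels) {
        utils::write.csv(cbind(cs$group_stats),
                         file.path(out_dir, paste0("cluster_", r, ".csv")),
                         row.names = FALSE)
      }
    }
    res
  })

  # -- report -----------------------------------------------------------
  t_report <- proc.time()[3L]
  report <- stage("report", {
    tab <- lapply(inf, function(x) {
      list(n_significant = sum(x$inference$significant),
           min_p_corrected = min(x$inference$p_corrected),
           n_voxels = length(x$inference$p_corrected))
    })
    verdicts <- lapply(inf, function(x) {
      cs <- x$clusters
      if (cs$no_significant_voxels) return(list(ordering = NA))
      m <- cs$group_stats$mean
      list(ordering = all(diff(m) < 0),
           pairwise = cs$pairwise)
    })
    report$inference <- tab
    report$verdicts <- verdicts
    report$behaviour <- list(
      correct = as.list(colMeans(
        behav$summary[, c("correct_reward", "correct_bivalent",
                          "correct_neutral")])),
      win_stay = mean(behav$summary$win_stay, na.rm = TRUE),
      lose_shift = mean(behav$summary$lose_shift, na.rm = TRUE))
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    files <- files[!grepl("run_report[.]json$", files)]
    report$manifest <- data.frame(
      file = sub(paste0("^", out_dir, "/?"), "", files),
      md5 = unname(tools::md5sum(files)), stringsAsFactors = FALSE)
    report$stages$report <- list(status = "ok",
                                 seconds = round(proc.time()[3L] - t_report, 2))
    report$total_seconds <- round(proc.time()[3L] - t_all, 2)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report
  })

  out <- list(report = report, cohort = cohort, behaviour = behav,
              copes = copes, inference = inf, config = config)
  class(out) <- "pe_run_report"
  invisible(out)
}

#' @export
print.pe_run_report <- function(x, ...) {
  cat("Pipeline run (seed", x$config$seed, ")\n")
  for (nm in names(x$report$stages))
    cat(sprintf("  %-10s %s (%.1f s)\n", nm, x$report$stages[[nm]]$status,
                x$report$stages[[nm]]$seconds))
  for (r in names(x$inference)) {
    pr <- x$inference[[r]]$inference
    cat(sprintf("  %-9s %3d voxels, %3d significant, min corrected p = %.4f\n",
                r, length(pr$p_corrected), sum(pr$significant),
                min(pr$p_corrected)))
  }
  invisible(x)
}
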