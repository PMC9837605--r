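#' Simulate one subject's task, behavior and outcomes
#'
#' Sequence, responses and classified outcomes for subject `i`, with all
#' randomness derived from the root seed via named substreams.
#'
#' @param i Subject index (1-based).
#' @param task_cfg An [eat_task_config()] (its `rng_seed` is replaced by a
#'   derived per-subject stream).
#' @param behavior A [behavior_params()].
#' @param seed Root seed.
#' @return List with `seq`, `responses`, `outcomes`, `subject_id`.
#' @export
simulate_subject <- function(i, task_cfg = eat_task_config(),
                             behavior = behavior_params(), seed = 1L) {
  task_cfg$rng_seed <- derive_seed(seed, "sequence", i)
  sq <- generate_sequence(task_cfg)
  id <- sprintf("sub-%02d", i)
  resp <- simulate_responses(sq, behavior,
                             seed = derive_seed(seed, "behavior", i),
                             subject_id = id)
  out <- classify_trials(sq, resp)
  list(seq = sq, responses = resp, outcomes = out, subject_id = id)
}

#' Subject-level event-related analysis
#'
#' Builds the FIR deconvolution design, fits the per-voxel GLM, estimates
#' residual spatial smoothness, and converts per-condition IRFs into
#' percent-area activation maps.
#'
#' @param seq,outcomes Subject task data.
#' @param bold An `eat_bold`.
#' @param fir_window_s FIR window (s).
#' @param drift_order Legendre drift order.
#' @return List with `maps` (named list of 3D pct-area arrays), `beta0`
#'   (3D baseline array), `fwhm` (smoothness estimate), `glm` (the fit,
#'   residuals dropped).
#' @export
subject_level_analysis <- function(seq, outcomes, bold,
                                   fir_window_s = 8 * 2.46,
                                   drift_order = 3L, conditions = NULL) {
  n_vol <- dim(bold$data)[4]
  design <- build_design_matrix(seq, outcomes, n_vol, bold$tr_s,
                                fir_window_s, drift_order)
  fit <- fit_glm(bold, design)
  gs <- fit$grid_shape
  # smoothness from a subsample of residual volumes (they share one field)
  keep <- unique(round(seq.int(1L, n_vol, length.out = 12L)))
  res4d <- array(t(fit$residuals[keep, , drop = FALSE]), c(gs, length(keep)))
  fwhm <- estimate_fwhm(res4d, bold$voxel_mm)
  maps <- activation_maps(fit, conditions %||%
                            names(fit$design$condition_cols))
  fit$residuals <- NULL
  list(maps = maps, beta0 = array(fit$beta0, gs), fwhm = fwhm, glm = fit)
}

#' Simulate a cohort to disk
#'
#' Writes a self-describing directory: one folder per subject with
#' `events.tsv`, `responses.tsv`, `outcomes.tsv` and `bold.nii.gz`, a
#' cohort-level `traits.tsv`, and `ground_truth.json` recording every
#' planted parameter and per-subject stream seed.
#'
#' @param n Number of subjects.
#' @param dir Output directory (created if needed).
#' @param task_cfg,behavior,neuro,traits Generating parameter objects.
#' @param seed Root seed.
#' @return The cohort directory path, invisibly.
#' @export
simulate_cohort <- function(n, dir, task_cfg = eat_task_config(),
                            behavior = behavior_params(),
                            neuro = neuro_params(),
                            traits = trait_params(), seed = 1L) {
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create cohort directory: ", dir)
  awareness <- numeric(n)
  subj_seeds <- list()
  for (i in seq_len(n)) {
    s <- simulate_subject(i, task_cfg, behavior, seed)
    sdir <- file.path(dir, s$subject_id)
    dir.create(sdir, showWarnings = FALSE)
    write_events_tsv(s$seq, file.path(sdir, "events.tsv"))
    write_responses_tsv(s$responses, file.path(sdir, "responses.tsv"))
    write_outcomes_tsv(s$outcomes, file.path(sdir, "outcomes.tsv"))
    bold_seed <- derive_seed(seed, "bold", i)
    bold <- simulate_bold(s$seq, s$outcomes, neuro, seed = bold_seed)
    write_bold_nifti(bold, file.path(sdir, "bold.nii.gz"))
    ct <- attr(s$outcomes, "counts")
    n_err <- ct[["aware_error"]] + ct[["unaware_error"]]
    awareness[i] <- if (n_err) 100 * ct[["aware_error"]] / n_err else NA
    subj_seeds[[s$subject_id]] <- list(
      sequence = derive_seed(seed, "sequence", i),
      behavior = derive_seed(seed, "behavior", i), bold = bold_seed)
  }
  tm <- simulate_traits(n, traits, neural_outcome = awareness,
                        seed = derive_seed(seed, "traits"))
  write_traits_tsv(tm, file.path(dir, "traits.tsv"))
  gt <- list(seed = seed, n_subjects = n,
             task = unclass(task_cfg), behavior = unclass(behavior),
             neuro = neuro_ground_truth(neuro),
             traits = list(true_effects = as.list(traits$true_effects),
                           mcar_rate = traits$mcar_rate),
             subject_seeds = subj_seeds)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

neuro_ground_truth <- function(neuro) {
  list(grid_shape = neuro$grid_shape, voxel_mm = neuro$voxel_mm,
       tr_s = neuro$tr_s, hrf_true = unclass(neuro$hrf_true),
       noise_sd = neuro$noise_sd, ar1_rho = neuro$ar1_rho,
       drift_amp = neuro$drift_amp, smooth_fwhm_mm = neuro$smooth_fwhm_mm,
       baseline = neuro$baseline,
       regions = lapply(neuro$regions, function(r)
         list(n_voxels = nrow(r$mask), amp_aware = r$amp_aware,
              amp_unaware = r$amp_unaware, amp_correct = r$amp_correct)))
}

#' Group-level analysis over a simulated cohort
#'
#' Simulates `n` subjects end to end (behavior, BOLD, subject-level GLM and
#' percent-area maps), then runs the group stage: paired aware-vs-unaware
#' t-map, residual-smoothness estimate, cluster-extent threshold (either
#' supplied or selected by Monte Carlo simulation) and cluster extraction.
#' BOLD runs are discarded after each subject-level fit.
#'
#' @param n Cohort size.
#' @param task_cfg,behavior,neuro Generator parameters.
#' @param seed Root seed.
#' @param fir_window_s,drift_order Subject-level analysis settings.
#' @param voxel_p Two-tailed voxel-wise p for the group map.
#' @param null_dist Optional precomputed `null_cluster_dist` (skips the
#'   Monte Carlo stage; its grid must match).
#' @param n_iter_cluster Iterations when the Monte Carlo stage runs here.
#' @param alpha Corrected cluster level.
#' @param connectivity Cluster connectivity.
#' @param min_volume_uL Optional hard extent override in microliters (e.g.
#'   a conventional 250 uL floor); the larger of this and the simulated
#'   threshold is applied when both are present.
#' @param conditions FIR classes to carry into activation maps.
#' @return List with `tmap`, `clusters`, `maps` (per-condition 4D arrays),
#'   `behavior` (per-subject summary data.frame), `fwhm_mm`, `null_dist`,
#'   `t_threshold`.
#' @export
run_group_analysis <- function(n = 30L, task_cfg = eat_task_config(),
                               behavior = behavior_params(),
                               neuro = neuro_params(), seed = 1L,
                               fir_window_s = 8 * 2.46, drift_order = 3L,
                               voxel_p = 0.001, null_dist = NULL,
                               n_iter_cluster = 2000L, alpha = 0.010,
                               connectivity = 6L, min_volume_uL = NULL,
                               conditions = c("aware_error", "unaware_error",
                                              "correct_inhibition")) {
  gs <- neuro$grid_shape
  conds <- conditions
  maps <- lapply(conds, function(cl) array(NA_real_, c(gs, n)))
  names(maps) <- conds
  behav <- vector("list", n)
  fwhms <- numeric(n)
  for (i in seq_len(n)) {
    s <- simulate_subject(i, task_cfg, behavior, seed)
    bold <- simulate_bold(s$seq, s$outcomes, neuro,
                          seed = derive_seed(seed, "bold", i))
    sl <- subject_level_analysis(s$seq, s$outcomes, bold, fir_window_s,
                                 drift_order, conditions = conds)
    for (cl in conds)
      if (!is.null(sl$maps[[cl]]))
        maps[[cl]][, , , i] <- sl$maps[[cl]]
    fwhms[i] <- sl$fwhm$geometric_mean
    behav[[i]] <- cbind(subject = s$subject_id,
                        summarize_behavior(s$outcomes, s$responses, s$seq))
    rm(bold, sl)
  }
  behav <- do.call(rbind, behav)
  fwhm_mm <- mean(fwhms, na.rm = TRUE)

  tmap <- paired_t_map(maps$aware_error, maps$unaware_error, neuro$voxel_mm)
  if (is.null(null_dist))
    null_dist <- simulate_null_clusters(gs, neuro$voxel_mm, fwhm_mm,
                                        voxel_p, n_iter_cluster,
                                        seed = derive_seed(seed, "clustsim"),
                                        alpha = alpha,
                                        connectivity = connectivity)
  t_thr <- stats::qt(1 - voxel_p / 2, tmap$df)
  min_uL <- max(null_dist$threshold_uL, min_volume_uL %||% 0)
  clusters <- extract_clusters(tmap, t_thr, min_uL, connectivity)
  list(tmap = tmap, clusters = clusters, maps = maps, behavior = behav,
       fwhm_mm = fwhm_mm, null_dist = null_dist, t_threshold = t_thr)
}

#' Run the full pipeline: simulation, group inference, ROI association and
#' trait lasso
#'
#' Executes every stage on one synthetic cohort and writes the standard
#' output files (behavioral summary, cluster table, ROI correlation table,
#' lasso stability table shaped like a questionnaire-by-outcome report, and
#' a frozen copy of the resolved configuration) to `out_dir`.
#'
#' @param config An `eat_config` (see [default_pipeline_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, a list with all stage results.
#' @export
run_full_pipeline <- function(config = default_pipeline_config(),
                              out_dir = tempfile("eat-run-")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_pipeline_config(config, file.path(out_dir, "config_used.yaml"))
  seed <- config$seed

  task_cfg <- do.call(eat_task_config, c(config$task, rng_seed = seed))
  behavior <- do.call(behavior_params, config$behavior)
  neuro <- do.call(neuro_params, config$neuro)
  an <- config$analysis

  grp <- run_group_analysis(config$n_subjects, task_cfg, behavior, neuro,
                            seed = seed, fir_window_s = an$fir_window_s,
                            drift_order = an$drift_order,
                            voxel_p = an$voxel_p,
                            n_iter_cluster = an$n_iter_cluster,
                            alpha = an$alpha,
                            connectivity = an$connectivity,
                            min_volume_uL = an$min_volume_uL)
  write_tsv(grp$behavior, file.path(out_dir, "behavior_summary.tsv"))
  write_cluster_tsv(grp$clusters, file.path(out_dir, "clusters.tsv"))

  result <- list(group = grp, roi = NULL, correlations = NULL, lasso = NULL)

  if (nrow(grp$clusters) > 0) {
    roi <- cluster_means(grp$maps["aware_error"], grp$clusters)$aware_error
    behav_idx <- grp$behavior[, c("inhibition_pct", "awareness_pct",
                                  "postnogo_adjust_unaware_ms")]
    corr <- behavior_correlations(roi, behav_idx)
    write_tsv(corr, file.path(out_dir, "roi_behavior_correlations.tsv"))
    result$roi <- roi
    result$correlations <- corr

    traits <- do.call(trait_params, config$traits)
    tm <- simulate_traits(config$n_subjects, traits,
                          neural_outcome = grp$behavior$awareness_pct,
                          seed = derive_seed(seed, "traits"))
    outcomes <- cbind(error_awareness = grp$behavior$awareness_pct,
                      roi[, seq_len(min(4L, ncol(roi))), drop = FALSE])
    stab <- list()
    for (j in seq_len(ncol(outcomes))) {
      y <- outcomes[, j]
      ok <- stats::complete.cases(tm, y)
      if (sum(ok) >= 20L)
        stab[[colnames(outcomes)[j]]] <-
          bootstrap_stability(tm, y, n_boot = an$n_boot,
                              seed = derive_seed(seed, "lasso", j))
    }
    if (length(stab)) {
      wide <- data.frame(predictor = stab[[1]]$predictor)
      for (nm in names(stab)) {
        wide[[paste0(nm, ".coeff")]] <- stab[[nm]]$coefficient
        wide[[paste0(nm, ".pct_nonzero")]] <- stab[[nm]]$pct_nonzero
      }
      write_tsv(wide, file.path(out_dir, "trait_lasso_stability.tsv"))
      result$lasso <- stab
    }
  }
  invisible(result)
}
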