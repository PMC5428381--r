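#' Pipeline run configuration
#'
#' Collects every threshold of the analysis in one place. Defaults are the
#' published values: 10 ppm annotation tolerance, 0.7 merge correlation,
#' 0.05 min merge RT difference, 0.1 s cross-dataset RT tolerance, 2.5 sd
#' internal-standard quality cutoff, removal of confounded lipids at
#' corrected p < 0.01, 10 x 10 cross-validation, enrichment/permutation
#' sample counts of 1000 and significance at 0.05, 0.9 x clade-max MLS
#' long-living cutoff (built into the labeling), and 100 clade-elimination
#' replicates.
#'
#' @param n_peaks peaks per tissue in the simulated lipidome.
#' @param tol_ppm annotation and cross-matching mass tolerance, ppm.
#' @param corr_min,rt_max_diff peak-merge thresholds (Pearson r; minutes).
#' @param rt_tol_sec cross-dataset RT tolerance, seconds.
#' @param k_sd internal-standard quality cutoff, sd units.
#' @param confound_alpha removal threshold on corrected p.
#' @param n_perm permutations for the confounder correction.
#' @param alpha_grid elastic-net mixing grid.
#' @param folds,repeats cross-validation design.
#' @param n_samp enrichment correction draws.
#' @param enrich_alpha enrichment significance level.
#' @param holdout_reps clade-elimination replicates per fraction.
#' @param holdout_fractions clade-elimination removal fractions.
#' @param enzyme_effect planted dN/dS reduction in the simulation.
#' @param stages character vector of enabled stages, in order.
#' @param seed master seed; every stage derives its own sub-seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_peaks = 350L,
                       tol_ppm = 10,
                       corr_min = 0.7,
                       rt_max_diff = 0.05,
                       rt_tol_sec = 0.1,
                       k_sd = 2.5,
                       confound_alpha = 0.01,
                       n_perm = 1000L,
                       alpha_grid = c(0.1, 0.5, 0.9),
                       folds = 10L,
                       repeats = 10L,
                       n_samp = 1000L,
                       enrich_alpha = 0.05,
                       holdout_reps = 100L,
                       holdout_fractions = seq(0.1, 1, by = 0.1),
                       enzyme_effect = 0.5,
                       stages = c("simulate", "process", "confound", "fit",
                                  "characterize", "evolve"),
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes the enabled stages in order: cohort + lipidome simulation, peak
#' processing per tissue, confounder filtering, cross-validated elastic-net
#' classification and predictor selection per tissue, predictor
#' characterization (cross-clade correlation, class/sub-class/pathway
#' enrichment with concentration shifts, tissue overlaps), optionally the
#' clade-elimination protocol (`"holdout"` stage, off by default — it
#' dominates the runtime), and the enzyme dN/dS comparison. When ground
#' truth is present the report records recovery metrics.
#'
#' @param config a [run_config()].
#' @return list of class `run_report`: per-stage results plus
#'   `auc_by_tissue`, `mean_auc`, `predictor_recovery`.
#' @export
run_pipeline <- function(config = run_config()) {
  report <- list(config = config, seed = config$seed)
  seed <- config$seed
  on <- function(st) st %in% config$stages

  # --- simulate ---------------------------------------------------------
  cohort <- generate_cohort(seed = derive_seed(seed, "stage-sim"))
  sim <- generate_lipidome(cohort, n_peaks = config$n_peaks,
                           seed = derive_seed(seed, "stage-sim"))
  report$truth <- sim$truth
  report$n_samples <- nrow(cohort$samples)
  tissues <- names(sim$tables)

  processed <- list()
  if (on("process")) {
    for (ts in tissues)
      processed[[ts]] <- process_peak_table(
        sim$tables[[ts]], cohort, sim$reference, sim$is_peak,
        tol_ppm = config$tol_ppm, k_sd = config$k_sd,
        corr_min = config$corr_min, rt_max_diff = config$rt_max_diff)
    report$peaks_after_processing <-
      vapply(processed, function(p) ncol(p$table$intensities), integer(1))
  }

  if (on("confound")) {
    report$confounder <- list()
    for (ts in tissues) {
      scan <- confounder_scan(processed[[ts]]$table, cohort,
                              n_perm = config$n_perm,
                              seed = derive_seed(seed, "stage-confound", ts))
      flt <- filter_confounded(scan, alpha = config$confound_alpha)
      processed[[ts]]$table <- subset_peaks(processed[[ts]]$table,
                                            peaks = flt$retained)
      report$confounder[[ts]] <- list(
        removed = length(flt$removed),
        removal_counts = stats::setNames(flt$removal_counts,
                                         flt$removal_factors))
    }
  }

  designs <- models <- list()
  if (on("fit")) {
    aucs <- alphas <- fracs <- stats::setNames(numeric(length(tissues)),
                                               tissues)
    for (ts in tissues) {
      d <- build_design(processed[[ts]]$table, cohort)
      cv <- cross_validate(d$x, d$y, alpha_grid = config$alpha_grid,
                           folds = config$folds, repeats = config$repeats,
                           seed = derive_seed(seed, "stage-fit", ts))
      m <- select_predictors(d$x, d$y, cv$best_alpha,
                             seed = derive_seed(seed, "stage-fit", ts))
      designs[[ts]] <- d
      models[[ts]] <- m
      aucs[ts] <- cv$mean_auc
      alphas[ts] <- cv$best_alpha
      fracs[ts] <- m$predictor_fraction
    }
    report$designs <- designs
    report$models <- models
    report$auc_by_tissue <- aucs
    report$mean_auc <- mean(aucs)
    report$best_alpha_by_tissue <- alphas
    report$predictor_fraction_by_tissue <- fracs
    report$predictor_recovery <- mean(vapply(tissues, function(ts)
      mean(sim$truth$predictor_peaks %in% models[[ts]]$selected_peaks),
      numeric(1)))
  }

  if (on("characterize") && on("fit")) {
    ch <- list()
    for (ts in tissues) {
      changes <- clade_changes(processed[[ts]]$table, cohort)
      pred <- models[[ts]]$selected_peaks
      ann <- processed[[ts]]$annotations
      universe <- intersect(unique(ann$peak_id),
                            processed[[ts]]$table$peak_meta$peak_id)
      entry <- list(n_predictors = length(pred))
      if (length(intersect(pred, rownames(changes))) >= 3L)
        entry$crossclade <- crossclade_change_correlation(
          changes, pred, n_perm = config$n_perm,
          seed = derive_seed(seed, "stage-char", ts))
      if (length(intersect(pred, universe)) >= 1L) {
        groups <- peak_groups(ann, "sub_class")
        entry$enrichment <- class_enrichment(
          pred, groups, universe, n_samp = config$n_samp,
          seed = derive_seed(seed, "stage-char", ts))
        sig <- entry$enrichment$group_id[
          entry$enrichment$perm_p < config$enrich_alpha]
        pred_changes <- changes[intersect(pred, rownames(changes)), ,
                                drop = FALSE]
        entry$shifts <- lapply(stats::setNames(sig, sig), function(gid) {
          gp <- intersect(groups[[gid]], rownames(pred_changes))
          if (length(gp) == 0L) return(NULL)
          concentration_shift_test(gp, pred_changes, n_perm = config$n_perm,
                                   seed = derive_seed(seed, "shift", ts, gid))
        })
      }
      ch[[ts]] <- entry
    }
    report$characterization <- ch
  }

  if (on("holdout") && on("fit")) {
    hd <- lapply(designs, function(d) {
      smp <- cohort$samples
      d$individual <- smp$individual_id[match(rownames(d$x), smp$sample_id)]
      d
    })
    report$holdout <- do.call(rbind, lapply(unique(cohort$species$clade),
      function(cl) run_clade_elimination(
        hd, cohort, cl, fractions = config$holdout_fractions,
        reps = config$holdout_reps,
        seed = derive_seed(seed, "stage-holdout", cl))))
  }

  if (on("evolve") && on("fit")) {
    enz <- generate_enzyme_tables(sim$truth, sim$reference,
                                  enzyme_effect = config$enzyme_effect,
                                  seed = derive_seed(seed, "stage-evolve"))
    # predictor compounds pooled over tissues, quantile per tissue group
    report$enzyme <- list()
    for (ts in tissues) {
      ann <- processed[[ts]]$annotations
      pred_cmp <- unique(ann$compound_id[
        ann$peak_id %in% models[[ts]]$selected_peaks])
      if (length(pred_cmp) == 0L) next
      sel <- select_lifespan_enzymes(enz, pred_cmp, q = enzyme_quantile(ts))
      report$enzyme[[ts]] <- list(
        n_selected = length(sel$selected),
        long = compare_dnds(enz, sel$selected, "long"),
        short = compare_dnds(enz, sel$selected, "short"))
    }
    report$enzyme_table <- enz
  }

  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("lifelipid run report\n")
  if (!is.null(x$auc_by_tissue)) {
    cat(sprintf("  mean CV AUC: %.3f (max %.3f)\n", x$mean_auc,
                max(x$auc_by_tissue)))
    for (ts in names(x$auc_by_tissue))
      cat(sprintf("    %-11s AUC %.3f  alpha %.1f  predictors %.0f%%\n", ts,
                  x$auc_by_tissue[ts], x$best_alpha_by_tissue[ts],
                  100 * x$predictor_fraction_by_tissue[ts]))
  }
  if (!is.null(x$predictor_recovery))
    cat(sprintf("  planted predictor recovery: %.2f\n", x$predictor_recovery))
  invisible(x)
}

#' Confounder-filter calibration under a global null
#'
#' Simulates a lipidome with no planted lifespan or confounder effects over
#' the default cohort (one tissue), runs every factor test with maxT
#' permutation correction, and reports the fraction of lipids whose
#' corrected p-value falls below `alpha` — the realized family-wise removal
#' rate per factor, which the correction should keep at or below `alpha`.
#'
#' @param n_peaks null lipids to simulate (default 10000).
#' @param n_perm permutations per factor (default 1000).
#' @param alpha removal threshold (default 0.01).
#' @param seed integer seed.
#' @return named numeric: per-factor fraction of lipids removed.
#' @export
null_confounder_calibration <- function(n_peaks = 10000L, n_perm = 1000L,
                                        alpha = 0.01, seed = 7L) {
  cohort <- generate_cohort(tissues = "liver",
                            seed = derive_seed(seed, "null-cohort"))
  cfg <- lipidome_config(n_predictors = 0L, n_confounded = 0L,
                         effect_size = 0, missing_rate = 0,
                         annotated_fraction = 0, n_duplicate_pairs = 0L)
  sim <- generate_lipidome(cohort, n_peaks = n_peaks, config = cfg,
                           seed = derive_seed(seed, "null-lipidome"))
  tab <- impute_halfmin(normalize_by_internal_standard(
    sim$tables$liver, sim$is_peak)$table)
  vapply(confounder_factors(), function(f) {
    res <- permutation_correct(tab, cohort, f, n_perm = n_perm, seed = seed)
    mean(res$corrected_p < alpha)
  }, numeric(1))
}
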