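# Shared setup for the analysis drivers: deterministic rebuild of the
# benchmark cohort, lipidome and processed tables. Every driver sources
# this file; all stages derive their sub-seeds from MASTER_SEED, so any
# script can be run on its own and reproduces the same state.

library(lifelipid)

MASTER_SEED <- 1L
RESULTS_DIR <- file.path("results")
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

build_benchmark <- function(seed = MASTER_SEED) {
  cohort <- generate_cohort(seed = derive_seed(seed, "stage-sim"))
  sim <- generate_lipidome(cohort, n_peaks = 350L,
                           seed = derive_seed(seed, "stage-sim"))
  list(cohort = cohort, sim = sim)
}

process_all_tissues <- function(bm) {
  lapply(bm$sim$tables, function(tab)
    process_peak_table(tab, bm$cohort, bm$sim$reference, bm$sim$is_peak))
}

filter_all_tissues <- function(processed, bm, n_perm = 1000L,
                               seed = MASTER_SEED) {
  out <- list()
  for (ts in names(processed)) {
    scan <- confounder_scan(processed[[ts]]$table, bm$cohort,
                            n_perm = n_perm,
                            seed = derive_seed(seed, "stage-confound", ts))
    flt <- filter_confounded(scan, alpha = 0.01)
    pr <- processed[[ts]]
    pr$table <- subset_peaks(pr$table, peaks = flt$retained)
    pr$confounder_scan <- scan
    pr$confounder_filter <- flt
    out[[ts]] <- pr
  }
  out
}
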