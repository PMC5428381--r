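#!/usr/bin/env Rscript
# Long-lifespan classifiers per tissue: 10 x 10 stratified cross-validated
# elastic-net logistic regression (mixing parameter selected by held-out
# AUC, penalty by inner-CV deviance), refit on all samples to extract the
# MLS predictor lipids. The SVM-RFE and linear elastic-net alternatives
# are run on one tissue for comparison, as secondary models.

source(file.path("analysis", "common.R"))

bm <- build_benchmark()
filtered <- filter_all_tissues(process_all_tissues(bm), bm)

rows <- list()
predictor_rows <- list()
for (ts in names(filtered)) {
  d <- build_design(filtered[[ts]]$table, bm$cohort)
  cv <- cross_validate(d$x, d$y,
                       seed = derive_seed(MASTER_SEED, "stage-fit", ts))
  m <- select_predictors(d$x, d$y, cv$best_alpha,
                         seed = derive_seed(MASTER_SEED, "stage-fit", ts))
  recovery <- mean(bm$sim$truth$predictor_peaks %in% m$selected_peaks)
  rows[[ts]] <- data.frame(
    tissue = ts, mean_cv_auc = cv$mean_auc, best_alpha = cv$best_alpha,
    lambda = m$cv_lambda, n_predictors = length(m$selected_peaks),
    predictor_fraction = m$predictor_fraction, planted_recovery = recovery)
  predictor_rows[[ts]] <- data.frame(
    tissue = ts, peak_id = m$selected_peaks,
    coefficient = m$coefficients[m$selected_peaks])
}
auc_tab <- do.call(rbind, rows)
write.table(auc_tab, file.path(RESULTS_DIR, "model_performance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, predictor_rows),
            file.path(RESULTS_DIR, "mls_predictors.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(auc_tab, row.names = FALSE, digits = 3)
cat(sprintf("\nmean AUC %.3f, max %.3f; planted-predictor recovery %.2f\n",
            mean(auc_tab$mean_cv_auc), max(auc_tab$mean_cv_auc),
            mean(auc_tab$planted_recovery)))

# secondary models on muscle: SVM-RFE and the linear elastic net on
# clade-normalized lifespan
d <- build_design(filtered$muscle$table, bm$cohort)
rfe <- svm_rfe(d$x, d$y, folds = 5, repeats = 1,
               seed = derive_seed(MASTER_SEED, "rfe"))
cat(sprintf("SVM-RFE (muscle): %d features chosen, CV AUC %.3f\n",
            rfe$best_n_features, rfe$cv_auc))
resp <- normalized_mls(bm$cohort, rownames(d$x))
lin <- fit_elasticnet_linear(d$x, resp, alpha = 0.5, lambda = 0.05)
cat(sprintf("linear elastic net (muscle): %d nonzero coefficients\n",
            length(lin$selected_peaks)))
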