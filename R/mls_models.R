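#' Label long-living species within each clade
#'
#' A species is long-living iff its maximal lifespan strictly exceeds 0.9
#' of the highest MLS in its clade; the clade maximum is therefore always
#' labeled.
#'
#' @param species species data frame (`species_id`, `clade`, `mls`).
#' @return data.frame with `species_id`, `clade`, `mls`, `clade_max_mls`,
#'   `threshold` and `is_long_living`.
#' @export
label_long_living <- function(species) {
  if (any(!is.finite(species$mls))) stop("species with missing MLS")
  clade_max <- tapply(species$mls, species$clade, max)
  thr <- 0.9 * clade_max[species$clade]
  data.frame(species_id = species$species_id,
             clade = species$clade,
             mls = species$mls,
             clade_max_mls = as.vector(clade_max[species$clade]),
             threshold = as.vector(thr),
             is_long_living = species$mls > as.vector(thr),
             stringsAsFactors = FALSE)
}

#' Build the classification design for one tissue
#'
#' Standardizes the (imputed, log-scale) peak matrix per column and attaches
#' the binary long-living label per sample.
#'
#' @param table processed [peak_table()].
#' @param cohort cohort list.
#' @return list with `x` (standardized matrix), `y` (logical labels),
#'   `species` (per-sample species id), `clade` (per-sample clade).
#' @export
build_design <- function(table, cohort) {
  labels <- label_long_living(cohort$species)
  smp <- cohort$samples[match(rownames(table$intensities),
                              cohort$samples$sample_id), , drop = FALSE]
  y <- labels$is_long_living[match(smp$species_id, labels$species_id)]
  list(x = standardize_columns(table$intensities), y = y,
       species = smp$species_id,
       clade = labels$clade[match(smp$species_id, labels$species_id)])
}

#' Fit a logistic elastic-net model at fixed penalty
#'
#' Minimizes the mean negative Bernoulli log-likelihood plus
#' `lambda * ((1 - alpha)/2 * sum(beta^2) + alpha * sum(|beta|))`, intercept
#' unpenalized. The solver is glmnet, run along a decreasing lambda path
#' ending at the requested value for warm-started stability.
#'
#' @param x standardized samples x features matrix.
#' @param y binary labels.
#' @param alpha elastic-net mixing in `[0, 1]`.
#' @param lambda penalty strength (>= 0).
#' @return list of class `predictor_model`: `alpha`, `lambda`, `intercept`,
#'   `coefficients` (named), `selected_peaks`.
#' @export
fit_elasticnet_logistic <- function(x, y, alpha, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  y <- as.logical(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  lam_path <- exp(seq(log(max(lambda * 50, 1)), log(max(lambda, 1e-4)),
                      length.out = 30))
  # glmnet flags class counts below 8 ("dangerous ground"); routine for
  # the small long-living class, so muffled while other warnings pass
  fit <- withCallingHandlers(
    glmnet::glmnet(x, factor(y), family = "binomial", alpha = alpha,
                   lambda = lam_path, standardize = FALSE, thresh = 1e-10),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  cf <- as.matrix(stats::coef(fit, s = max(lambda, 1e-4), exact = FALSE))[, 1]
  beta <- cf[-1]
  structure(list(alpha = alpha, lambda = lambda, intercept = unname(cf[1]),
                 coefficients = beta,
                 selected_peaks = names(beta)[beta != 0]),
            class = "predictor_model")
}

#' Predict scores from a fitted penalized model
#' @param object a `predictor_model`.
#' @param newx matrix with the model's feature columns.
#' @param ... unused.
#' @return linear predictor per row.
#' @export
predict.predictor_model <- function(object, newx, ...) {
  drop(newx[, names(object$coefficients), drop = FALSE] %*%
         object$coefficients) + object$intercept
}

# stratified inner foldid for cv.glmnet
inner_foldid <- function(y, k) {
  f <- stratified_folds(y, k)
  # guard: cv.glmnet requires every fold nonempty
  stopifnot(length(unique(f)) == k)
  f
}

#' Repeated stratified cross-validation of the elastic-net classifier
#'
#' `repeats` rounds of `folds`-fold stratified cross-validation. Within
#' each training split and for each candidate alpha, the penalty strength
#' is chosen along a warm-started lambda path by inner cross-validated
#' binomial deviance (`cv.glmnet`); the held-out fold is then scored and
#' its AUC computed as
#' the Mann-Whitney concordance. The mixing parameter maximizing the mean
#' held-out AUC over all `folds x repeats` evaluations is reported.
#'
#' @param x standardized samples x features matrix.
#' @param y binary labels.
#' @param alpha_grid candidate mixing parameters.
#' @param folds outer folds (default 10).
#' @param repeats outer repeats (default 10).
#' @param inner_folds folds of the inner lambda selection.
#' @param seed integer seed.
#' @return list: `best_alpha`, `mean_auc` (at `best_alpha`), `fold_aucs`
#'   (matrix folds*repeats x alpha), `auc_by_alpha`.
#' @export
cross_validate <- function(x, y, alpha_grid = c(0.1, 0.5, 0.9),
                           folds = 10L, repeats = 10L, inner_folds = 3L,
                           seed = 1L) {
  y <- as.logical(y)
  if (min(sum(y), sum(!y)) < 2L) stop("need >= 2 samples per class")
  folds <- min(folds, sum(y), sum(!y))
  fold_aucs <- matrix(NA_real_, folds * repeats, length(alpha_grid),
                      dimnames = list(NULL, paste0("alpha_", alpha_grid)))
  row <- 0L
  for (rep_i in seq_len(repeats)) {
    set.seed(derive_seed(seed, "cv", rep_i))
    fid <- stratified_folds(y, folds)
    for (k in seq_len(folds)) {
      row <- row + 1L
      tr <- fid != k
      te <- !tr
      for (a in seq_along(alpha_grid)) {
        # glmnet warns about small per-fold class counts; expected here
        cvfit <- suppressWarnings(glmnet::cv.glmnet(
          x[tr, , drop = FALSE], factor(y[tr]), family = "binomial",
          alpha = alpha_grid[a], type.measure = "deviance",
          foldid = inner_foldid(y[tr], inner_folds),
          standardize = FALSE, nlambda = 50))
        score <- drop(stats::predict(cvfit, x[te, , drop = FALSE],
                                     s = "lambda.min"))
        fold_aucs[row, a] <- auc_score(score, y[te])
      }
    }
  }
  auc_by_alpha <- colMeans(fold_aucs, na.rm = TRUE)
  best <- which.max(auc_by_alpha)
  list(best_alpha = alpha_grid[best],
       mean_auc = unname(auc_by_alpha[best]),
       fold_aucs = fold_aucs,
       auc_by_alpha = auc_by_alpha)
}

#' Refit on all samples and extract predictor lipids
#'
#' Retrains the elastic-net logistic model on all samples at the
#' cross-validation-selected mixing parameter (penalty strength chosen by
#' inner cross-validated deviance) and returns the peaks with nonzero
#' coefficients — the MLS predictors.
#'
#' @param x standardized samples x features matrix.
#' @param y binary labels.
#' @param best_alpha mixing parameter from [cross_validate()].
#' @param inner_folds folds for the lambda selection.
#' @param seed integer seed.
#' @return list of class `predictor_model` with additionally
#'   `predictor_fraction` (selected / total features).
#' @export
select_predictors <- function(x, y, best_alpha, inner_folds = 5L, seed = 1L) {
  set.seed(derive_seed(seed, "refit"))
  cvfit <- suppressWarnings(glmnet::cv.glmnet(
    x, factor(as.logical(y)), family = "binomial",
    alpha = best_alpha, type.measure = "deviance",
    foldid = inner_foldid(as.logical(y), inner_folds),
    standardize = FALSE, nlambda = 50))
  model <- fit_elasticnet_logistic(x, y, best_alpha, cvfit$lambda.min)
  model$cv_lambda <- cvfit$lambda.min
  model$predictor_fraction <- length(model$selected_peaks) / ncol(x)
  model
}

#' Linear elastic-net model of clade-normalized lifespan
#'
#' Same penalty as the logistic model but squared-error loss; the response
#' is species MLS divided by the clade maximum (so the longest-living
#' species of each clade has response exactly 1), broadcast to individuals.
#'
#' @param x standardized samples x features matrix.
#' @param y_mls_norm normalized lifespan response in `(0, 1]` per sample.
#' @param alpha elastic-net mixing.
#' @param lambda penalty strength.
#' @return `predictor_model` (with `response = "gaussian"`).
#' @export
fit_elasticnet_linear <- function(x, y_mls_norm, alpha, lambda) {
  if (any(y_mls_norm <= 0)) stop("normalized MLS must be positive")
  if (stats::sd(y_mls_norm) == 0)  # constant response: fully shrunk model
    return(structure(list(alpha = alpha, lambda = lambda,
                          intercept = y_mls_norm[1],
                          coefficients = stats::setNames(rep(0, ncol(x)),
                                                         colnames(x)),
                          selected_peaks = character(0),
                          response = "gaussian"),
                     class = "predictor_model"))
  lam_path <- exp(seq(log(max(lambda * 50, 1)), log(max(lambda, 1e-4)),
                      length.out = 30))
  fit <- glmnet::glmnet(x, y_mls_norm, family = "gaussian", alpha = alpha,
                        lambda = lam_path, standardize = FALSE,
                        thresh = 1e-10)
  cf <- as.matrix(stats::coef(fit, s = max(lambda, 1e-4), exact = FALSE))[, 1]
  beta <- cf[-1]
  structure(list(alpha = alpha, lambda = lambda, intercept = unname(cf[1]),
                 coefficients = beta,
                 selected_peaks = names(beta)[beta != 0],
                 response = "gaussian"),
            class = "predictor_model")
}

#' Clade-normalized lifespan response
#'
#' @param cohort cohort list.
#' @param sample_ids samples for which to build the response.
#' @return numeric vector: species MLS / clade maximum MLS per sample.
#' @export
normalized_mls <- function(cohort, sample_ids) {
  smp <- cohort$samples[match(sample_ids, cohort$samples$sample_id), ]
  sp <- cohort$species[match(smp$species_id, cohort$species$species_id), ]
  clade_max <- tapply(cohort$species$mls, cohort$species$clade, max)
  sp$mls / as.vector(clade_max[sp$clade])
}

# linear-SVM feature weights (w = t(coefs) %*% SV)
svm_weights <- function(x, y) {
  fit <- e1071::svm(x, factor(y), kernel = "linear", scale = FALSE)
  drop(crossprod(fit$coefs, fit$SV))
}

# one RFE trajectory: feature sets visited while removing step_n lowest-|w|
# features per iteration (ties broken by column index) until <= min_features
rfe_trajectory <- function(x, y, step_n, min_features) {
  active <- seq_len(ncol(x))
  sets <- list(active)
  while (length(active) > min_features) {
    w <- abs(svm_weights(x[, active, drop = FALSE], y))
    drop_n <- min(step_n, length(active) - min_features)
    ord <- order(w, seq_along(active))  # lowest |w| first, ties by index
    active <- sort(active[-ord[seq_len(drop_n)]])
    sets[[length(sets) + 1L]] <- active
  }
  sets
}

#' SVM recursive feature elimination
#'
#' In every cross-validation run, a linear SVM is fit and
#' `ceil(step_fraction x initial features)` features with the lowest
#' absolute weight are removed iteratively until no more than
#' `min_features` remain; held-out AUC is recorded at every visited feature
#' count. The best-performing count (mean across runs) is chosen and the
#' model refit on all data down to that count.
#'
#' @param x standardized samples x features matrix.
#' @param y binary labels.
#' @param step_fraction fraction of the initial feature count removed per
#'   iteration (default 0.01, minimum one feature).
#' @param min_features stopping size (default 10).
#' @param folds,repeats cross-validation design.
#' @param seed integer seed.
#' @return list: `best_n_features`, `feature_set` (column names),
#'   `cv_auc_by_size`, `cv_auc` at the chosen size.
#' @export
svm_rfe <- function(x, y, step_fraction = 0.01, min_features = 10L,
                    folds = 5L, repeats = 2L, seed = 1L) {
  y <- as.logical(y)
  if (min_features > ncol(x)) stop("min_features exceeds feature count")
  step_n <- max(1L, ceiling(step_fraction * ncol(x)))
  sizes <- NULL
  auc_runs <- list()
  for (rep_i in seq_len(repeats)) {
    set.seed(derive_seed(seed, "rfe", rep_i))
    fid <- stratified_folds(y, folds)
    for (k in seq_len(folds)) {
      tr <- fid != k
      traj <- rfe_trajectory(x[tr, , drop = FALSE], y[tr], step_n,
                             min_features)
      aucs <- vapply(traj, function(active) {
        fit <- e1071::svm(x[tr, active, drop = FALSE], factor(y[tr]),
                          kernel = "linear", scale = FALSE)
        pr <- stats::predict(fit, x[!tr, active, drop = FALSE],
                             decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        dec <- dv[, 1]
        # orient decision values towards the positive (TRUE) class
        if (startsWith(colnames(dv)[1], "FALSE")) dec <- -dec
        auc_score(dec, y[!tr])
      }, numeric(1))
      sz <- vapply(traj, length, integer(1))
      if (is.null(sizes)) sizes <- sz
      auc_runs[[length(auc_runs) + 1L]] <- aucs[seq_along(sizes)]
    }
  }
  auc_mat <- do.call(rbind, auc_runs)
  mean_auc <- colMeans(auc_mat, na.rm = TRUE)
  best <- which.max(mean_auc)
  # final refit on all data down to the chosen size
  traj_all <- rfe_trajectory(x, y, step_n, min_features)
  sz_all <- vapply(traj_all, length, integer(1))
  chosen <- traj_all[[which(sz_all == sizes[best])[1]]]
  list(best_n_features = sizes[best],
       feature_set = colnames(x)[chosen],
       cv_auc_by_size = stats::setNames(mean_auc, sizes),
       cv_auc = unname(mean_auc[best]))
}
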