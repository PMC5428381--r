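#' Tissue groups used for merged datasets
#' @return named list: `brain` (cortex, cerebellum) and `nonneural`
#'   (liver, muscle, kidney).
#' @export
tissue_groups <- function() {
  list(brain = c("cortex", "cerebellum"),
       nonneural = c("liver", "muscle", "kidney"))
}

# fit one clade-holdout model: lambda by inner-CV deviance at fixed alpha
holdout_fit <- function(x, y, alpha = 0.5, inner_folds = 3L, seed = 1L) {
  select_predictors(x, y, best_alpha = alpha, inner_folds = inner_folds,
                    seed = seed)
}

#' Merge per-tissue datasets by coefficient rank
#'
#' For each tissue, features are sorted by absolute model coefficient
#' (descending), ties and zero-coefficient features by the difference in
#' mean concentration between long- and short-living training individuals
#' (descending). Zero-coefficient, lowest-difference features are removed
#' so every tissue retains the same number of features — the minimum over
#' tissues of the nonzero-coefficient count (at least 1). The reduced
#' matrices are then concatenated row-wise (samples of all tissues), with
#' features aligned purely by rank position, since features are
#' tissue-specific and carry no cross-tissue identity.
#'
#' @param designs named list per tissue: list(x = matrix, y = labels)
#'   (training rows only for the sorting statistics; `x_all` optional).
#' @param models named list per tissue of `predictor_model`s fitted on the
#'   same training split.
#' @return list with `order` (named list of ranked kept column names per
#'   tissue) and `width`.
#' @export
merge_tissue_datasets <- function(designs, models) {
  stopifnot(identical(sort(names(designs)), sort(names(models))))
  ranked <- lapply(names(designs), function(ts) {
    d <- designs[[ts]]
    m <- models[[ts]]
    cf <- m$coefficients[colnames(d$x)]
    cf[is.na(cf)] <- 0
    diff <- colMeans(d$x[d$y, , drop = FALSE]) -
      colMeans(d$x[!d$y, , drop = FALSE])
    ord <- order(-abs(cf), -diff)
    list(cols = colnames(d$x)[ord], nonzero = sum(cf != 0))
  })
  names(ranked) <- names(designs)
  width <- max(1L, min(vapply(ranked, `[[`, integer(1), "nonzero")))
  if (any(vapply(ranked, `[[`, integer(1), "nonzero") == 0L))
    stop("a tissue retained zero features (all coefficients zero)")
  list(order = lapply(ranked, function(r) r$cols[seq_len(width)]),
       width = width)
}

# assemble the merged matrix for given sample rows using a rank order
assemble_merged <- function(designs, order, rows = NULL) {
  parts <- lapply(names(order), function(ts) {
    x <- designs[[ts]]$x[, order[[ts]], drop = FALSE]
    colnames(x) <- sprintf("rank_%03d", seq_len(ncol(x)))
    x
  })
  x <- do.call(rbind, parts)
  y <- unlist(lapply(names(order), function(ts) designs[[ts]]$y))
  keep <- if (is.null(rows)) rep(TRUE, nrow(x)) else rows
  list(x = x[keep, , drop = FALSE], y = y[keep])
}

#' Clade-elimination robustness protocol
#'
#' For a test clade and each removal fraction, repeatedly samples that
#' fraction of the clade's individuals, moves all their samples from the
#' training to the test set, fits per-tissue elastic-net models on the
#' remaining training samples, merges tissues into brain
#' (cortex + cerebellum) and non-neural (liver + muscle + kidney) datasets
#' by coefficient rank, refits on the merged training data, and records the
#' AUC on the held-out clade individuals only. Fraction 1.0 removes the
#' clade entirely from training.
#'
#' @param designs named list per tissue: `list(x, y, individual)` from
#'   [build_design()] plus the per-sample individual id.
#' @param cohort cohort list.
#' @param test_clade clade to eliminate.
#' @param fractions removal fractions in `(0, 1]`.
#' @param reps replicates per fraction.
#' @param alpha elastic-net mixing used throughout (fixed).
#' @param seed integer seed; each (fraction, replicate) uses a
#'   counter-derived sub-seed, so any replicate is reproducible alone.
#' @return tidy data.frame: `clade`, `fraction`, `replicate`, `dataset`
#'   (tissue, `brain`, `nonneural`), `auc` (`NA` when the held-out set is
#'   single-class).
#' @export
run_clade_elimination <- function(designs, cohort, test_clade,
                                  fractions = seq(0.1, 1.0, by = 0.1),
                                  reps = 100L, alpha = 0.5, seed = 1L) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  smp <- cohort$samples
  sp <- cohort$species
  clade_of <- stats::setNames(sp$clade, sp$species_id)
  indiv <- unique(smp[, c("individual_id", "species_id")])
  clade_indiv <- indiv$individual_id[clade_of[indiv$species_id] == test_clade]
  if (length(clade_indiv) == 0L) stop("clade absent from cohort: ", test_clade)
  indiv_of <- lapply(designs, function(d)
    smp$individual_id[match(rownames(d$x), smp$sample_id)])

  out <- list()
  for (fr in fractions) {
    n_rm <- max(1L, round(fr * length(clade_indiv)))
    for (rep_i in seq_len(reps)) {
      set.seed(derive_seed(seed, "holdout", test_clade,
                           round(fr * 100), rep_i))
      held <- if (fr >= 1) clade_indiv else sample(clade_indiv, n_rm)
      models <- list()
      tr_designs <- list()
      for (ts in names(designs)) {
        d <- designs[[ts]]
        te <- indiv_of[[ts]] %in% held
        if (length(unique(d$y[!te])) < 2L) next
        x_tr <- d$x[!te, , drop = FALSE]
        m <- holdout_fit(x_tr, d$y[!te], alpha = alpha,
                         seed = derive_seed(seed, "hfit", ts, rep_i))
        models[[ts]] <- m
        tr_designs[[ts]] <- list(x = x_tr, y = d$y[!te])
        auc <- if (any(te))
          auc_score(predict(m, d$x[te, , drop = FALSE]), d$y[te])
        else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          clade = test_clade, fraction = fr, replicate = rep_i,
          dataset = ts, auc = auc, stringsAsFactors = FALSE)
      }
      for (grp in names(tissue_groups())) {
        tss <- intersect(tissue_groups()[[grp]], names(models))
        if (length(tss) < 2L) next
        mg <- merge_tissue_datasets(tr_designs[tss], models[tss])
        train <- assemble_merged(tr_designs[tss], mg$order)
        m <- holdout_fit(train$x, train$y, alpha = alpha,
                         seed = derive_seed(seed, "hmerge", grp, rep_i))
        te_designs <- lapply(tss, function(ts) {
          d <- designs[[ts]]
          te <- indiv_of[[ts]] %in% held
          list(x = d$x[te, , drop = FALSE], y = d$y[te])
        })
        names(te_designs) <- tss
        test <- assemble_merged(te_designs, mg$order)
        auc <- if (nrow(test$x) > 0L)
          auc_score(predict(m, test$x), test$y) else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          clade = test_clade, fraction = fr, replicate = rep_i,
          dataset = grp, auc = auc, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Permutation baseline of classifier accuracy
#'
#' Randomizes the output labels `n_rand` times and reruns the full
#' fit-and-evaluate step on each permutation, returning the mean and sd of
#' the resulting AUCs — the random-predictor reference band.
#'
#' @param x feature matrix.
#' @param y binary labels.
#' @param n_rand permutations (default 100).
#' @param seed integer seed.
#' @param eval_fun function `(x, y) -> AUC`; the default fits the
#'   elastic-net model at a fixed weak penalty under stratified 3-fold
#'   cross-validation with seed-fixed folds and returns the mean held-out
#'   AUC. The penalty is fixed rather than CV-selected because under
#'   destroyed labels the selected penalty collapses to the constant model,
#'   which would make the baseline degenerate (every AUC exactly 0.5).
#' @param alpha mixing for the default evaluator.
#' @param lambda fixed penalty strength for the default evaluator.
#' @return list with `mean_auc`, `sd_auc` and the vector `aucs`.
#' @export
random_baseline <- function(x, y, n_rand = 100L, seed = 1L,
                            eval_fun = NULL, alpha = 0.5, lambda = 0.05) {
  y <- as.logical(y)
  if (is.null(eval_fun)) {
    eval_fun <- function(x, yp) {
      set.seed(derive_seed(seed, "baseline-folds"))
      k <- min(3L, sum(yp), sum(!yp))
      if (k < 2L) return(NA_real_)
      fid <- stratified_folds(yp, k)
      aucs <- vapply(seq_len(k), function(f) {
        tr <- fid != f
        if (length(unique(yp[tr])) < 2L) return(NA_real_)
        m <- fit_elasticnet_logistic(x[tr, , drop = FALSE], yp[tr],
                                     alpha = alpha, lambda = lambda)
        auc_score(predict(m, x[!tr, , drop = FALSE]), yp[!tr])
      }, numeric(1))
      mean(aucs, na.rm = TRUE)
    }
  }
  aucs <- vapply(seq_len(n_rand), function(b) {
    set.seed(derive_seed(seed, "baseline", b))
    yp <- y[sample.int(length(y))]  # forced here: eval_fun may reseed
    eval_fun(x, yp)
  }, numeric(1))
  list(mean_auc = mean(aucs, na.rm = TRUE),
       sd_auc = stats::sd(aucs, na.rm = TRUE),
       aucs = aucs)
}
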