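test_that("long-living labels follow the 0.9 x clade-max rule", {
  # primates with max MLS 100: threshold 90; 100 labeled, 85 not
  sp <- data.frame(species_id = c("a", "b", "c", "d"),
                   clade = c("primate", "primate", "primate", "rodent"),
                   mls = c(100, 85, 92, 30), stringsAsFactors = FALSE)
  ll <- label_long_living(sp)
  expect_equal(ll$threshold[1:3], rep(90, 3))
  expect_equal(ll$is_long_living, c(TRUE, FALSE, TRUE, TRUE))
  # a single-species clade is always long-living (max > 0.9 max)
  expect_true(ll$is_long_living[ll$species_id == "d"])
  # the clade maximum is always labeled
  expect_true(all(tapply(ll$is_long_living, ll$clade, any)))
  # default synthetic cohort matches the generator's planted counts
  co <- generate_cohort(seed = 19)
  sim <- generate_lipidome(co, n_peaks = 60, seed = 19)
  llc <- label_long_living(co$species)
  expect_setequal(llc$species_id[llc$is_long_living],
                  sim$truth$long_living_species)
})

test_that("AUC equals exhaustive pairwise concordance", {
  # fixed 12-sample fixture: count concordant pairs by hand (oracle)
  scores <- c(0.9, 0.8, 0.7, 0.65, 0.6, 0.55, 0.5, 0.45, 0.4, 0.3, 0.2, 0.1)
  y <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE,
         FALSE, FALSE, FALSE, FALSE)
  pairs <- expand.grid(pos = which(y), neg = which(!y))
  conc <- mean(ifelse(scores[pairs$pos] > scores[pairs$neg], 1,
                      ifelse(scores[pairs$pos] == scores[pairs$neg], 0.5, 0)))
  expect_equal(auc_score(scores, y), conc)

  # property: identity holds on random inputs with ties, and matches pROC
  set.seed(2)
  for (i in 1:20) {
    s <- sample(seq(0, 1, 0.1), 30, replace = TRUE)
    yy <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(0.3, 0.7))
    if (length(unique(yy)) < 2) next
    pp <- expand.grid(pos = which(yy), neg = which(!yy))
    oracle <- mean(ifelse(s[pp$pos] > s[pp$neg], 1,
                          ifelse(s[pp$pos] == s[pp$neg], 0.5, 0)))
    expect_equal(auc_score(s, yy), oracle)
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(3)
    s <- rnorm(40); yy <- rep(c(TRUE, FALSE), 20)
    roc <- suppressMessages(pROC::roc(yy, s, levels = c(FALSE, TRUE),
                                      direction = "<"))
    expect_equal(auc_score(s, yy), as.numeric(pROC::auc(roc)))
  }
  expect_true(is.na(auc_score(1:3, c(TRUE, TRUE, TRUE))))
})

test_that("elastic-net logistic solutions match a dense grid-search minimizer", {
  set.seed(4)
  n <- 40
  x <- cbind(f1 = rnorm(n), f2 = rnorm(n))
  x <- scale(x)
  eta <- 1.2 * x[, 1] - 0.5 * x[, 2]
  y <- runif(n) < plogis(eta)
  alpha <- 0.5; lam <- 0.1
  obj <- function(b0, b1, b2) {
    lin <- b0 + x[, 1] * b1 + x[, 2] * b2
    mean(log(1 + exp(lin)) - y * lin) +
      lam * ((1 - alpha) / 2 * (b1^2 + b2^2) + alpha * (abs(b1) + abs(b2)))
  }
  fit <- fit_elasticnet_logistic(x, y, alpha, lam)
  f_hat <- obj(fit$intercept, fit$coefficients[1], fit$coefficients[2])
  # oracle: dense brute-force grid over (intercept, b1, b2)
  grid <- seq(-2, 2, by = 0.05)
  best <- Inf
  for (b1 in grid) for (b2 in grid) {
    v <- min(vapply(grid, function(b0) obj(b0, b1, b2), numeric(1)))
    if (v < best) best <- v
  }
  expect_lte(f_hat, best + 1e-3)
})

test_that("full shrinkage and ridge symmetry behave as closed forms predict", {
  set.seed(5)
  n <- 60
  x <- scale(matrix(rnorm(n * 3), n, 3))
  colnames(x) <- c("a", "b", "c")
  y <- rep(c(TRUE, FALSE), c(20, 40))
  # huge lambda: all coefficients zero, intercept = logit prevalence
  fit <- fit_elasticnet_logistic(x, y, alpha = 0.5, lambda = 50)
  expect_true(all(fit$coefficients == 0))
  expect_equal(fit$intercept, qlogis(mean(y)), tolerance = 1e-4)
  expect_length(fit$selected_peaks, 0L)

  # two identical columns under pure ridge get equal coefficients
  x2 <- cbind(x[, 1], x[, 1], x[, 3])
  colnames(x2) <- c("d1", "d2", "z")
  y2 <- x[, 1] + rnorm(n, 0, 0.5) > 0
  fit2 <- fit_elasticnet_logistic(x2, y2, alpha = 0, lambda = 0.2)
  expect_equal(fit2$coefficients[["d1"]], fit2$coefficients[["d2"]],
               tolerance = 1e-6)
  expect_error(fit_elasticnet_logistic(x, y, 0.5, -1), "lambda")
  expect_error(fit_elasticnet_logistic(x, rep(TRUE, n), 0.5, 1), "classes")
})

test_that("elastic-net solutions satisfy the subgradient optimality conditions", {
  set.seed(6)
  n <- 80
  x <- scale(matrix(rnorm(n * 10), n, 10))
  colnames(x) <- paste0("f", 1:10)
  y <- runif(n) < plogis(1.5 * x[, 1] - x[, 2])
  for (alpha in c(0.3, 0.9)) {
    lam <- 0.05
    fit <- fit_elasticnet_logistic(x, y, alpha, lam)
    p <- plogis(fit$intercept + drop(x %*% fit$coefficients))
    grad <- drop(crossprod(x, p - y)) / n
    b <- fit$coefficients
    kkt_nz <- grad[b != 0] + lam * (1 - alpha) * b[b != 0] +
      lam * alpha * sign(b[b != 0])
    expect_true(all(abs(kkt_nz) < 1e-4))
    if (any(b == 0))
      expect_true(all(abs(grad[b == 0]) <= lam * alpha + 1e-4))
  }
})

test_that("cross-validation recovers separable signal and is null-calibrated", {
  set.seed(8)
  n <- 60
  x <- scale(matrix(rnorm(n * 6), n, 6))
  colnames(x) <- paste0("f", 1:6)
  y <- rep(c(TRUE, FALSE), c(15, 45))
  x[, 1] <- x[, 1] + ifelse(y, 10, 0)  # perfectly separating feature
  x <- scale(x)
  cv <- cross_validate(x, y, alpha_grid = c(0.5), folds = 5, repeats = 2,
                       seed = 10)
  expect_equal(cv$mean_auc, 1.0)

  yp <- sample(y)
  x0 <- scale(matrix(rnorm(n * 6), n, 6))
  colnames(x0) <- paste0("f", 1:6)
  cv0 <- cross_validate(x0, yp, alpha_grid = c(0.5), folds = 5, repeats = 4,
                        seed = 11)
  mc_se <- stats::sd(cv0$fold_aucs, na.rm = TRUE) /
    sqrt(sum(!is.na(cv0$fold_aucs)))
  expect_lt(abs(cv0$mean_auc - 0.5), max(4 * mc_se, 0.15))
  expect_error(cross_validate(x, rep(TRUE, n), c(0.5)), "class")
})

test_that("predictor selection is invariant to column permutation", {
  set.seed(12)
  n <- 50
  x <- scale(matrix(rnorm(n * 8), n, 8))
  colnames(x) <- paste0("f", 1:8)
  y <- runif(n) < plogis(2 * x[, 2] - 1.5 * x[, 5])
  fit <- fit_elasticnet_logistic(x, y, 0.5, 0.05)
  perm <- c(5, 3, 8, 1, 2, 7, 4, 6)
  fitp <- fit_elasticnet_logistic(x[, perm], y, 0.5, 0.05)
  expect_setequal(fit$selected_peaks, fitp$selected_peaks)
  expect_equal(fitp$coefficients[names(fit$coefficients)],
               fit$coefficients, tolerance = 1e-6)
})

test_that("SVM-RFE removes by step rule, halts at the floor, and keeps informative features", {
  set.seed(13)
  n <- 60
  p <- 100
  x <- matrix(rnorm(n * p), n, p)
  colnames(x) <- paste0("f", 1:p)
  y <- rep(c(TRUE, FALSE), each = n / 2)
  x[, 1] <- x[, 1] + ifelse(y, 3, 0)
  x[, 2] <- x[, 2] - ifelse(y, 3, 0)
  x <- scale(x)

  # 100 features at step_fraction 0.01: exactly 1 removed per iteration
  traj <- lifelipid:::rfe_trajectory(x, y, step_n = 1L, min_features = 10L)
  sizes <- vapply(traj, length, integer(1))
  expect_equal(sizes, seq(100L, 10L, by = -1L))
  expect_lte(min(sizes), 10L)

  res <- svm_rfe(x, y, step_fraction = 0.01, min_features = 10,
                 folds = 3, repeats = 1, seed = 14)
  expect_lte(res$best_n_features, 100L)
  final10 <- traj[[which(sizes == 10L)]]
  # oracle: the two planted features dominate any |t|-ranking
  expect_true(all(c(1L, 2L) %in% final10))
  expect_gte(res$cv_auc, 0.9)
  expect_error(svm_rfe(x[, 1:5], y, min_features = 10), "min_features")
})

test_that("the linear elastic-net model uses clade-normalized lifespan", {
  co <- generate_cohort(seed = 17)
  resp <- normalized_mls(co, co$samples$sample_id)
  expect_true(all(resp > 0 & resp <= 1))
  # the clade-maximum species has response exactly 1
  ll <- label_long_living(co$species)
  max_sp <- ll$species_id[ll$mls == ll$clade_max_mls]
  smp_max <- co$samples$species_id %in% max_sp
  expect_true(all(resp[smp_max] == 1))

  set.seed(18)
  x <- scale(matrix(rnorm(40 * 4), 40, 4))
  colnames(x) <- paste0("f", 1:4)
  # constant response: fully shrunk model
  fit0 <- fit_elasticnet_linear(x, rep(1, 40), 0.5, 0.1)
  expect_true(all(fit0$coefficients == 0))

  # grid-search equivalence for the gaussian objective
  y <- 0.8 * x[, 1] + rnorm(40, 0, 0.2)
  y <- (y - min(y)) / (max(y) - min(y)) * 0.9 + 0.05
  alpha <- 0.5; lam <- 0.05
  fit <- fit_elasticnet_linear(x[, 1:2], y, alpha, lam)
  obj <- function(b0, b1, b2) {
    r <- y - (b0 + x[, 1] * b1 + x[, 2] * b2)
    mean(r^2) / 2 +
      lam * ((1 - alpha) / 2 * (b1^2 + b2^2) + alpha * (abs(b1) + abs(b2)))
  }
  f_hat <- obj(fit$intercept, fit$coefficients[1], fit$coefficients[2])
  grid <- seq(-1, 1, by = 0.02)
  best <- Inf
  for (b1 in grid) for (b2 in grid) {
    v <- min(vapply(seq(0, 1, 0.02), function(b0) obj(b0, b1, b2),
                    numeric(1)))
    if (v < best) best <- v
  }
  expect_lte(f_hat, best + 1e-3)
})

test_that("benchmark AUC is non-decreasing in the planted effect size", {
  co <- generate_cohort(seed = 23)
  aucs <- vapply(c(0, 1, 2), function(es) {
    sim <- generate_lipidome(
      co, n_peaks = 80,
      config = lipidome_config(effect_size = es, n_predictors = 15,
                               n_confounded = 10),
      seed = 23)
    tab <- impute_halfmin(normalize_by_internal_standard(
      sim$tables$muscle, sim$is_peak)$table)
    d <- build_design(tab, co)
    cross_validate(d$x, d$y, alpha_grid = 0.5, folds = 5, repeats = 2,
                   seed = 23)$mean_auc
  }, numeric(1))
  expect_true(all(diff(aucs) > -0.05))
  expect_gt(aucs[3], aucs[1])
})
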