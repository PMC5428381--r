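#' Confounding factors tested against lipid concentrations
#' @return character vector of factor names.
#' @export
confounder_factors <- function() {
  c("sex", "hibernation", "diet", "bmr", "body_temp", "body_mass", "age")
}

# Resolve a factor to its observation unit and design vector.
# Species-level traits (hibernation, diet, BMR, body temperature, body mass)
# are tested against species-mean log concentrations to avoid
# pseudoreplication; individual-level attributes (sex, age) are tested at
# the sample level.
factor_design <- function(table, cohort, factor) {
  smp <- cohort$samples[match(rownames(table$intensities),
                              cohort$samples$sample_id), , drop = FALSE]
  species_level <- factor %in% c("hibernation", "diet", "bmr", "body_temp",
                                 "body_mass")
  if (species_level) {
    sums <- rowsum(table$intensities, smp$species_id)
    counts <- table(smp$species_id)
    y <- sums / as.vector(counts[rownames(sums)])
    sp <- cohort$species[match(rownames(y), cohort$species$species_id), ]
    x <- switch(factor,
                hibernation = sp$hibernates,
                diet = sp$diet,
                bmr = sp$bmr,
                body_temp = sp$body_temp,
                body_mass = sp$body_mass)
  } else {
    y <- table$intensities
    x <- switch(factor, sex = smp$sex, age = smp$age)
  }
  type <- switch(factor,
                 sex = , hibernation = "binary",
                 diet = "categorical",
                 "continuous")
  list(x = x, y = y, type = type)
}

# Per-peak test statistics for one factor design, fully vectorized.
# Binary factors use the pooled two-sample t statistic (identical to the
# regression t on a 0/1 design); continuous factors the simple-regression
# F; categorical factors the one-way ANOVA F.
factor_statistics <- function(x, y, type) {
  m <- nrow(y)
  if (type %in% c("binary", "continuous")) {
    xn <- if (type == "binary") as.numeric(factor(x)) else as.numeric(x)
    sx <- stats::sd(xn)
    if (!is.finite(sx) || sx == 0)
      return(list(statistic = rep(0, ncol(y)), raw_p = rep(1, ncol(y)),
                  df = c(1, m - 2), degenerate = TRUE))
    xc <- (xn - mean(xn)) / sx
    yc <- sweep(y, 2, colMeans(y))
    sy <- sqrt(colSums(yc^2) / (m - 1))
    sy[sy == 0] <- Inf
    r <- as.vector(crossprod(xc, yc)) / ((m - 1) * sy)
    r <- pmin(pmax(r, -1), 1)
    tval <- r * sqrt((m - 2) / pmax(1 - r^2, 1e-300))
    list(statistic = abs(tval),
         raw_p = 2 * stats::pt(-abs(tval), df = m - 2),
         df = c(1, m - 2), degenerate = FALSE)
  } else {
    g <- factor(x)
    k <- nlevels(g)
    if (k < 2L)
      return(list(statistic = rep(0, ncol(y)), raw_p = rep(1, ncol(y)),
                  df = c(0, m - 1), degenerate = TRUE))
    n_g <- as.vector(table(g))
    tot <- colSums(y)
    gs <- rowsum(y, g)
    bss <- colSums(gs^2 / n_g) - tot^2 / m
    tss <- colSums(y^2) - tot^2 / m
    wss <- pmax(tss - bss, 1e-300)
    fval <- (bss / (k - 1)) / (wss / (m - k))
    list(statistic = fval,
         raw_p = stats::pf(fval, k - 1, m - k, lower.tail = FALSE),
         df = c(k - 1, m - k), degenerate = FALSE)
  }
}

#' Test every peak against one confounding factor
#'
#' Applies the factor-appropriate test per peak: two-sided t-test for sex
#' and hibernation, one-way ANOVA for diet, simple linear regression for
#' BMR, body temperature, body mass and age. Species-level traits are
#' tested on species-mean log concentrations; sex and age at the sample
#' level. Requires a complete (imputed) log-scale table.
#'
#' @param table log-scale [peak_table()] without missing values.
#' @param cohort cohort list.
#' @param factor one of [confounder_factors()].
#' @return data.frame with `peak_id`, `factor`, `statistic`, `raw_p`,
#'   `degenerate`.
#' @export
factor_association <- function(table, cohort, factor) {
  factor <- match.arg(factor, confounder_factors())
  d <- factor_design(table, cohort, factor)
  s <- factor_statistics(d$x, d$y, d$type)
  data.frame(peak_id = table$peak_meta$peak_id, factor = factor,
             statistic = s$statistic, raw_p = s$raw_p,
             degenerate = s$degenerate, stringsAsFactors = FALSE)
}

#' Permutation family-wise correction of factor associations
#'
#' Westfall-Young maxT correction: factor values are permuted across
#' observation units `n_perm` times; each peak's corrected p-value is
#' `(1 + #permutations whose maximum statistic over peaks >= observed) /
#' (n_perm + 1)`. Monotonicity in the observed statistic is enforced
#' (step-down), so the corrected p never drops below `1 / (n_perm + 1)` and
#' never falls below the raw p.
#'
#' @param table log-scale [peak_table()] without missing values.
#' @param cohort cohort list.
#' @param factor one of [confounder_factors()].
#' @param n_perm permutations (default 1000, minimum 100).
#' @param seed integer seed.
#' @return [factor_association()] result with a `corrected_p` column.
#' @export
permutation_correct <- function(table, cohort, factor, n_perm = 1000L,
                                seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  obs <- factor_association(table, cohort, factor)
  d <- factor_design(table, cohort, match.arg(factor, confounder_factors()))
  if (obs$degenerate[1]) {
    obs$corrected_p <- 1
    return(obs)
  }
  set.seed(derive_seed(seed, "maxT", factor))
  m <- nrow(d$y)
  max_stats <- numeric(n_perm)

  if (d$type %in% c("binary", "continuous")) {
    xn <- if (d$type == "binary") as.numeric(factor(d$x)) else as.numeric(d$x)
    xc0 <- (xn - mean(xn)) / stats::sd(xn)
    yc <- sweep(d$y, 2, colMeans(d$y))
    sy <- sqrt(colSums(yc^2) / (m - 1))
    sy[sy == 0] <- Inf
    chunk <- 200L
    done <- 0L
    while (done < n_perm) {
      nb <- min(chunk, n_perm - done)
      xp <- vapply(seq_len(nb), function(i) xc0[sample.int(m)], numeric(m))
      r <- crossprod(xp, yc) / outer(rep(m - 1, nb), sy)
      r <- pmin(pmax(r, -1), 1)
      tv <- abs(r) * sqrt((m - 2) / pmax(1 - r^2, 1e-300))
      max_stats[done + seq_len(nb)] <- apply(tv, 1, max)
      done <- done + nb
    }
  } else {
    g <- factor(d$x)
    k <- nlevels(g)
    n_g <- as.vector(table(g))
    tot <- colSums(d$y)
    tss <- colSums(d$y^2) - tot^2 / m
    for (b in seq_len(n_perm)) {
      gp <- g[sample.int(m)]
      gs <- rowsum(d$y, gp)
      bss <- colSums(gs^2 / n_g) - tot^2 / m
      wss <- pmax(tss - bss, 1e-300)
      max_stats[b] <- max((bss / (k - 1)) / (wss / (m - k)))
    }
  }

  # ties counted with a relative tolerance so permutations equivalent to
  # the observed labeling are not lost to float noise
  corrected <- vapply(obs$statistic, function(s)
    (1 + sum(max_stats >= s - 1e-9 * abs(s) - 1e-12)) / (n_perm + 1),
    numeric(1))
  # step-down monotonicity: a peak with a smaller statistic can never have
  # a smaller corrected p
  ord <- order(obs$statistic, decreasing = TRUE)
  corrected[ord] <- cummax(corrected[ord])
  obs$corrected_p <- pmax(corrected, obs$raw_p)
  obs
}

#' Scan all confounding factors with permutation correction
#'
#' @inheritParams permutation_correct
#' @param factors factors to test (default all of [confounder_factors()]).
#' @return data.frame of per-(peak, factor) results with corrected p-values.
#' @export
confounder_scan <- function(table, cohort, factors = confounder_factors(),
                            n_perm = 1000L, seed = 1L) {
  do.call(rbind, lapply(factors, function(f)
    permutation_correct(table, cohort, f, n_perm = n_perm, seed = seed)))
}

#' Remove peaks associated with any confounding factor
#'
#' A peak is removed iff its corrected p-value falls below `alpha` for any
#' tested factor.
#'
#' @param results output of [confounder_scan()] (needs `corrected_p`).
#' @param alpha removal threshold (default 0.01).
#' @return list with `retained` and `removed` peak ids and `removal_counts`
#'   per factor.
#' @export
filter_confounded <- function(results, alpha = 0.01) {
  sig <- results[results$corrected_p < alpha, , drop = FALSE]
  removed <- unique(sig$peak_id)
  retained <- setdiff(unique(results$peak_id), removed)
  counts <- table(factor(sig$factor, levels = unique(results$factor)))
  list(retained = retained, removed = removed,
       removal_counts = as.vector(counts),
       removal_factors = names(counts))
}

#' Test a lipid series for age-related change
#'
#' Fits polynomials of degree 1 to `max_degree` in age, picks the best by
#' adjusted R-squared, and tests it against the constant model with an
#' F-test; the series is age-related iff that p-value is below `alpha`.
#'
#' @param age,value paired numeric vectors.
#' @param max_degree maximum polynomial degree (default 3).
#' @param alpha significance threshold (default 0.01).
#' @return list with `is_age_related`, `best_degree`, `F_p`, `flagged`
#'   (insufficient distinct ages).
#' @export
fit_age_polynomial <- function(age, value, max_degree = 3L, alpha = 0.01) {
  ok <- is.finite(age) & is.finite(value)
  age <- age[ok]; value <- value[ok]
  if (length(unique(age)) < max_degree + 2L)
    return(list(is_age_related = FALSE, best_degree = NA_integer_,
                F_p = NA_real_, flagged = TRUE))
  fits <- lapply(seq_len(max_degree), function(d)
    stats::lm(value ~ stats::poly(age, d)))
  # zero-residual fits trigger a spurious precision warning in summary.lm
  adj <- vapply(fits, function(f)
    suppressWarnings(summary(f)$adj.r.squared), numeric(1))
  best <- which.max(adj)
  sm <- suppressWarnings(summary(fits[[best]]))
  fstat <- sm$fstatistic
  p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  list(is_age_related = is.finite(p) && p < alpha,
       best_degree = best, F_p = unname(p), flagged = FALSE)
}
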