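#' Per-clade concentration change of each peak
#'
#' Change = mean log concentration in long-living species minus mean in all
#' other species of the clade.
#'
#' @param table processed log-scale [peak_table()] (complete matrix).
#' @param cohort cohort list.
#' @return matrix peaks x clades of changes.
#' @export
clade_changes <- function(table, cohort) {
  labels <- label_long_living(cohort$species)
  smp <- cohort$samples[match(rownames(table$intensities),
                              cohort$samples$sample_id), ]
  cl <- labels$clade[match(smp$species_id, labels$species_id)]
  ll <- labels$is_long_living[match(smp$species_id, labels$species_id)]
  clades <- unique(labels$clade)
  out <- sapply(clades, function(cc) {
    sel <- cl == cc
    colMeans(table$intensities[sel & ll, , drop = FALSE]) -
      colMeans(table$intensities[sel & !ll, , drop = FALSE])
  })
  rownames(out) <- table$peak_meta$peak_id
  out
}

#' Cross-clade correlation of predictor concentration changes
#'
#' Pearson correlation, per clade pair, of the per-peak concentration
#' changes restricted to the predictor set; the permutation null shuffles
#' the peak identity of one clade's change vector.
#'
#' @param changes peaks x clades change matrix ([clade_changes()]).
#' @param predictor_peaks predictor peak ids.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame: `clade_a`, `clade_b`, `r`, `perm_p` (one-sided,
#'   positive correlation).
#' @export
crossclade_change_correlation <- function(changes, predictor_peaks,
                                          n_perm = 1000L, seed = 1L) {
  pred <- intersect(predictor_peaks, rownames(changes))
  if (length(pred) < 3L) stop("need >= 3 predictor peaks")
  ch <- changes[pred, , drop = FALSE]
  clades <- colnames(ch)
  set.seed(derive_seed(seed, "crossclade"))
  out <- list()
  for (i in seq_along(clades)[-length(clades)]) {
    for (j in seq((i + 1L), length(clades))) {
      r_obs <- stats::cor(ch[, i], ch[, j])
      r_null <- vapply(seq_len(n_perm), function(b)
        stats::cor(ch[sample.int(nrow(ch)), i], ch[, j]), numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        clade_a = clades[i], clade_b = clades[j], r = r_obs,
        perm_p = (1 + sum(r_null >= r_obs)) / (n_perm + 1),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# upper-tail hypergeometric enrichment p
hyper_p <- function(overlap, group_size, universe_size, n_drawn) {
  stats::phyper(overlap - 1, group_size, universe_size - group_size,
                n_drawn, lower.tail = FALSE)
}

#' Peak groups from annotation metadata
#'
#' Maps annotated peaks into lipid classes, sub-classes or pathways;
#' ambiguously annotated peaks contribute once to every group they match.
#'
#' @param annotations output of [annotate_adducts()].
#' @param grouping grouping column.
#' @return named list of peak-id vectors per group.
#' @export
peak_groups <- function(annotations, grouping = c("lipid_class", "sub_class",
                                                  "pathway")) {
  grouping <- match.arg(grouping)
  g <- unique(annotations[, c("peak_id", grouping)])
  g <- g[!is.na(g[[grouping]]), , drop = FALSE]
  split(g$peak_id, g[[grouping]])
}

#' Lipid-group enrichment of the predictor set
#'
#' Hypergeometric upper-tail test of each group (class, sub-class or
#' pathway) against the annotated universe, with an empirical family-wise
#' correction: `n_samp` random draws of `|predictor set|` peaks from the
#' universe, recording each draw's minimum group p; a group's corrected p
#' is the fraction of draws whose minimum p is at or below its
#' hypergeometric p (add-one estimator).
#'
#' @param predictor_peaks predictor peak ids.
#' @param groups named list of peak-id vectors ([peak_groups()]).
#' @param universe annotated peak ids forming the sampling universe.
#' @param n_samp random draws (default 1000).
#' @param seed integer seed.
#' @return data.frame: `group_id`, `overlap`, `group_size`, `universe`,
#'   `hyper_p`, `perm_p`.
#' @export
class_enrichment <- function(predictor_peaks, groups, universe,
                             n_samp = 1000L, seed = 1L) {
  groups <- lapply(groups, intersect, universe)
  groups <- groups[vapply(groups, length, integer(1)) > 0L]
  if (length(groups) == 0L) stop("no group present in the universe")
  pred <- intersect(predictor_peaks, universe)
  n_drawn <- length(pred)
  gs <- vapply(groups, length, integer(1))
  ov <- vapply(groups, function(g) length(intersect(g, pred)), integer(1))
  hp <- hyper_p(ov, gs, length(universe), n_drawn)

  set.seed(derive_seed(seed, "enrichment"))
  min_ps <- vapply(seq_len(n_samp), function(b) {
    draw <- sample(universe, n_drawn)
    ovb <- vapply(groups, function(g) length(intersect(g, draw)), integer(1))
    min(hyper_p(ovb, gs, length(universe), n_drawn))
  }, numeric(1))
  perm_p <- vapply(hp, function(p)
    (1 + sum(min_ps <= p)) / (n_samp + 1), numeric(1))
  data.frame(group_id = names(groups), overlap = ov, group_size = gs,
             universe = length(universe), hyper_p = hp, perm_p = perm_p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Concentration-shift test for a predictor group
#'
#' Statistic: the median across clades of the median concentration change
#' of the group's predictor peaks. The null resamples equally sized peak
#' sets from the full predictor set; the p-value is two-sided. The
#' direction (`up`/`down`) is the sign of the statistic when significant at
#' `alpha`, `none` otherwise.
#'
#' @param group_peaks predictor peak ids of the group.
#' @param changes peaks x clades change matrix over all predictor peaks.
#' @param n_perm resamples (default 1000).
#' @param alpha significance level for the direction call (default 0.05).
#' @param seed integer seed.
#' @return list: `statistic`, `p`, `direction`.
#' @export
concentration_shift_test <- function(group_peaks, changes, n_perm = 1000L,
                                     alpha = 0.05, seed = 1L) {
  pred <- rownames(changes)
  grp <- intersect(group_peaks, pred)
  if (length(grp) == 0L) stop("group is empty")
  stat_of <- function(peaks)
    stats::median(apply(changes[peaks, , drop = FALSE], 2, stats::median))
  obs <- stat_of(grp)
  set.seed(derive_seed(seed, "shift"))
  null <- vapply(seq_len(n_perm), function(b)
    stat_of(sample(pred, length(grp))), numeric(1))
  p <- (1 + sum(abs(null) >= abs(obs))) / (n_perm + 1)
  list(statistic = obs, p = p,
       direction = if (p < alpha) c("down", "up")[(obs > 0) + 1] else "none")
}

#' Double-bond association within a predictor group
#'
#' Spearman correlation between double-bond counts and concentration change
#' (per-peak median across clades) within the group, with a permutation
#' p-value, plus the group's median double-bond count and 0.25-0.75
#' quartiles.
#'
#' @param group_peaks peak ids of the group.
#' @param db_counts named double-bond counts per peak.
#' @param changes peaks x clades change matrix.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @return list: `rho`, `p`, `median_db`, `db_quartiles`, `defined`.
#' @export
doublebond_association <- function(group_peaks, db_counts, changes,
                                   n_perm = 1000L, seed = 1L) {
  grp <- intersect(group_peaks, names(db_counts))
  grp <- intersect(grp, rownames(changes))
  db <- db_counts[grp]
  ch <- apply(changes[grp, , drop = FALSE], 1, stats::median)
  med <- stats::median(db)
  qs <- stats::quantile(db, c(0.25, 0.75), names = FALSE)
  if (length(unique(db)) < 2L)
    return(list(rho = NA_real_, p = 1, median_db = med,
                db_quartiles = qs, defined = FALSE))
  rho <- stats::cor(db, ch, method = "spearman")
  set.seed(derive_seed(seed, "doublebond"))
  null <- vapply(seq_len(n_perm), function(b)
    stats::cor(db[sample.int(length(db))], ch, method = "spearman"),
    numeric(1))
  p <- (1 + sum(abs(null) >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p = p, median_db = med, db_quartiles = qs, defined = TRUE)
}

#' Significance of predictor overlap between two tissues
#'
#' Peaks are first matched across the two tissues by m/z and retention time
#' ([match_across_datasets()]); the hypergeometric test then asks whether
#' the matched predictor sets overlap more than expected within the matched
#' universe.
#'
#' @param pred_a,pred_b predictor peak ids per tissue.
#' @param matches output of [match_across_datasets()] for the two tissue
#'   tables.
#' @return list: `overlap`, `n_a`, `n_b`, `universe`, `p`.
#' @export
tissue_overlap <- function(pred_a, pred_b, matches) {
  if (nrow(matches) == 0L) stop("empty matched universe")
  a_in <- matches$peak_a %in% pred_a
  b_in <- matches$peak_b %in% pred_b
  overlap <- sum(a_in & b_in)
  n_a <- sum(a_in)
  n_b <- sum(b_in)
  list(overlap = overlap, n_a = n_a, n_b = n_b, universe = nrow(matches),
       p = hyper_p(overlap, n_a, nrow(matches), n_b))
}

#' Percentile test of fatty-acid concentration differences
#'
#' Locates each focal peak's long-vs-short concentration change within the
#' distribution of the same change across all other peaks of the tissue
#' (complement universe); the two-sided p is the tail fraction of the
#' complement distribution at or beyond the observed change.
#'
#' @param focal_peaks focal (e.g. fatty-acid) peak ids.
#' @param changes peaks x clades change matrix over all peaks.
#' @return data.frame: `peak_id`, `change` (median across clades),
#'   `percentile`, `p`.
#' @export
fattyacid_percentile_test <- function(focal_peaks, changes) {
  med <- apply(changes, 1, stats::median)
  focal <- intersect(focal_peaks, names(med))
  bg <- med[setdiff(names(med), focal)]
  out <- lapply(focal, function(pk) {
    pc <- mean(bg <= med[pk])
    data.frame(peak_id = pk, change = med[pk], percentile = pc,
               p = 2 * min(mean(bg >= med[pk]), mean(bg <= med[pk])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
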