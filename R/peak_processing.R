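#' Normalize a peak table by the internal standard
#'
#' Divides each sample's intensities by that sample's internal-standard
#' peak intensity and log-transforms, yielding log concentrations relative
#' to the spiked standard. The internal-standard peak is dropped from the
#' output matrix. Samples in which the standard was not detected cannot be
#' normalized and are flagged.
#'
#' @param table a raw-scale [peak_table()].
#' @param is_peak peak id of the internal standard.
#' @return list with `table` (log-scale `peak_table` without the IS column),
#'   `is_levels` (named IS intensity per retained sample) and
#'   `flagged_samples` (samples lacking the IS, removed).
#' @export
normalize_by_internal_standard <- function(table, is_peak) {
  if (table$log_scale) stop("table is already on the log scale")
  j <- match(is_peak, table$peak_meta$peak_id)
  if (is.na(j)) stop("internal-standard peak not found: ", is_peak)
  is_det <- table$detected[, j]
  flagged <- rownames(table$intensities)[!is_det]
  keep_s <- which(is_det)
  is_levels <- table$intensities[keep_s, j]
  vals <- log(table$intensities[keep_s, -j, drop = FALSE] / is_levels)
  det <- table$detected[keep_s, -j, drop = FALSE]
  vals[!det] <- NA_real_
  out <- peak_table(vals, det, table$peak_meta[-j, , drop = FALSE],
                    tissue = table$tissue, log_scale = TRUE)
  list(table = out,
       is_levels = stats::setNames(is_levels, rownames(vals)),
       flagged_samples = flagged)
}

#' Quality-filter samples on internal-standard level
#'
#' Removes samples whose internal-standard intensity lies outside
#' `k_sd` standard deviations of the tissue mean. Mean and sd are computed
#' once on all samples of the tissue before any removal (single pass, no
#' re-estimation).
#'
#' @param is_levels named numeric, IS intensity per sample.
#' @param k_sd cutoff in sd units (default 2.5).
#' @return character vector of retained sample ids.
#' @export
qc_filter_samples <- function(is_levels, k_sd = 2.5) {
  mu <- mean(is_levels)
  sdv <- stats::sd(is_levels)
  keep <- if (!is.finite(sdv) || sdv == 0) rep(TRUE, length(is_levels))
          else abs(is_levels - mu) <= k_sd * sdv
  if (!any(keep)) stop("all samples removed by the IS quality filter")
  names(is_levels)[keep]
}

#' Filter peaks on per-species detection
#'
#' Keeps a peak iff it was detected in at least `min_fraction` of the
#' individuals of at least one species in the tissue.
#'
#' @param table a [peak_table()] of one tissue.
#' @param cohort cohort list (needs `samples` with `sample_id`,
#'   `species_id`).
#' @param min_fraction detection fraction threshold (default 0.5).
#' @return character vector of retained peak ids.
#' @export
detection_filter <- function(table, cohort, min_fraction = 0.5) {
  sp <- cohort$samples$species_id[match(rownames(table$detected),
                                        cohort$samples$sample_id)]
  counts <- table(sp)
  sums <- rowsum(table$detected + 0, sp)
  frac <- sums / as.vector(counts[rownames(sums)])
  keep <- apply(frac, 2, function(f) any(f >= min_fraction))
  table$peak_meta$peak_id[keep]
}

#' Annotate peaks by adduct mass matching
#'
#' Matches each peak's observed m/z against reference compound ion masses
#' (monoisotopic mass plus adduct shift) within a relative tolerance in
#' parts per million, honouring the peak's ionization mode and the adducts
#' allowed for each compound's class. Matching runs in two passes — primary
#' adducts first, then the rarer ones — and all matches within tolerance are
#' retained, so a peak may be annotated ambiguously.
#'
#' @param table a [peak_table()].
#' @param reference list with `compounds` and `adducts` as produced by
#'   [generate_lipid_reference()].
#' @param tol_ppm mass tolerance, ppm (default 10).
#' @return data.frame with one row per (peak, compound, adduct) match:
#'   `peak_id`, `compound_id`, `adduct`, `ppm_error`, `pass`
#'   (`"primary"`/`"rare"`), plus compound class metadata.
#' @export
annotate_adducts <- function(table, reference, tol_ppm = 10) {
  if (nrow(reference$compounds) == 0L) stop("empty reference table")
  cmp <- reference$compounds
  ad <- merge(reference$adducts, cmp,
              by = "lipid_class")
  ad$expected_mz <- ad$monoisotopic_mass + ad$mass_shift
  meta <- table$peak_meta
  match_pass <- function(adducts) {
    res <- lapply(seq_len(nrow(meta)), function(i) {
      cand <- adducts[adducts$mode == meta$mode[i], , drop = FALSE]
      ppm <- abs(meta$mz[i] - cand$expected_mz) / cand$expected_mz * 1e6
      hit <- which(ppm <= tol_ppm)
      if (length(hit) == 0L) return(NULL)
      data.frame(peak_id = meta$peak_id[i],
                 compound_id = cand$compound_id[hit],
                 adduct = cand$name[hit],
                 ppm_error = ppm[hit],
                 lipid_class = cand$lipid_class[hit],
                 sub_class = cand$sub_class[hit],
                 pathway = cand$pathway[hit],
                 n_double_bonds = cand$n_double_bonds[hit],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  }
  primary <- match_pass(ad[ad$primary, , drop = FALSE])
  rare <- match_pass(ad[!ad$primary, , drop = FALSE])
  out <- rbind(
    if (!is.null(primary)) cbind(primary, pass = "primary"),
    if (!is.null(rare)) cbind(rare, pass = "rare"))
  if (is.null(out))
    out <- data.frame(peak_id = character(), compound_id = character(),
                      adduct = character(), ppm_error = numeric(),
                      lipid_class = character(), sub_class = character(),
                      pathway = character(), n_double_bonds = integer(),
                      pass = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Merge redundant peaks of the same compound
#'
#' Builds a graph on peaks with an edge wherever (i) Pearson correlation of
#' log concentrations over jointly detected samples exceeds `corr_min`,
#' (ii) retention times differ by less than `rt_max_diff` minutes, and
#' (iii) both peaks matched the same reference compound; connected
#' components are merged into composite peaks whose per-sample value is the
#' arithmetic mean of the member log concentrations. Correlations over
#' fewer than `min_shared` jointly detected samples are treated as
#' undefined (no edge).
#'
#' @param table a log-scale [peak_table()].
#' @param annotations output of [annotate_adducts()].
#' @param corr_min correlation threshold (default 0.7, strict `>`).
#' @param rt_max_diff RT difference threshold in minutes (default 0.05,
#'   strict `<`).
#' @param min_shared minimum jointly detected samples for a correlation.
#' @return a composite `peak_table`; merged columns keep the first member's
#'   id and metadata, and `peak_meta$n_members` records component sizes.
#' @export
merge_peaks <- function(table, annotations, corr_min = 0.7,
                        rt_max_diff = 0.05, min_shared = 3L) {
  stopifnot(table$log_scale)
  meta <- table$peak_meta
  n <- nrow(meta)
  cmp_sets <- split(annotations$compound_id, annotations$peak_id)
  # candidate pairs: same compound and close RT; correlation checked last
  cand <- list()
  ann_peaks <- intersect(meta$peak_id, names(cmp_sets))
  idx <- match(ann_peaks, meta$peak_id)
  if (length(idx) > 1L) {
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in seq((a + 1L), length(idx))) {
        i <- idx[a]; j <- idx[b]
        if (abs(meta$rt[i] - meta$rt[j]) >= rt_max_diff) next
        if (length(intersect(cmp_sets[[ann_peaks[a]]],
                             cmp_sets[[ann_peaks[b]]])) == 0L) next
        shared <- table$detected[, i] & table$detected[, j]
        if (sum(shared) < min_shared) next
        r <- stats::cor(table$intensities[shared, i],
                        table$intensities[shared, j])
        if (is.finite(r) && r > corr_min)
          cand[[length(cand) + 1L]] <- c(i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(cand) > 0L)
    g <- igraph::add_edges(g, unlist(cand))
  comp <- igraph::components(g)$membership
  keep_first <- !duplicated(comp)
  new_idx <- match(comp, comp[keep_first])

  vals <- matrix(NA_real_, nrow(table$intensities), sum(keep_first))
  det <- matrix(FALSE, nrow(table$intensities), sum(keep_first))
  for (k in seq_len(sum(keep_first))) {
    members <- which(new_idx == k)
    if (length(members) == 1L) {
      vals[, k] <- table$intensities[, members]
      det[, k] <- table$detected[, members]
    } else {
      sub <- table$intensities[, members, drop = FALSE]
      vals[, k] <- rowMeans(sub, na.rm = TRUE)
      det[, k] <- rowSums(table$detected[, members, drop = FALSE]) > 0
      vals[!det[, k], k] <- NA_real_
    }
  }
  new_meta <- meta[keep_first, , drop = FALSE]
  new_meta$n_members <- tabulate(new_idx, sum(keep_first))
  dimnames(vals) <- list(rownames(table$intensities), new_meta$peak_id)
  dimnames(det) <- dimnames(vals)
  peak_table(vals, det, new_meta, tissue = table$tissue, log_scale = TRUE)
}

#' Match peaks across two datasets by m/z and retention time
#'
#' Pairs peaks of two tables whose m/z agree within `tol_ppm` and whose
#' retention times agree within `rt_tol_sec` seconds (tables store RT in
#' minutes). Matching is one-to-one: candidates are resolved by nearest
#' m/z, ties by nearest RT, then by lower peak index.
#'
#' @param a,b [peak_table()] objects with compatible mode conventions.
#' @param tol_ppm m/z tolerance, ppm (default 10).
#' @param rt_tol_sec RT tolerance, seconds (default 0.1).
#' @return data.frame with `peak_a`, `peak_b`, `ppm_diff`, `rt_diff_sec`.
#' @export
match_across_datasets <- function(a, b, tol_ppm = 10, rt_tol_sec = 0.1) {
  ma <- a$peak_meta; mb <- b$peak_meta
  pairs <- list()
  for (i in seq_len(nrow(ma))) {
    ppm <- abs(ma$mz[i] - mb$mz) / mb$mz * 1e6
    rts <- abs(ma$rt[i] - mb$rt) * 60
    ok <- which(ppm <= tol_ppm & rts <= rt_tol_sec &
                  ma$mode[i] == mb$mode)
    if (length(ok) == 0L) next
    ord <- order(ppm[ok], rts[ok], ok)
    j <- ok[ord[1L]]
    pairs[[length(pairs) + 1L]] <-
      data.frame(peak_a = ma$peak_id[i], peak_b = mb$peak_id[j],
                 ppm_diff = ppm[j], rt_diff_sec = rts[j],
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pairs)
  if (is.null(out))
    return(data.frame(peak_a = character(), peak_b = character(),
                      ppm_diff = numeric(), rt_diff_sec = numeric(),
                      stringsAsFactors = FALSE))
  # enforce one-to-one on the b side: keep the closest a per b peak
  out <- out[order(out$ppm_diff, out$rt_diff_sec), , drop = FALSE]
  out <- out[!duplicated(out$peak_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Impute undetected values by half-minimum
#'
#' Replaces undetected entries by half the smallest detected concentration
#' of the same peak in the tissue (on the log scale: the per-peak minimum
#' minus log 2), a standard left-censoring surrogate applied before model
#' fitting. Peaks with no detected value at all are set to the matrix-wide
#' minimum minus log 2.
#'
#' @param table a log-scale [peak_table()].
#' @return a `peak_table` with a complete intensity matrix (`detected`
#'   unchanged).
#' @export
impute_halfmin <- function(table) {
  stopifnot(table$log_scale)
  vals <- table$intensities
  global_min <- suppressWarnings(min(vals, na.rm = TRUE))
  for (j in seq_len(ncol(vals))) {
    miss <- !table$detected[, j]
    if (!any(miss)) next
    m <- suppressWarnings(min(vals[, j], na.rm = TRUE))
    if (!is.finite(m)) m <- global_min
    vals[miss, j] <- m - log(2)
  }
  out <- table
  out$intensities <- vals
  out
}

#' Run the full peak-processing stage for one tissue
#'
#' Internal-standard normalization, IS-based sample quality filtering,
#' per-species detection filtering, adduct annotation, correlated-peak
#' merging and half-minimum imputation, in the order the pipeline applies
#' them.
#'
#' @param table raw-scale [peak_table()].
#' @param cohort cohort list.
#' @param reference lipid reference.
#' @param is_peak internal-standard peak id.
#' @param tol_ppm annotation mass tolerance, ppm.
#' @param k_sd IS quality cutoff in sd units.
#' @param corr_min,rt_max_diff peak-merging thresholds.
#' @return list with the processed log-scale `table`, the `annotations`
#'   (recomputed on the merged table), and bookkeeping (`retained_samples`,
#'   `retained_peaks`).
#' @export
process_peak_table <- function(table, cohort, reference, is_peak,
                               tol_ppm = 10, k_sd = 2.5,
                               corr_min = 0.7, rt_max_diff = 0.05) {
  norm <- normalize_by_internal_standard(table, is_peak)
  keep_samples <- qc_filter_samples(norm$is_levels, k_sd = k_sd)
  tab <- subset_peaks(norm$table, samples = keep_samples)
  keep_peaks <- detection_filter(tab, cohort)
  tab <- subset_peaks(tab, peaks = keep_peaks)
  ann <- annotate_adducts(tab, reference, tol_ppm = tol_ppm)
  tab <- merge_peaks(tab, ann, corr_min = corr_min,
                     rt_max_diff = rt_max_diff)
  ann <- ann[ann$peak_id %in% tab$peak_meta$peak_id, , drop = FALSE]
  tab <- impute_halfmin(tab)
  list(table = tab, annotations = ann,
       retained_samples = keep_samples, retained_peaks = tab$peak_meta$peak_id)
}
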