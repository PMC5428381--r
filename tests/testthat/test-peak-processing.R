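test_that("internal-standard normalization computes log ratios exactly", {
  # 5-sample fixture with stated IS values; oracle: hand-computed log ratios
  raw <- rbind(c(1000, 200, 50),
               c(500, 100, 25),
               c(800, 160, 40),
               c(1200, 240, 60),
               c(900, 180, 45))
  is_lv <- c(100, 50, 80, 120, 90)
  tab <- make_table(cbind(raw, is_lv), log_scale = FALSE,
                    peak_ids = c("a", "b", "c", "IS"))
  out <- normalize_by_internal_standard(tab, "IS")
  expect_equal(unname(out$is_levels), is_lv)
  expect_equal(unname(out$table$intensities),
               unname(log(raw / is_lv)))
  # intensity 1000 over IS 100 is log(10)
  expect_equal(out$table$intensities[1, "a"], log(10))
  expect_false("IS" %in% out$table$peak_meta$peak_id)
  expect_true(out$table$log_scale)

  # constant IS level c: output is log(intensity) - log(c)
  tabc <- make_table(cbind(raw, 100), log_scale = FALSE,
                     peak_ids = c("a", "b", "c", "IS"))
  outc <- normalize_by_internal_standard(tabc, "IS")
  expect_equal(unname(outc$table$intensities),
               unname(log(raw) - log(100)))

  # sample with undetected IS is flagged and dropped
  det <- matrix(TRUE, 5, 4)
  det[2, 4] <- FALSE
  tabf <- make_table(cbind(raw, is_lv), log_scale = FALSE, detected = det,
                     peak_ids = c("a", "b", "c", "IS"))
  outf <- normalize_by_internal_standard(tabf, "IS")
  expect_equal(outf$flagged_samples, "s02")
  expect_equal(nrow(outf$table$intensities), 4L)
})

test_that("IS quality filter removes exactly the out-of-band samples", {
  base <- c(95, 100, 105, 98, 102, 101, 99, 100)
  mu <- mean(c(base, 0))  # placeholder, recomputed below
  # design a fixture where one sample sits beyond mean + 3 sd
  x <- c(base, mean(base) + 6 * stats::sd(base))
  x[9] <- mean(x[1:8]) + 3 * stats::sd(c(x[1:8], x[9]))
  # iterate once so the z-score of sample 9 on the full vector exceeds 2.5
  repeat {
    z <- abs(x - mean(x)) / stats::sd(x)
    if (z[9] > 2.5) break
    x[9] <- x[9] + 5
  }
  names(x) <- sprintf("s%02d", seq_along(x))
  kept <- qc_filter_samples(x, k_sd = 2.5)
  expect_equal(setdiff(names(x), kept), "s09")
  # a sample exactly at the tissue mean is always retained
  expect_true(names(x)[which.min(abs(x - mean(x)))] %in% kept)
  # the default cutoff is 2.5 sd
  expect_identical(formals(qc_filter_samples)$k_sd, 2.5)
  expect_error(qc_filter_samples(c(a = 0, b = 1e9), k_sd = 1e-6), "all samples")
})

test_that("detection filter keeps peaks detected in half of one species-tissue", {
  co <- mini_cohort(n_sp = 5)
  # 10 samples (one per species), 3 peaks
  det <- matrix(FALSE, 10, 3)
  det[, 1] <- TRUE                 # everywhere -> kept
  det[1, 2] <- TRUE                # 1 of 1 individuals of species 1 -> kept
  vals <- matrix(1, 10, 3)
  tab <- make_table(vals, detected = det,
                    sample_ids = co$samples$sample_id)
  kept <- detection_filter(tab, co)
  expect_equal(kept, c("p01", "p02"))

  # 3 of 5 individuals in one species-tissue (>= 0.5) retained;
  # 2 of 5 everywhere (0.4) removed
  co5 <- mini_cohort(n_sp = 2)
  co5$samples <- do.call(rbind, replicate(5, co5$samples, simplify = FALSE))
  co5$samples$sample_id <- sprintf("%s_%d", co5$samples$sample_id,
                                   rep(1:5, each = 4))
  det2 <- matrix(FALSE, 20, 2)
  sp1 <- which(co5$samples$species_id == "rodent_01")
  det2[sp1[1:3], 1] <- TRUE
  for (sp in unique(co5$samples$species_id))
    det2[which(co5$samples$species_id == sp)[1:2], 2] <- TRUE
  tab2 <- make_table(matrix(1, 20, 2), detected = det2,
                     sample_ids = co5$samples$sample_id)
  expect_equal(detection_filter(tab2, co5), "p01")
})

test_that("adduct annotation applies the ppm tolerance exactly", {
  ref <- list(
    compounds = data.frame(compound_id = "c1",
                           monoisotopic_mass = 500 - 1.007276,
                           lipid_class = "cls", sub_class = "clsa",
                           pathway = "pw", n_double_bonds = 2,
                           stringsAsFactors = FALSE),
    adducts = data.frame(lipid_class = "cls", name = "+H",
                         mass_shift = 1.007276, mode = "pos", primary = TRUE,
                         stringsAsFactors = FALSE))
  # expected ion m/z exactly 500; 9.8 ppm in, 10.2 ppm out
  tab <- make_table(matrix(1, 2, 3),
                    mz = c(500.0, 500 * (1 + 9.8e-6), 500 * (1 + 10.2e-6)),
                    rt = c(1, 1, 1), log_scale = TRUE)
  ann <- annotate_adducts(tab, ref, tol_ppm = 10)
  expect_setequal(ann$peak_id, c("p01", "p02"))
  expect_equal(ann$ppm_error[ann$peak_id == "p01"], 0, tolerance = 1e-9)
  expect_equal(ann$ppm_error[ann$peak_id == "p02"], 9.8, tolerance = 1e-6)
  expect_true(all(ann$pass == "primary"))
  expect_error(annotate_adducts(tab, list(compounds = ref$compounds[0, ],
                                          adducts = ref$adducts)), "empty")
})

test_that("5 ppm matches are a subset of 10 ppm matches and ppm is scale-free", {
  co <- generate_cohort(seed = 21)
  sim <- generate_lipidome(co, n_peaks = 200, seed = 21)
  tab <- sim$tables$kidney
  ann10 <- annotate_adducts(tab, sim$reference, tol_ppm = 10)
  ann5 <- annotate_adducts(tab, sim$reference, tol_ppm = 5)
  key <- function(a) paste(a$peak_id, a$compound_id, a$adduct)
  expect_true(all(key(ann5) %in% key(ann10)))
  expect_gt(nrow(ann10), 0L)

  # relative tolerance: scaling all masses and m/z leaves matches unchanged
  tab_s <- tab
  tab_s$peak_meta$mz <- tab$peak_meta$mz * 1.001
  ref_s <- sim$reference
  ref_s$compounds$monoisotopic_mass <- ref_s$compounds$monoisotopic_mass * 1.001
  ref_s$adducts$mass_shift <- ref_s$adducts$mass_shift * 1.001
  ann_s <- annotate_adducts(tab_s, ref_s, tol_ppm = 10)
  expect_identical(key(ann_s), key(ann10))
})

test_that("peak merging reproduces the hand-derived component structure", {
  # 6-peak fixture: designed correlations and RT/compound pattern.
  # Peaks 1,2,3 share compound cA; 1-2 correlated & close RT, 3 far in RT.
  # Peaks 4,5 share compound cB, correlated, close RT. Peak 6 unannotated.
  set.seed(42)
  base <- rnorm(30)
  vals <- cbind(p1 = base,
                p2 = base + rnorm(30, 0, 0.05),
                p3 = base + rnorm(30, 0, 0.05),
                p4 = rnorm(30),
                p5 = NA,
                p6 = rnorm(30))
  vals[, "p5"] <- vals[, "p4"] + rnorm(30, 0, 0.05)
  tab <- make_table(vals, rt = c(1.00, 1.02, 3.00, 5.00, 5.01, 1.00),
                    peak_ids = paste0("p", 1:6))
  ann <- data.frame(peak_id = c("p1", "p2", "p3", "p4", "p5"),
                    compound_id = c("cA", "cA", "cA", "cB", "cB"),
                    stringsAsFactors = FALSE)
  merged <- merge_peaks(tab, ann)
  # oracle: exhaustive pairwise rule + transitive closure by hand:
  # edges {1,2} and {4,5}; components {1,2},{3},{4,5},{6}
  expect_equal(sort(merged$peak_meta$n_members), c(1, 1, 2, 2))
  expect_equal(ncol(merged$intensities), 4L)
  expect_equal(sum(merged$peak_meta$n_members), 6L)
  # composite value is the member mean
  comp <- merged$peak_meta$peak_id[merged$peak_meta$n_members == 2][1]
  expect_equal(merged$intensities[, "p1"], rowMeans(vals[, c("p1", "p2")]),
               ignore_attr = TRUE)

  # correlation undefined on < 3 shared samples: no edge
  det <- !is.na(vals)
  det[3:30, 2] <- FALSE
  tab2 <- make_table(vals, rt = c(1.00, 1.02, 3, 5, 5.01, 1),
                     detected = det, peak_ids = paste0("p", 1:6))
  tab2$intensities[!det] <- NA
  merged2 <- merge_peaks(tab2, ann)
  expect_true(all(merged2$peak_meta$peak_id[merged2$peak_meta$n_members == 2]
                  != "p1"))
})

test_that("merging never widens the table and preserves the member count sum", {
  co <- generate_cohort(seed = 8)
  sim <- generate_lipidome(co, n_peaks = 150, seed = 8)
  norm <- normalize_by_internal_standard(sim$tables$heart, sim$is_peak)
  ann <- annotate_adducts(norm$table, sim$reference)
  merged <- merge_peaks(norm$table, ann)
  expect_lte(ncol(merged$intensities), ncol(norm$table$intensities))
  expect_equal(sum(merged$peak_meta$n_members),
               ncol(norm$table$intensities))
  # the generator's duplicated split-peaks produce composites
  expect_gt(max(merged$peak_meta$n_members), 1L)
})

test_that("cross-dataset matching honours both tolerances one-to-one", {
  a <- make_table(matrix(1, 2, 3), mz = c(500, 600, 700),
                  rt = c(5, 6, 7))
  # b peak 1: identical; peak 2: 9 ppm off but 0.2 s RT apart; peak 3: match
  b <- make_table(matrix(1, 2, 3),
                  mz = c(500, 600 * (1 + 9e-6), 700.0001),
                  rt = c(5, 6 + 0.2 / 60, 7 + 0.05 / 60))
  m <- match_across_datasets(a, b, tol_ppm = 10, rt_tol_sec = 0.1)
  expect_equal(m$peak_a, c("p01", "p03"))
  expect_equal(m$peak_b, c("p01", "p03"))
  # defaults are 10 ppm and 0.1 s
  expect_identical(formals(match_across_datasets)$tol_ppm, 10)
  expect_identical(formals(match_across_datasets)$rt_tol_sec, 0.1)

  # nearest-m/z resolution when two candidates are in tolerance
  a2 <- make_table(matrix(1, 2, 1), mz = 500, rt = 5)
  b2 <- make_table(matrix(1, 2, 2), mz = c(500 * (1 + 4e-6), 500),
                   rt = c(5, 5))
  m2 <- match_across_datasets(a2, b2)
  expect_equal(m2$peak_b, "p02")
})

test_that("half-minimum imputation completes the matrix without touching detected values", {
  vals <- rbind(c(1.0, NA), c(2.0, 5.0), c(NA, 7.0))
  det <- !is.na(vals)
  tab <- make_table(vals, detected = det)
  imp <- impute_halfmin(tab)
  expect_false(anyNA(imp$intensities))
  expect_equal(imp$intensities[3, 1], 1.0 - log(2))
  expect_equal(imp$intensities[1, 2], 5.0 - log(2))
  expect_equal(imp$intensities[det], tab$intensities[det])
})

test_that("normalization then QC is idempotent on an already-filtered table", {
  co <- generate_cohort(seed = 15)
  sim <- generate_lipidome(co, n_peaks = 100, seed = 15)
  norm <- normalize_by_internal_standard(sim$tables$cortex, sim$is_peak)
  kept <- qc_filter_samples(norm$is_levels)
  is2 <- norm$is_levels[kept]
  kept2 <- qc_filter_samples(is2)
  # a second pass on the filtered samples with the same statistics keeps all
  mu <- mean(norm$is_levels); sdv <- stats::sd(norm$is_levels)
  in_band <- abs(is2 - mu) <= 2.5 * sdv
  expect_true(all(in_band))
  expect_setequal(kept2, kept[abs(is2 - mean(is2)) <= 2.5 * stats::sd(is2)])
})
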