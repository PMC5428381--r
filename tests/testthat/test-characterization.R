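test_that("cross-clade change correlation is exact on identical vectors and matches enumeration", {
  ch <- cbind(rodent = c(1, -2, 0.5, 3, -1, 2),
              primate = c(1, -2, 0.5, 3, -1, 2),
              bat = c(0.9, -1.8, 0.4, 2.5, -0.8, 1.7))
  rownames(ch) <- paste0("p", 1:6)
  res <- crossclade_change_correlation(ch, rownames(ch), n_perm = 500,
                                       seed = 1)
  expect_equal(res$r[res$clade_a == "rodent" & res$clade_b == "primate"], 1)
  expect_true(all(res$r > 0.9))

  # n = 6: oracle enumerates all 6! = 720 peak-identity permutations
  set.seed(2)
  cha <- cbind(a = rnorm(6), b = rnorm(6))
  rownames(cha) <- paste0("q", 1:6)
  r_obs <- cor(cha[, 1], cha[, 2])
  exact <- mean(vapply(all_perms(6), function(p)
    cor(cha[p, 1], cha[, 2]) >= r_obs, logical(1)))
  res2 <- crossclade_change_correlation(cha, rownames(cha), n_perm = 2000,
                                        seed = 3)
  mc_se <- sqrt(exact * (1 - exact) / 2000)
  expect_lt(abs(res2$perm_p - exact), 2 * mc_se + 2 / 2000)
  expect_error(crossclade_change_correlation(cha, c("q1", "q2")), ">= 3")
})

test_that("the generator's clade-shared signal yields significant cross-clade correlation", {
  bm <- default_benchmark()
  tab <- impute_halfmin(normalize_by_internal_standard(
    bm$sim$tables$cortex, bm$sim$is_peak)$table)
  ch <- clade_changes(tab, bm$cohort)
  res <- crossclade_change_correlation(ch, bm$sim$truth$predictor_peaks,
                                       n_perm = 1000, seed = 4)
  expect_true(all(res$r > 0))
  expect_true(all(res$perm_p < 0.01))
})

test_that("hypergeometric enrichment equals the exact tail sum and the empirical floor holds", {
  # universe 20, group 5, draws 8, overlap 4: exact combinatorial tail
  exact <- sum(choose(5, 4:5) * choose(15, 8 - (4:5))) / choose(20, 8)
  expect_equal(lifelipid:::hyper_p(4, 5, 20, 8), exact, tolerance = 1e-12)

  universe <- paste0("p", 1:20)
  groups <- list(g1 = universe[1:5], g2 = universe[6:12])
  pred <- c(universe[1:4], universe[13:16])  # 4 of 5 in g1
  res <- class_enrichment(pred, groups, universe, n_samp = 300, seed = 5)
  expect_equal(res$hyper_p[res$group_id == "g1"], exact, tolerance = 1e-12)
  expect_true(all(res$perm_p >= 1 / 301))
  expect_true(all(res$perm_p >= res$hyper_p - 0.1))  # correction inflates

  # predictor set equal to an entire group: overlap = group size, minimal p
  res2 <- class_enrichment(universe[1:5], groups, universe, n_samp = 200,
                           seed = 6)
  expect_equal(res2$overlap[res2$group_id == "g1"], 5L)
  expect_equal(res2$hyper_p[res2$group_id == "g1"],
               min(res2$hyper_p))
  expect_error(class_enrichment(pred, list(gx = "absent"), universe),
               "no group")
})

test_that("enrichment is invariant to peak id relabeling", {
  universe <- paste0("p", 1:30)
  groups <- list(a = universe[1:6], b = universe[7:20])
  pred <- universe[c(1:5, 21:24)]
  res <- class_enrichment(pred, groups, universe, n_samp = 500, seed = 7)
  relab <- stats::setNames(paste0("z", 30:1), universe)
  res2 <- class_enrichment(unname(relab[pred]),
                           lapply(groups, function(g) unname(relab[g])),
                           unname(relab[universe]), n_samp = 500, seed = 7)
  expect_equal(res2$hyper_p, res$hyper_p)
  expect_equal(res2$perm_p, res$perm_p)
})

test_that("concentration-shift test matches exhaustive subset enumeration", {
  # 10 predictors, 4-peak group: all C(10,4) = 210 subsets enumerable
  set.seed(8)
  ch <- cbind(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  rownames(ch) <- paste0("p", 1:10)
  grp <- paste0("p", 1:4)
  stat_of <- function(rows)
    median(apply(ch[rows, , drop = FALSE], 2, median))
  obs <- stat_of(grp)
  subsets <- combn(10, 4)
  null <- apply(subsets, 2, function(ix) stat_of(rownames(ch)[ix]))
  exact <- mean(abs(null) >= abs(obs) - 1e-12)
  res <- concentration_shift_test(grp, ch, n_perm = 2000, seed = 9)
  expect_equal(res$statistic, obs)
  mc_se <- sqrt(exact * (1 - exact) / 2000)
  expect_lt(abs(res$p - exact), 2 * mc_se + 0.02)

  # strongly shifted group: direction up with minimal p
  ch2 <- ch; ch2[1:4, ] <- ch2[1:4, ] + 10
  res2 <- concentration_shift_test(paste0("p", 1:4), ch2, n_perm = 400,
                                   seed = 10)
  expect_equal(res2$direction, "up")
  expect_lte(res2$p, 0.05)
  expect_error(concentration_shift_test(character(0), ch), "empty")
})

test_that("random groups give uniform shift p-values", {
  set.seed(11)
  ch <- cbind(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  rownames(ch) <- paste0("p", 1:40)
  ps <- vapply(1:60, function(i)
    concentration_shift_test(sample(rownames(ch), 8), ch, n_perm = 200,
                             seed = 100 + i)$p, numeric(1))
  # null calibration: roughly uniform; mean near 0.5, few small p
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("double-bond association detects planted monotone structure", {
  db <- stats::setNames(c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9), paste0("p", 1:10))
  ch <- cbind(a = as.numeric(db) * 0.3, b = as.numeric(db) * 0.3 + 0.05)
  rownames(ch) <- names(db)
  res <- doublebond_association(names(db), db, ch, n_perm = 500, seed = 12)
  expect_true(res$defined)
  expect_equal(res$rho, 1)
  expect_lt(res$p, 0.05)
  expect_equal(res$median_db, 4.5)
  # quartile reporting uses the 0.25 and 0.75 probabilities
  expect_equal(res$db_quartiles, unname(quantile(db, c(0.25, 0.75))))

  # constant counts: undefined, flagged
  db0 <- stats::setNames(rep(3, 10), names(db))
  res0 <- doublebond_association(names(db), db0, ch)
  expect_false(res0$defined)
  expect_equal(res0$p, 1)
})

test_that("tissue overlap significance equals the exact tail on a 20-peak universe", {
  matches <- data.frame(peak_a = paste0("a", 1:20), peak_b = paste0("b", 1:20),
                        stringsAsFactors = FALSE)
  pred_a <- paste0("a", 1:8)
  pred_b <- paste0("b", c(1:4, 9:13))
  res <- tissue_overlap(pred_a, pred_b, matches)
  expect_equal(res$overlap, 4L)
  exact <- sum(choose(8, 4:8) * choose(12, 9 - (4:8))) / choose(20, 9)
  expect_equal(res$p, exact, tolerance = 1e-12)

  # identical sets: maximal overlap, minimal p; disjoint sets: p near 1
  res_id <- tissue_overlap(pred_a, paste0("b", 1:8), matches)
  expect_equal(res_id$overlap, 8L)
  expect_lt(res_id$p, res$p)
  res_dis <- tissue_overlap(paste0("a", 1:3), paste0("b", 10:12), matches)
  expect_equal(res_dis$overlap, 0L)
  expect_gt(res_dis$p, 0.5)
  expect_error(tissue_overlap(pred_a, pred_b, matches[0, ]), "empty")
})

test_that("fatty-acid percentile test places focal changes in the complement distribution", {
  ch <- cbind(a = c(5, -5, seq(-1, 1, length.out = 18)))
  rownames(ch) <- paste0("p", 1:20)
  res <- fattyacid_percentile_test(c("p1", "p2"), ch)
  expect_equal(res$percentile[res$peak_id == "p1"], 1)
  expect_equal(res$percentile[res$peak_id == "p2"], 0)
  expect_true(all(res$p <= 2 / 18 + 1e-12))
})
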