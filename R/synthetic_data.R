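#' Tissues covered by the study design
#'
#' @return character vector of the six sampled tissues.
#' @export
lifelipid_tissues <- function() {
  c("liver", "muscle", "kidney", "heart", "cortex", "cerebellum")
}

#' Cohort generator configuration
#'
#' Defaults emulate the study design: three mammalian clades (rodents,
#' primates, bats) whose maximal lifespans (MLS) span the published ranges
#' (4-31 years in rodents, 15-100 in primates, 10-33 in bats), with one
#' long-living rodent and primate and two long-living bat species planted
#' by construction, mirroring the naked mole-rat, human and two bat species.
#' Body mass is drawn per clade and basal metabolic rate follows a noisy
#' allometric power law on mass; MLS is drawn independently of mass so that
#' lifespan is uncoupled from the confounders by design.
#'
#' @param mls_range named list of `c(min, max)` MLS per clade, years.
#' @param n_long named integer vector: long-living species per clade.
#' @param mass_range named list of `c(min, max)` body mass per clade, grams
#'   (log-uniform draw).
#' @param bmr_exponent,bmr_coef allometric rule `bmr = coef * mass^exponent`
#'   (W), with multiplicative log-normal noise `bmr_noise_sd`.
#' @param bmr_noise_sd sd of the log-scale BMR noise.
#' @param body_temp_mean,body_temp_sd body temperature distribution, deg C.
#' @param diets diet categories sampled per species.
#' @param p_hibernate named probability of hibernation per clade.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(mls_range = list(rodent = c(4, 31),
                                           primate = c(15, 100),
                                           bat = c(10, 33)),
                          n_long = c(rodent = 1L, primate = 1L, bat = 2L),
                          mass_range = list(rodent = c(20, 2000),
                                            primate = c(100, 70000),
                                            bat = c(5, 60)),
                          bmr_exponent = 0.75,
                          bmr_coef = 0.018,
                          bmr_noise_sd = 0.15,
                          body_temp_mean = 36.5,
                          body_temp_sd = 1.0,
                          diets = c("herbivore", "omnivore", "insectivore",
                                    "carnivore"),
                          p_hibernate = c(rodent = 0.25, primate = 0,
                                          bat = 0.5)) {
  structure(list(mls_range = mls_range, n_long = n_long,
                 mass_range = mass_range, bmr_exponent = bmr_exponent,
                 bmr_coef = bmr_coef, bmr_noise_sd = bmr_noise_sd,
                 body_temp_mean = body_temp_mean, body_temp_sd = body_temp_sd,
                 diets = diets, p_hibernate = p_hibernate),
            class = "cohort_config")
}

#' Generate a synthetic multi-clade cohort
#'
#' Draws species-level traits (clade, MLS, BMR, body mass and temperature,
#' diet, hibernation) and individual-level samples (tissue, sex, age,
#' internal-standard level). Each species contributes `n_individuals`
#' individuals, each sampled in every tissue; sex and age are shared by an
#' individual across its tissues while the internal-standard level varies
#' per measurement.
#'
#' @param n_species_per_clade named integer vector, species per clade;
#'   default `c(rodent = 16, primate = 12, bat = 7)` (35 species).
#' @param n_individuals individuals per species (default 3).
#' @param tissues tissues sampled (default [lifelipid_tissues()]).
#' @param seed integer seed; the draw is deterministic given seed and config.
#' @param config a [cohort_config()].
#' @return list with `species` and `samples` data frames.
#' @export
generate_cohort <- function(n_species_per_clade = c(rodent = 16L,
                                                    primate = 12L,
                                                    bat = 7L),
                            n_individuals = 3L,
                            tissues = lifelipid_tissues(),
                            seed = 1L,
                            config = cohort_config()) {
  if (any(n_species_per_clade < 2L))
    stop("each clade needs at least 2 species")
  if (n_individuals < 1L) stop("n_individuals must be >= 1")
  if (length(tissues) == 0L) stop("tissue list must be nonempty")
  clades <- names(n_species_per_clade)
  set.seed(derive_seed(seed, "cohort"))

  species <- do.call(rbind, lapply(clades, function(cl) {
    n <- n_species_per_clade[[cl]]
    n_long <- min(config$n_long[[cl]], n - 1L)
    rng <- config$mls_range[[cl]]
    # long-living species pinned near the top of the clade range, the rest
    # kept below 0.85 of it, so the 0.9 x clade-max rule labels exactly
    # n_long species
    mls <- c(stats::runif(n_long, 0.95 * rng[2], rng[2]),
             stats::runif(n - n_long, rng[1], 0.85 * rng[2]))
    mrng <- log(config$mass_range[[cl]])
    mass <- exp(stats::runif(n, mrng[1], mrng[2]))
    bmr <- config$bmr_coef * mass^config$bmr_exponent *
      exp(stats::rnorm(n, 0, config$bmr_noise_sd))
    data.frame(
      species_id = sprintf("%s_%02d", cl, seq_len(n)),
      clade = cl,
      mls = mls,
      bmr = bmr,
      body_mass = mass,
      body_temp = stats::rnorm(n, config$body_temp_mean, config$body_temp_sd),
      diet = sample(config$diets, n, replace = TRUE),
      hibernates = stats::runif(n) < config$p_hibernate[[cl]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(species) <- NULL

  indiv <- do.call(rbind, lapply(seq_len(nrow(species)), function(i) {
    data.frame(
      individual_id = sprintf("%s_i%d", species$species_id[i],
                              seq_len(n_individuals)),
      species_id = species$species_id[i],
      sex = sample(c("M", "F"), n_individuals, replace = TRUE),
      age = stats::runif(n_individuals, 0.1, 0.8) * species$mls[i],
      stringsAsFactors = FALSE
    )
  }))

  samples <- do.call(rbind, lapply(tissues, function(ts) {
    data.frame(
      sample_id = paste(indiv$individual_id, ts, sep = "_"),
      individual_id = indiv$individual_id,
      species_id = indiv$species_id,
      tissue = ts,
      sex = indiv$sex,
      age = indiv$age,
      is_level = exp(stats::rnorm(nrow(indiv), log(1e5), 0.25)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(samples) <- NULL
  list(species = species, samples = samples)
}

#' Construct a peak table
#'
#' The central container of the pipeline: a samples x peaks intensity matrix
#' with a same-shape detection mask and per-peak metadata (m/z, retention
#' time in minutes, ionization mode). Values may be raw intensities or, after
#' normalization, log concentrations (`log_scale`).
#'
#' @param intensities numeric matrix, samples in rows, peaks in columns;
#'   dimnames are sample and peak ids.
#' @param detected logical matrix of the same shape; undetected entries carry
#'   `NA` intensity.
#' @param peak_meta data frame with columns `peak_id`, `mz`, `rt`, `mode`
#'   (and optionally annotation columns), one row per column of
#'   `intensities`.
#' @param tissue tissue label.
#' @param log_scale whether values are log concentrations.
#' @return object of class `peak_table`.
#' @export
peak_table <- function(intensities, detected, peak_meta, tissue = NA_character_,
                       log_scale = FALSE) {
  stopifnot(identical(dim(intensities), dim(detected)),
            nrow(peak_meta) == ncol(intensities),
            identical(peak_meta$peak_id, colnames(intensities)))
  structure(list(intensities = intensities, detected = detected,
                 peak_meta = peak_meta, tissue = tissue,
                 log_scale = log_scale),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("peak_table: %d samples x %d peaks (%s, %s scale), %.1f%% detected\n",
              nrow(x$intensities), ncol(x$intensities),
              ifelse(is.na(x$tissue), "no tissue", x$tissue),
              ifelse(x$log_scale, "log", "raw"),
              100 * mean(x$detected)))
  invisible(x)
}

#' @export
dim.peak_table <- function(x) dim(x$intensities)

#' Subset a peak table by samples and/or peaks
#'
#' @param table a [peak_table()].
#' @param samples sample ids or indices to keep (NULL = all).
#' @param peaks peak ids or indices to keep (NULL = all).
#' @return the subsetted `peak_table`.
#' @export
subset_peaks <- function(table, samples = NULL, peaks = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(table$intensities)) else samples
  pi <- if (is.null(peaks)) seq_len(ncol(table$intensities)) else peaks
  if (is.character(pi)) pi <- match(pi, table$peak_meta$peak_id)
  peak_table(table$intensities[si, pi, drop = FALSE],
             table$detected[si, pi, drop = FALSE],
             table$peak_meta[pi, , drop = FALSE],
             tissue = table$tissue, log_scale = table$log_scale)
}

#' Lipidome generator configuration
#'
#' Controls the planted signal and noise structure of the synthetic
#' lipidome. Log-scale intensities are a sum of a per-peak baseline, a
#' species random effect, a planted long-living shift for predictor peaks
#' (same sign in every clade), linear confounder terms for confounded peaks,
#' and individual noise; the table is exponentiated and multiplied by the
#' sample's internal-standard level, so internal-standard normalization and
#' the log transform recover the simulated log concentrations.
#'
#' `effect_size` is the standardized mean difference (relative to the total
#' within-group sd, species effect plus individual noise) between long-living
#' and other species at predictor peaks; `tissue_effect_mult` lets one
#' tissue carry a stronger signal (cortex by default, the designated
#' high-signal tissue).
#'
#' @param n_predictors planted lifespan-associated peaks.
#' @param n_confounded planted confounder-associated peaks.
#' @param effect_size standardized mean difference of the planted shift.
#' @param confounder_effect standardized slope magnitude of confounded peaks.
#' @param tissue_effect_mult named multipliers of `effect_size` per tissue;
#'   unlisted tissues use 1.
#' @param sigma_species sd of the species random effect (log scale).
#' @param noise_sd sd of individual noise (log scale).
#' @param missing_rate marginal probability that a peak measurement is
#'   undetected, in `[0, 1)`.
#' @param baseline_mean,baseline_sd per-peak log-intensity baseline.
#' @param annotated_fraction fraction of peaks carrying a database compound.
#' @param mz_range observable m/z window, Da.
#' @param rt_range chromatographic window, minutes.
#' @param is_mz m/z of the internal-standard peak (PC 34:0 [M+H]+).
#' @param n_duplicate_pairs annotated peaks duplicated as split features of
#'   the same compound (exercises peak merging).
#' @return list of class `lipidome_config`.
#' @export
lipidome_config <- function(n_predictors = 25L,
                            n_confounded = 25L,
                            effect_size = 2.0,
                            confounder_effect = 1.5,
                            tissue_effect_mult = c(cortex = 1.5),
                            sigma_species = 0.3,
                            noise_sd = 0.4,
                            missing_rate = 0.15,
                            baseline_mean = 11,
                            baseline_sd = 1,
                            annotated_fraction = 0.6,
                            mz_range = c(100, 1500),
                            rt_range = c(0, 20),
                            is_mz = 762.6007,
                            n_duplicate_pairs = 6L) {
  structure(as.list(environment()), class = "lipidome_config")
}

#' Generate a synthetic lipid compound reference
#'
#' Builds a stand-in compound database: monoisotopic masses, a hierarchy of
#' lipid classes, sub-classes and pathways, double-bond counts, and an
#' allowed-adduct table per class (a primary adduct per ionization mode plus
#' rarer alternatives). It mimics the shape of a lipid database, not its
#' content.
#'
#' @param n_compounds number of reference compounds.
#' @param n_classes,subclasses_per_class,n_pathways taxonomy sizes.
#' @param mass_range monoisotopic mass window, Da.
#' @param seed integer seed.
#' @return list with `compounds` and `adducts` data frames.
#' @export
generate_lipid_reference <- function(n_compounds = 200L,
                                     n_classes = 12L,
                                     subclasses_per_class = 2L,
                                     n_pathways = 12L,
                                     mass_range = c(200, 1400),
                                     seed = 1L) {
  set.seed(derive_seed(seed, "reference"))
  classes <- sprintf("class_%02d", seq_len(n_classes))
  cls <- sample(classes, n_compounds, replace = TRUE)
  sub <- paste0(cls, letters[sample.int(subclasses_per_class,
                                        n_compounds, replace = TRUE)])
  compounds <- data.frame(
    compound_id = sprintf("cmp_%04d", seq_len(n_compounds)),
    monoisotopic_mass = stats::runif(n_compounds, mass_range[1], mass_range[2]),
    lipid_class = cls,
    sub_class = sub,
    pathway = sprintf("pathway_%02d", sample.int(n_pathways, n_compounds,
                                                 replace = TRUE)),
    n_double_bonds = stats::rpois(n_compounds, 3),
    stringsAsFactors = FALSE
  )
  adduct_defs <- data.frame(
    name = c("+H", "+NH4", "+Na", "-H", "+HCOO"),
    mass_shift = c(1.007276, 18.033823, 22.989218, -1.007276, 44.998201),
    mode = c("pos", "pos", "pos", "neg", "neg"),
    primary = c(TRUE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  # every class allows both primary adducts; each rare adduct is allowed in
  # a random ~60% of classes
  adducts <- do.call(rbind, lapply(classes, function(cl) {
    keep <- adduct_defs$primary | stats::runif(nrow(adduct_defs)) < 0.6
    cbind(lipid_class = cl, adduct_defs[keep, , drop = FALSE])
  }))
  rownames(adducts) <- NULL
  list(compounds = compounds, adducts = adducts)
}

#' Generate synthetic tissue lipidomes with known ground truth
#'
#' Produces one raw-intensity [peak_table()] per tissue over a shared peak
#' universe, plus the ground truth needed for parameter-recovery tests.
#' Predictor peaks receive a long-living concentration shift with the same
#' sign in every clade; confounded peaks receive a linear term in one
#' confounding factor; every peak also carries a species random effect and
#' individual noise. Raw intensities are the exponentiated log
#' concentrations multiplied by each sample's internal-standard level, and
#' an internal-standard peak is appended to every table.
#'
#' @param cohort output of [generate_cohort()].
#' @param n_peaks peaks per tissue table (excluding the internal standard).
#' @param config a [lipidome_config()].
#' @param reference optional output of [generate_lipid_reference()]; built
#'   automatically when `NULL`.
#' @param seed integer seed.
#' @return list with `tables` (named list of `peak_table` per tissue),
#'   `reference`, `is_peak` (internal-standard peak id) and `truth`
#'   (predictor peak ids and signs, per-tissue multipliers, confounded peak
#'   map, predictor compound ids, effect size).
#' @export
generate_lipidome <- function(cohort, n_peaks = 350L,
                              config = lipidome_config(),
                              reference = NULL, seed = 1L) {
  if (nrow(cohort$samples) == 0L) stop("cohort is empty")
  if (config$missing_rate >= 1) stop("missing_rate must be < 1")
  if (n_peaks < config$n_predictors + config$n_confounded)
    stop("n_peaks smaller than the planted sets")
  set.seed(derive_seed(seed, "lipidome"))
  if (is.null(reference))
    reference <- generate_lipid_reference(
      n_compounds = max(50L, round(n_peaks * config$annotated_fraction * 0.8)),
      seed = derive_seed(seed, "lipidome", "ref"))

  tissues <- unique(cohort$samples$tissue)
  peak_ids <- sprintf("peak_%04d", seq_len(n_peaks))

  # planted sets: predictors first (always annotated, so enzyme links can
  # point at them), then confounded peaks
  predictor_peaks <- peak_ids[seq_len(config$n_predictors)]
  confounded_idx <- config$n_predictors + seq_len(config$n_confounded)
  confounders <- c("sex", "hibernation", "diet", "bmr", "body_temp",
                   "body_mass", "age")
  confounded_map <- stats::setNames(
    sample(confounders, config$n_confounded, replace = TRUE),
    peak_ids[confounded_idx])

  # peak -> compound/adduct assignment; ~annotated_fraction of peaks match a
  # reference compound through an allowed adduct, with a few duplicated
  # split-peaks of the same compound for the merge stage
  n_annot <- round(n_peaks * config$annotated_fraction)
  annot_idx <- seq_len(max(n_annot, config$n_predictors))
  cmp_pick <- sample(nrow(reference$compounds), length(annot_idx),
                     replace = length(annot_idx) > nrow(reference$compounds))
  if (config$n_duplicate_pairs > 0L) {
    # split-peak sources sit outside the planted predictor/confounded sets
    offset <- config$n_predictors + config$n_confounded
    n_dup <- min(config$n_duplicate_pairs,
                 max(0L, (length(annot_idx) - offset) %/% 2L))
    config$n_duplicate_pairs <- n_dup
    dup_src <- annot_idx[offset + seq_len(n_dup)]
    dup_dst <- annot_idx[length(annot_idx) - seq_len(n_dup) + 1L]
    cmp_pick[match(dup_dst, annot_idx)] <- cmp_pick[match(dup_src, annot_idx)]
  }
  compound_id <- rep(NA_character_, n_peaks)
  compound_id[annot_idx] <- reference$compounds$compound_id[cmp_pick]

  mode <- sample(c("pos", "neg"), n_peaks, replace = TRUE)
  mz <- stats::runif(n_peaks, config$mz_range[1], config$mz_range[2])
  rt <- stats::runif(n_peaks, config$rt_range[1], config$rt_range[2])
  for (i in annot_idx) {
    ad <- reference$adducts[reference$adducts$lipid_class ==
                              reference$compounds$lipid_class[cmp_pick[match(i, annot_idx)]] &
                            reference$adducts$mode == mode[i], , drop = FALSE]
    ad <- ad[sample.int(nrow(ad), 1L), ]
    mass <- reference$compounds$monoisotopic_mass[cmp_pick[match(i, annot_idx)]]
    # observed m/z within ~3 ppm of the adduct ion mass
    mz[i] <- (mass + ad$mass_shift) * (1 + stats::rnorm(1, 0, 1e-6))
  }
  # duplicated split-peaks share compound, near-identical RT
  if (config$n_duplicate_pairs > 0L) {
    rt[dup_dst] <- rt[dup_src] + stats::runif(config$n_duplicate_pairs,
                                              -0.02, 0.02)
    mode[dup_dst] <- mode[dup_src]
    mz[dup_dst] <- mz[dup_src] * (1 + stats::rnorm(config$n_duplicate_pairs,
                                                   0, 2e-6))
  }
  ann <- match(compound_id, reference$compounds$compound_id)
  base_meta <- data.frame(
    peak_id = peak_ids, mz = mz, rt = rt, mode = mode,
    compound_id = compound_id,
    lipid_class = reference$compounds$lipid_class[ann],
    sub_class = reference$compounds$sub_class[ann],
    pathway = reference$compounds$pathway[ann],
    n_double_bonds = reference$compounds$n_double_bonds[ann],
    stringsAsFactors = FALSE
  )

  sd_total <- sqrt(config$sigma_species^2 + config$noise_sd^2)
  sign_p <- sample(c(-1, 1), config$n_predictors, replace = TRUE)
  species <- cohort$species
  long_living <- label_long_living(species)$is_long_living
  names(long_living) <- species$species_id

  conf_z <- local({
    z <- function(v) {
      v <- as.numeric(v)
      s <- stats::sd(v)
      if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
    }
    list(bmr = stats::setNames(z(log(species$bmr)), species$species_id),
         body_mass = stats::setNames(z(log(species$body_mass)),
                                     species$species_id),
         body_temp = stats::setNames(z(species$body_temp), species$species_id),
         hibernation = stats::setNames(ifelse(species$hibernates, 0.5, -0.5),
                                       species$species_id),
         diet = stats::setNames(
           z(as.integer(factor(species$diet))), species$species_id))
  })

  mu_peak <- stats::rnorm(n_peaks, config$baseline_mean, config$baseline_sd)
  tissue_mult <- vapply(tissues, function(ts)
    unname(config$tissue_effect_mult[ts] %||% NA_real_), numeric(1))
  tissue_mult[is.na(tissue_mult)] <- 1
  names(tissue_mult) <- tissues

  tables <- stats::setNames(vector("list", length(tissues)), tissues)
  for (ts in tissues) {
    smp <- cohort$samples[cohort$samples$tissue == ts, , drop = FALSE]
    n_s <- nrow(smp)
    sp_idx <- match(smp$species_id, species$species_id)
    set.seed(derive_seed(seed, "lipidome", ts))
    mu_ts <- mu_peak + stats::rnorm(n_peaks, 0, 0.5)
    # species random effect: one draw per (species, peak)
    u <- matrix(stats::rnorm(nrow(species) * n_peaks, 0, config$sigma_species),
                nrow(species), n_peaks)
    log_conc <- matrix(mu_ts, n_s, n_peaks, byrow = TRUE) + u[sp_idx, ] +
      matrix(stats::rnorm(n_s * n_peaks, 0, config$noise_sd), n_s, n_peaks)
    # duplicated split-peaks of one compound share the concentration
    # profile up to small measurement noise (so the merge stage sees them
    # as correlated)
    if (config$n_duplicate_pairs > 0L)
      log_conc[, dup_dst] <- log_conc[, dup_src] +
        matrix(stats::rnorm(n_s * length(dup_dst), 0, 0.05),
               n_s, length(dup_dst))
    # planted long-living shift, clade-shared sign
    shift <- sign_p * config$effect_size * tissue_mult[[ts]] * sd_total
    is_long <- long_living[smp$species_id]
    log_conc[, seq_len(config$n_predictors)] <-
      log_conc[, seq_len(config$n_predictors)] +
      outer(as.numeric(is_long), shift)
    # confounder terms
    for (j in seq_along(confounded_map)) {
      fac <- confounded_map[[j]]
      zval <- switch(fac,
        sex = ifelse(smp$sex == "M", 0.5, -0.5),
        age = {
          s <- stats::sd(smp$age)
          (smp$age - mean(smp$age)) / ifelse(s > 0, s, 1)
        },
        conf_z[[fac]][smp$species_id])
      log_conc[, confounded_idx[j]] <- log_conc[, confounded_idx[j]] +
        config$confounder_effect * sd_total * zval
    }
    intens <- exp(log_conc) * smp$is_level
    det <- matrix(stats::runif(n_s * n_peaks) >= config$missing_rate,
                  n_s, n_peaks)
    # append the internal-standard peak, detected everywhere
    intens <- cbind(intens, smp$is_level)
    det <- cbind(det, TRUE)
    meta <- rbind(base_meta, data.frame(
      peak_id = "IS_PC34_0", mz = config$is_mz, rt = 10.0, mode = "pos",
      compound_id = NA, lipid_class = NA, sub_class = NA, pathway = NA,
      n_double_bonds = NA, stringsAsFactors = FALSE))
    dimnames(intens) <- list(smp$sample_id, meta$peak_id)
    dimnames(det) <- dimnames(intens)
    intens[!det] <- NA_real_  # undetected measurements carry no intensity
    tables[[ts]] <- peak_table(intens, det, meta, tissue = ts,
                               log_scale = FALSE)
  }

  truth <- list(
    predictor_peaks = predictor_peaks,
    predictor_signs = stats::setNames(sign_p, predictor_peaks),
    predictor_compounds = unique(stats::na.omit(
      base_meta$compound_id[match(predictor_peaks, base_meta$peak_id)])),
    confounded_peaks = confounded_map,
    effect_size = config$effect_size,
    tissue_effect_mult = tissue_mult,
    long_living_species = names(long_living)[long_living]
  )
  list(tables = tables, reference = reference, is_peak = "IS_PC34_0",
       truth = truth)
}

#' Generate a synthetic enzyme evolution table
#'
#' Links enzymes to compounds of the lipid reference and draws per-branch
#' dN/dS values. A planted subset of enzymes draws its links preferentially
#' from predictor compounds; the long-living-branch dN/dS of enzymes whose
#' links are predictor-enriched is scaled down by `enzyme_effect`, while the
#' short-living branch is left unshifted. Term annotations (a flat stand-in
#' for GO terms) are attached per enzyme, with planted enzymes concentrated
#' in a handful of terms so that term enrichment has structure to find.
#'
#' @param truth `truth` element of [generate_lipidome()] (needs
#'   `predictor_compounds`).
#' @param reference lipid reference (needs `compounds`).
#' @param n_enzymes number of enzymes (default 908).
#' @param mean_links mean links per enzyme (Poisson, min 1).
#' @param enzyme_effect multiplicative dN/dS reduction on the long-living
#'   branch for predictor-enriched enzymes, in `[0, 1)`.
#' @param planted_fraction fraction of enzymes drawing links preferentially
#'   from predictor compounds.
#' @param n_terms number of annotation terms.
#' @param seed integer seed.
#' @return data.frame of class `enzyme_table` with columns `enzyme_id`,
#'   `linked_lipids` (semicolon-separated compound ids), `dnds_long`,
#'   `dnds_short`, `terms` (semicolon-separated); attribute `planted`
#'   holds the planted enzyme ids.
#' @export
generate_enzyme_tables <- function(truth, reference, n_enzymes = 908L,
                                   mean_links = 6, enzyme_effect = 0.5,
                                   planted_fraction = 0.1, n_terms = 30L,
                                   seed = 1L) {
  if (n_enzymes < 1L) stop("n_enzymes must be >= 1")
  set.seed(derive_seed(seed, "enzymes"))
  cmp <- reference$compounds$compound_id
  pred_cmp <- intersect(truth$predictor_compounds, cmp)
  n_planted <- max(1L, round(n_enzymes * planted_fraction))
  planted <- seq_len(n_planted)

  links <- lapply(seq_len(n_enzymes), function(i) {
    k <- max(1L, stats::rpois(1, mean_links))
    if (i %in% planted && length(pred_cmp) > 0) {
      k_pred <- max(1L, stats::rbinom(1, k, 0.7))
      unique(c(sample(pred_cmp, min(k_pred, length(pred_cmp))),
               sample(cmp, max(0L, k - k_pred))))
    } else {
      sample(cmp, min(k, length(cmp)))
    }
  })
  prop <- vapply(links, function(l)
    length(intersect(l, pred_cmp)) / length(l), numeric(1))
  enriched <- prop >= 0.5

  base_long <- stats::rgamma(n_enzymes, shape = 2, rate = 10)
  base_short <- stats::rgamma(n_enzymes, shape = 2, rate = 10)
  dnds_long <- base_long * ifelse(enriched, 1 - enzyme_effect, 1)

  terms <- sprintf("term_%02d", seq_len(n_terms))
  hot <- terms[seq_len(max(2L, n_terms %/% 6L))]
  term_list <- lapply(seq_len(n_enzymes), function(i) {
    k <- sample(1:3, 1)
    if (i %in% planted) unique(c(sample(hot, 1), sample(terms, k)))
    else sample(terms, k)
  })

  out <- data.frame(
    enzyme_id = sprintf("enz_%04d", seq_len(n_enzymes)),
    linked_lipids = vapply(links, paste, character(1), collapse = ";"),
    dnds_long = dnds_long,
    dnds_short = base_short,
    terms = vapply(term_list, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  attr(out, "planted") <- out$enzyme_id[planted]
  class(out) <- c("enzyme_table", "data.frame")
  out
}
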