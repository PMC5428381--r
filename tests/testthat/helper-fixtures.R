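# In-code fixtures shared across test files.

# peak table from a plain matrix; metadata defaults are inert
make_table <- function(values, mz = NULL, rt = NULL, mode = "pos",
                       detected = NULL, tissue = "liver", log_scale = TRUE,
                       sample_ids = NULL, peak_ids = NULL) {
  values <- as.matrix(values)
  n <- nrow(values); p <- ncol(values)
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(n))
  if (is.null(peak_ids)) peak_ids <- sprintf("p%02d", seq_len(p))
  dimnames(values) <- list(sample_ids, peak_ids)
  if (is.null(detected)) detected <- !is.na(values)
  dimnames(detected) <- dimnames(values)
  meta <- data.frame(peak_id = peak_ids,
                     mz = if (is.null(mz)) seq(400, 500, length.out = p) else mz,
                     rt = if (is.null(rt)) seq(1, 2, length.out = p) else rt,
                     mode = rep_len(mode, p),
                     stringsAsFactors = FALSE)
  peak_table(values, detected, meta, tissue = tissue, log_scale = log_scale)
}

# minimal two-clade cohort for unit tests: n_sp species per clade, one
# individual per species, a single tissue
mini_cohort <- function(n_sp = 4L, mls = NULL, tissue = "liver") {
  clades <- rep(c("rodent", "primate"), each = n_sp)
  ids <- sprintf("%s_%02d", clades, rep(seq_len(n_sp), 2))
  if (is.null(mls)) mls <- c(seq(4, 10, length.out = n_sp),
                             seq(15, 60, length.out = n_sp))
  species <- data.frame(
    species_id = ids, clade = clades, mls = mls,
    bmr = seq_along(ids), body_mass = 10 * seq_along(ids),
    body_temp = 36 + seq_along(ids) / 10,
    diet = rep(c("herbivore", "omnivore"), length.out = length(ids)),
    hibernates = rep(c(TRUE, FALSE), length.out = length(ids)),
    stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = paste0(ids, "_", tissue),
    individual_id = paste0(ids, "_i1"),
    species_id = ids, tissue = tissue,
    sex = rep(c("M", "F"), length.out = length(ids)),
    age = 0.5 * mls, is_level = 100,
    stringsAsFactors = FALSE)
  list(species = species, samples = samples)
}

# all permutations of seq_len(n) (small n only), for enumeration oracles
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_perms(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# the shared default benchmark for the expensive acceptance checks,
# computed once per test run
benchmark_env <- new.env()
default_benchmark <- function() {
  if (!is.null(benchmark_env$bm)) return(benchmark_env$bm)
  cohort <- generate_cohort(seed = derive_seed(1L, "stage-sim"))
  sim <- generate_lipidome(cohort, n_peaks = 350L,
                           seed = derive_seed(1L, "stage-sim"))
  benchmark_env$bm <- list(cohort = cohort, sim = sim)
  benchmark_env$bm
}
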