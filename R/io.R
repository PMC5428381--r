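write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write a peak table to TSV files
#'
#' Emits `<prefix>_intensities.tsv` (samples x peaks; undetected entries
#' are `NA`) and `<prefix>_peaks.tsv` (peak metadata: peak_id, mz, rt_min,
#' mode, and any annotation columns).
#'
#' @param table a [peak_table()].
#' @param prefix file path prefix.
#' @return the two file paths, invisibly.
#' @export
write_peak_table <- function(table, prefix) {
  ip <- paste0(prefix, "_intensities.tsv")
  mp <- paste0(prefix, "_peaks.tsv")
  df <- data.frame(sample_id = rownames(table$intensities),
                   table$intensities, check.names = FALSE)
  write_tsv(df, ip)
  meta <- table$peak_meta
  names(meta)[names(meta) == "rt"] <- "rt_min"
  write_tsv(meta, mp)
  invisible(c(ip, mp))
}

#' Read a peak table written by [write_peak_table()]
#'
#' @param prefix file path prefix.
#' @param tissue,log_scale table attributes to restore.
#' @return a [peak_table()]; detection is inferred from `NA` entries.
#' @export
read_peak_table <- function(prefix, tissue = NA_character_,
                            log_scale = FALSE) {
  df <- read_tsv(paste0(prefix, "_intensities.tsv"))
  meta <- read_tsv(paste0(prefix, "_peaks.tsv"))
  names(meta)[names(meta) == "rt_min"] <- "rt"
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  peak_table(m, !is.na(m), meta, tissue = tissue, log_scale = log_scale)
}

#' Write cohort metadata to TSV
#' @param cohort cohort list.
#' @param prefix file path prefix.
#' @export
write_cohort <- function(cohort, prefix) {
  write_tsv(cohort$species, paste0(prefix, "_species.tsv"))
  write_tsv(cohort$samples, paste0(prefix, "_samples.tsv"))
  invisible(prefix)
}

#' Read cohort metadata written by [write_cohort()]
#' @param prefix file path prefix.
#' @return cohort list with `species` and `samples`.
#' @export
read_cohort <- function(prefix) {
  list(species = read_tsv(paste0(prefix, "_species.tsv")),
       samples = read_tsv(paste0(prefix, "_samples.tsv")))
}

#' Write a lipid reference as a single TSV
#'
#' One row per compound; the class's allowed adducts are serialized as a
#' semicolon-separated `name:mass_shift:mode` list.
#'
#' @param reference list with `compounds` and `adducts`.
#' @param path output file.
#' @export
write_lipid_reference <- function(reference, path) {
  ad_by_class <- split(reference$adducts, reference$adducts$lipid_class)
  ad_str <- vapply(reference$compounds$lipid_class, function(cl) {
    a <- ad_by_class[[cl]]
    paste(sprintf("%s:%.6f:%s", a$name, a$mass_shift, a$mode),
          collapse = ";")
  }, character(1))
  df <- reference$compounds
  df$adducts <- ad_str
  write_tsv(df, path)
  invisible(path)
}

#' Read a lipid reference written by [write_lipid_reference()]
#' @param path input file.
#' @return list with `compounds` and `adducts` (primary flag restored from
#'   the adduct name: `+H` and `-H` are primary).
#' @export
read_lipid_reference <- function(path) {
  df <- read_tsv(path)
  pieces <- lapply(unique(df$lipid_class), function(cl) {
    s <- df$adducts[match(cl, df$lipid_class)]
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(lipid_class = cl,
               name = vapply(parts, `[`, character(1), 1),
               mass_shift = as.numeric(vapply(parts, `[`, character(1), 2)),
               mode = vapply(parts, `[`, character(1), 3),
               stringsAsFactors = FALSE)
  })
  adducts <- do.call(rbind, pieces)
  adducts$primary <- adducts$name %in% c("+H", "-H")
  df$adducts <- NULL
  list(compounds = df, adducts = adducts)
}

#' Write a full simulation to a directory
#'
#' Peak tables, cohort, lipid reference and a JSON sidecar holding the
#' seed and ground truth.
#'
#' @param sim output of [generate_lipidome()].
#' @param cohort cohort list.
#' @param dir output directory (created if missing).
#' @param seed the generator seed, recorded in the sidecar.
#' @export
write_simulation <- function(sim, cohort, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, file.path(dir, "cohort"))
  for (ts in names(sim$tables))
    write_peak_table(sim$tables[[ts]], file.path(dir, ts))
  write_lipid_reference(sim$reference, file.path(dir, "lipid_reference.tsv"))
  sidecar <- list(seed = seed, is_peak = sim$is_peak, truth = sim$truth)
  jsonlite::write_json(sidecar, file.path(dir, "simulation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
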