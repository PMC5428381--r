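#' Parse an enzyme table's semicolon-separated list columns
#' @param table `enzyme_table` data frame.
#' @return list with `links` and `terms`, each a named list of character
#'   vectors per enzyme.
#' @export
enzyme_links <- function(table) {
  list(links = stats::setNames(strsplit(table$linked_lipids, ";", fixed = TRUE),
                               table$enzyme_id),
       terms = stats::setNames(strsplit(table$terms, ";", fixed = TRUE),
                               table$enzyme_id))
}

#' Select lifespan-related enzymes by predictor-link proportion
#'
#' For each enzyme, the proportion of its linked lipid compounds that are
#' MLS predictors is computed; enzymes at or above the `1 - q` quantile of
#' these proportions are selected (ties at the threshold included). The
#' default quantile fraction is 0.30, with 0.25 in heart and 0.35 in
#' non-neural tissues.
#'
#' @param table `enzyme_table` data frame.
#' @param predictor_compounds compound ids of the MLS predictors.
#' @param q top fraction to select (default [enzyme_quantile()] of the
#'   tissue).
#' @return list: `selected` enzyme ids, `proportions` (named), `threshold`.
#' @export
select_lifespan_enzymes <- function(table, predictor_compounds, q = 0.30) {
  if (nrow(table) == 0L) stop("empty enzyme link table")
  links <- enzyme_links(table)$links
  prop <- vapply(links, function(l)
    length(intersect(l, predictor_compounds)) / length(l), numeric(1))
  thr <- stats::quantile(prop, 1 - q, names = FALSE, type = 7)
  list(selected = table$enzyme_id[prop >= thr],
       proportions = prop, threshold = thr)
}

#' Tissue-specific top fraction for enzyme selection
#'
#' @param tissue tissue name.
#' @return 0.25 for heart, 0.35 for non-neural tissues (liver, muscle,
#'   kidney), 0.30 otherwise (brain tissues and default).
#' @export
enzyme_quantile <- function(tissue) {
  if (tissue == "heart") return(0.25)
  if (tissue %in% tissue_groups()$nonneural) return(0.35)
  0.30
}

#' Compare dN/dS between selected and background enzymes
#'
#' One-sided Wilcoxon rank-sum test of the hypothesis that the selected
#' (lifespan-related) enzymes have lower dN/dS than the background enzymes
#' on the chosen branch; the background excludes the selected set.
#'
#' @param table `enzyme_table` data frame.
#' @param selected selected enzyme ids.
#' @param branch `"long"` or `"short"` (which branch's dN/dS to compare).
#' @return list: `p`, `effect` (median difference selected - background),
#'   `stars` (significance marks at 0.05 / 0.01 / 0.001), `n_selected`,
#'   `n_background`.
#' @export
compare_dnds <- function(table, selected, branch = c("long", "short")) {
  branch <- match.arg(branch)
  col <- paste0("dnds_", branch)
  sel <- table$enzyme_id %in% selected
  if (!any(sel) || all(sel)) stop("both enzyme sets must be nonempty")
  x <- table[[col]][sel]
  y <- table[[col]][!sel]
  wt <- stats::wilcox.test(x, y, alternative = "less", exact = FALSE)
  p <- wt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else ""
  list(p = p, effect = stats::median(x) - stats::median(y), stars = stars,
       n_selected = sum(sel), n_background = sum(!sel))
}

#' Term-enrichment network of lifespan-related enzymes
#'
#' Tests each annotation term for hypergeometric enrichment of the given
#' enzyme set against all enzymes in the table, then connects significant
#' terms by edges weighted with the number of shared enzymes (restricted to
#' the enzyme set).
#'
#' @param table `enzyme_table` data frame.
#' @param enzymes enzyme ids with lower-dN/dS evidence.
#' @param alpha term significance level (default 0.05).
#' @return list with `terms` (data.frame: `term`, `overlap`, `term_size`,
#'   `p`, `significant`) and `edges` (data.frame: `term_a`, `term_b`,
#'   `weight`), plus `graph` (igraph object over significant terms).
#' @export
term_enrichment_network <- function(table, enzymes, alpha = 0.05) {
  ann <- enzyme_links(table)$terms
  if (all(lengths(ann) == 0L)) stop("no term annotations")
  term_members <- split(
    rep(names(ann), lengths(ann)), unlist(ann))
  n_all <- nrow(table)
  sel <- intersect(enzymes, table$enzyme_id)
  res <- do.call(rbind, lapply(names(term_members), function(tm) {
    mem <- term_members[[tm]]
    ov <- length(intersect(mem, sel))
    data.frame(term = tm, overlap = ov, term_size = length(mem),
               p = hyper_p(ov, length(mem), n_all, length(sel)),
               stringsAsFactors = FALSE)
  }))
  res$significant <- res$p < alpha
  sig <- res$term[res$significant]
  edges <- list()
  if (length(sig) > 1L) {
    for (i in seq_along(sig)[-length(sig)]) {
      for (j in seq((i + 1L), length(sig))) {
        shared <- length(intersect(
          intersect(term_members[[sig[i]]], sel),
          intersect(term_members[[sig[j]]], sel)))
        if (shared > 0L)
          edges[[length(edges) + 1L]] <- data.frame(
            term_a = sig[i], term_b = sig[j], weight = shared,
            stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(term_a = character(), term_b = character(),
               weight = integer(), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = sig))
  list(terms = res, edges = edges, graph = g)
}
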