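#' Derive a stream-specific random seed
#'
#' Splits a master seed into reproducible sub-seeds so that each pipeline
#' stage (and each replicate within a stage) consumes an independent,
#' individually re-runnable random stream.
#'
#' @param seed master integer seed.
#' @param ... integers or strings identifying the stream (stage name,
#'   replicate index, ...).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p))
    h <- (h * 69069 + as.double(p) + 1) %% 2147483647
  }
  as.integer(h)
}

#' Area under the ROC curve via rank concordance
#'
#' Computes the AUC as the Mann-Whitney concordance probability: the
#' fraction of (positive, negative) pairs in which the positive sample
#' receives the higher score, ties counting one half.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (logical, or coercible to 0/1).
#' @return AUC in `[0, 1]`; `NA` if either class is absent.
#' @export
auc_score <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified cross-validation folds
#'
#' @param labels binary labels.
#' @param k number of folds.
#' @return integer fold assignment per observation; each class is spread
#'   across folds as evenly as possible.
#' @keywords internal
stratified_folds <- function(labels, k) {
  y <- as.logical(labels)
  folds <- integer(length(y))
  for (cls in c(TRUE, FALSE)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Column-standardize a matrix
#'
#' Centers and scales columns to mean 0, sd 1; constant columns are centered
#' only (scale left at 1) so they cannot produce NaNs in penalized fits.
#' @keywords internal
standardize_columns <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
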