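#' @title Model evaluation metrics
#' @name metrics
#' @description AUC (Mann-Whitney formulation) and the maximized True Skill
#'   Statistic, as used to gate base models and score ensembles.
NULL

check_two_classes <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (sum(labels == 1) < 1 || sum(labels == 0) < 1) {
    stop("both a positive and a negative example are required")
  }
  labels
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) pairs with
#' `score_pos > score_neg`, ties counted one half. Computed from midranks,
#' so it is exact for any tie structure.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector (1 = presence).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- check_two_classes(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores)                  # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Maximized True Skill Statistic
#'
#' `TSS(theta) = sensitivity + specificity - 1` with prediction positive iff
#' `score >= theta`. All midpoints between adjacent distinct scores plus
#' `-Inf`/`+Inf` sentinels are scanned; on ties the smallest threshold is
#' returned.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector (1 = presence).
#' @return list with `threshold` and `tss`.
#' @export
max_tss <- function(scores, labels) {
  labels <- check_two_classes(labels)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  # counts of scores >= theta, per class, via sorted positions
  tss <- vapply(cand, function(th) {
    tp <- sum(scores >= th & labels == 1)
    fp <- sum(scores >= th & labels == 0)
    tp / n_pos + (n_neg - fp) / n_neg - 1
  }, numeric(1))
  # smallest threshold among ties (tolerance absorbs float rounding of
  # mathematically equal sensitivity/specificity sums)
  best <- which(tss >= max(tss) - 1e-12)[1]
  list(threshold = cand[best], tss = tss[best])
}
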