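# Evaluation metrics: ROC AUC (rank statistic) and Harrell's concordance
# index with the 0.5 tie convention for tied risks.

#' Area under the ROC curve
#'
#' Rank-based (Wilcoxon) AUC of a score against binary labels; tied scores
#' contribute 0.5.
#'
#' @param labels binary vector (0/1, logical, or a two-level factor whose
#'   second level is the positive class).
#' @param scores numeric scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
aucScore <- function(labels, scores) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("need both classes to compute AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Concordance index for survival risk scores
#'
#' Fraction of comparable pairs ordered correctly by the risk score. A pair
#' (i, j) is comparable when patient i has an observed event and
#' `time_i < time_j`; it counts 1 when `risk_i > risk_j`, 0.5 when the risks
#' are tied.
#'
#' @param risks numeric risk scores (higher = worse prognosis).
#' @param time follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @return C-index in `[0, 1]`.
#' @export
concordanceIndex <- function(risks, time, event) {
  stopifnot(length(risks) == length(time), length(time) == length(event))
  if (!all(event %in% c(0, 1))) stop("event must be 0 or 1")
  n <- length(risks)
  conc <- 0
  comp <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    j <- which(time > time[i])
    if (!length(j)) next
    comp <- comp + length(j)
    conc <- conc + sum(risks[i] > risks[j]) + 0.5 * sum(risks[i] == risks[j])
  }
  if (comp == 0) stop("no comparable pairs")
  conc / comp
}
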