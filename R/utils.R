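#' Area under the ROC curve for a two-group score comparison
#'
#' Rank-based AUC via the Mann-Whitney statistic: the probability that a
#' randomly chosen positive scores higher than a randomly chosen negative
#' (ties count half).
#'
#' @param scores_pos,scores_neg Numeric score vectors for the positive and
#'   negative group.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
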