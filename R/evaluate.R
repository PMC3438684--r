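# Validation metrics: confusion summaries, Mann-Whitney AUC, DeLong CI,
# and model-composition-by-rank curves.  The positive class is phenotype
# value 2 throughout.

#' Confusion-matrix summary
#'
#' @param predicted,truth vectors of classes in `{1, 2}`; class 2 is
#'   positive.
#' @return One-row tibble: `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, `accuracy`, `mean_sens_spec` (the linear transform
#'   `(J + 1) / 2` of Youden's J).
#' @export
#' @examples
#' confusion_metrics(c(2, 1, 2, 1), c(2, 1, 1, 1))
confusion_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must have the same length")
  }
  tp <- sum(predicted == 2 & truth == 2)
  fp <- sum(predicted == 2 & truth == 1)
  tn <- sum(predicted == 1 & truth == 1)
  fn <- sum(predicted == 1 & truth == 2)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 accuracy = (tp + tn) / length(truth),
                 mean_sens_spec = (sens + spec) / 2)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `AUC = (concordant pairs + 0.5 tied pairs) / (cases x controls)`,
#' computed from average ranks.
#'
#' @param scores numeric prediction scores (higher = more case-like).
#' @param labels classes in `{1, 2}`, 2 = case.
#' @return The AUC.
#' @export
auc_mann_whitney <- function(scores, labels) {
  case <- labels == 2
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong confidence interval for the AUC
#'
#' Normal-approximation interval using the DeLong variance estimate from
#' case and control placement values, truncated to `[0, 1]`.
#'
#' @inheritParams auc_mann_whitney
#' @param level confidence level.
#' @return Tibble with `auc`, `lower`, `upper`, `se`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  case <- labels == 2
  x <- scores[case]; y <- scores[!case]
  m <- length(x); n <- length(y)
  if (m < 2L || n < 2L) stop("need at least 2 cases and 2 controls")
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), 0)  # case placements
  v01 <- vapply(y, function(yj) mean(psi(x, yj)), 0)  # control placements
  auc <- mean(v10)
  se <- sqrt(var(v10) / m + var(v01) / n)
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(auc = auc,
                 lower = max(0, auc - z * se),
                 upper = min(1, auc + z * se),
                 se = se)
}

#' Model composition of the nested SNP sets
#'
#' For each rank cutoff `r`, the fractions of the nested set `Sigma_r` that
#' are causal and correctly modeled (split by causal type), causal but
#' assigned the wrong model, and non-causal; plus the per-rank causal
#' indicator (the color-bar statistic).
#'
#' @param ranking ranked assignment tibble (from `tidy()` of a
#'   [pleio_scan()]), with `snp_id` and `model` columns in rank order.
#' @param truth tibble with `snp_id` and `target` in
#'   `{"both", "Da", "Db", "none"}`; every ranked SNP must appear.
#' @return Tibble with one row per rank `r`: fractions
#'   `pleio_correct`, `da_correct`, `db_correct`, `mismodeled`,
#'   `non_causal` (summing to 1), and `causal_at_rank`.
#' @export
composition_by_rank <- function(ranking, truth) {
  stopifnot(all(c("snp_id", "model") %in% names(ranking)),
            all(c("snp_id", "target") %in% names(truth)))
  tgt <- truth$target[match(ranking$snp_id, truth$snp_id)]
  if (anyNA(tgt)) {
    stop("truth table is missing ranked SNP(s): ",
         paste(head(ranking$snp_id[is.na(tgt)], 3L), collapse = ", "))
  }
  correct_model <- unname(c(both = "Mab", Da = "Ma", Db = "Mb",
                            none = "")[tgt])
  ok <- ranking$model == correct_model
  causal <- tgt != "none"
  r <- seq_len(nrow(ranking))
  tibble::tibble(
    r = r,
    pleio_correct = cumsum(ok & tgt == "both") / r,
    da_correct = cumsum(ok & tgt == "Da") / r,
    db_correct = cumsum(ok & tgt == "Db") / r,
    mismodeled = cumsum(causal & !ok) / r,
    non_causal = cumsum(!causal) / r,
    causal_at_rank = causal)
}
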