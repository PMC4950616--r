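#' Evaluate a probabilistic prediction against observed presence/absence
#'
#' Computes the area under the ROC curve as the Mann--Whitney rank statistic:
#' the probability that a randomly chosen presence receives a higher
#' predicted probability than a randomly chosen absence, with ties counted
#' one half. Optionally reports sensitivity (true-positive fraction) and
#' specificity (true-negative fraction) at a threshold, where a cell is
#' predicted present when its probability is greater than or equal to the
#' threshold. An accuracy grade is attached from the conventional bands:
#' 0.90--1.00 excellent, 0.80--0.90 good, 0.70--0.80 fair, 0.60--0.70 poor,
#' 0.50--0.60 fail.
#'
#' @param observed integer/logical vector of 0/1 observations.
#' @param probabilities numeric vector of predicted probabilities.
#' @param threshold optional cut-off for sensitivity/specificity.
#' @return list with `auc`, `grade`, and (when `threshold` is given)
#'   `sensitivity`, `specificity`, `threshold`. With a single observed class
#'   the AUC is undefined: `auc` is `NA` and `degenerate` is `TRUE`.
#' @export
#' @examples
#' evaluate_roc(c(1, 0, 1, 0), c(0.9, 0.8, 0.3, 0.4))$auc  # 0.75
evaluate_roc <- function(observed, probabilities, threshold = NULL) {
  obs <- as.integer(observed)
  if (length(obs) != length(probabilities))
    stop_config("observed and probabilities differ in length")
  if (!all(obs %in% c(0L, 1L)))
    stop_config("observed must be 0/1")
  n1 <- sum(obs == 1L); n0 <- sum(obs == 0L)
  out <- list(auc = NA_real_, grade = NA_character_, degenerate = FALSE)
  if (n1 == 0L || n0 == 0L) {
    out$degenerate <- TRUE
  } else {
    r <- rank(probabilities)           # midranks: ties count 1/2
    out$auc <- (sum(r[obs == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    out$grade <- auc_grade(out$auc)
  }
  if (!is.null(threshold)) {
    pred <- probabilities >= threshold
    out$threshold <- threshold
    out$sensitivity <- if (n1 > 0) sum(pred & obs == 1L) / n1 else NA_real_
    out$specificity <- if (n0 > 0) sum(!pred & obs == 0L) / n0 else NA_real_
  }
  out
}

# Accuracy grade bands for an AUC value.
auc_grade <- function(auc) {
  if (is.na(auc)) return(NA_character_)
  if (auc >= 0.9) "excellent"
  else if (auc >= 0.8) "good"
  else if (auc >= 0.7) "fair"
  else if (auc >= 0.6) "poor"
  else "fail"
}

# Confidence band label for an agreement percentage (<=50 poor,
# 50-75 medium, >75 high).
agreement_band <- function(pct) {
  ifelse(is.na(pct), NA_character_,
         ifelse(pct <= 50, "poor", ifelse(pct <= 75, "medium", "high")))
}
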