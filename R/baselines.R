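# Classical comparison baselines: thin wrappers over established
# implementations, evaluated on the same preprocessed matrices as the
# network.

#' Multinomial logistic-regression baseline
#'
#' Fits \code{nnet::multinom} on the ordered, normalized training matrix
#' and scores the test cohort; the standard linear reference point for the
#' capacity-separation comparisons.
#'
#' @param train_cohort,test_cohort preprocessed labeled cohorts.
#' @return list with \code{accuracy}, predicted labels, and the fitted
#'   probability matrix on the test split.
#' @export
baseline_logistic <- function(train_cohort, test_cohort) {
  tr <- as_model_matrix(train_cohort)
  te <- as_model_matrix(test_cohort)
  if (is.null(tr$y)) stop("training cohort has no labels")
  df_tr <- data.frame(tr$X, y = factor(tr$y))
  fit <- nnet::multinom(y ~ ., df_tr, trace = FALSE)
  pr <- stats::predict(fit, data.frame(te$X), type = "probs")
  if (is.null(dim(pr))) pr <- rbind(pr)
  pred <- max.col(pr)
  list(accuracy = if (is.null(te$y)) NA_real_ else mean(pred == te$y),
       predicted = factor(.risk_levels[pred], levels = .risk_levels),
       prob = pr)
}
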