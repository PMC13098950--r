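# Entropy-based feature engineering: quantile discretization, marginal
# Shannon entropy with stable/uncertain marking, and conditional entropy
# H(Y|X) screening against the risk label.

#' Quantile-discretize a vector
#'
#' Continuous values are cut at empirical quantiles into at most \code{k}
#' bins (duplicate quantiles collapse, so skewed data never produce empty
#' bins); integer- or factor-valued input with no more than \code{k}
#' distinct values is treated as already discrete and passed through
#' unchanged.
#'
#' @param values numeric or factor vector, finite.
#' @param k target bin count (>= 2).
#' @return list with \code{bin_edges} (NULL for pass-through discrete
#'   input), \code{assignment} (integer bin per value) and \code{bin_probs}.
#' @export
discretize <- function(values, k = 10L) {
  if (k < 2L) stop("k must be >= 2")
  if (is.factor(values) || is.character(values))
    values <- as.integer(factor(values))
  if (any(!is.finite(values))) stop("values must be finite")
  ux <- sort(unique(values))
  if (length(ux) == 1L) {
    warning("all values identical: single bin")
    return(list(bin_edges = c(ux, ux), assignment = rep(1L, length(values)),
                bin_probs = 1))
  }
  if (length(ux) <= k) {
    assignment <- match(values, ux)
    probs <- as.numeric(table(factor(assignment, levels = seq_along(ux))))
    return(list(bin_edges = NULL, assignment = assignment,
                bin_probs = probs / length(values)))
  }
  edges <- unique(stats::quantile(values, probs = seq(0, 1, length.out = k + 1),
                                  names = FALSE, type = 7))
  assignment <- findInterval(values, edges, rightmost.closed = TRUE,
                             all.inside = TRUE)
  nb <- length(edges) - 1L
  probs <- as.numeric(table(factor(assignment, levels = seq_len(nb))))
  list(bin_edges = edges, assignment = assignment,
       bin_probs = probs / length(values))
}

#' Marginal Shannon entropy of a probability vector
#'
#' H = -sum p log2 p with 0 log 0 = 0, in bits.
#'
#' @param bin_probs nonnegative probabilities summing to 1.
#' @return entropy in bits, between 0 and log2(length(bin_probs)).
#' @export
marginal_entropy <- function(bin_probs) {
  if (any(bin_probs < 0)) stop("negative probability")
  if (abs(sum(bin_probs) - 1) > 1e-6) stop("probabilities must sum to 1")
  p <- bin_probs[bin_probs > 0]
  -sum(p * log2(p))
}

#' Conditional entropy H(Y | X) in bits
#'
#' Expected residual label uncertainty given the discretized feature:
#' H(Y|X) = sum_v p(v) H(Y | X = v). Never exceeds H(Y); equals H(Y) for
#' an uninformative (single-bin or independent) feature and 0 when X
#' determines Y.
#'
#' @param feature_bins discrete assignment vector (any discrete values).
#' @param labels class vector of equal length.
#' @return conditional entropy in bits.
#' @export
conditional_entropy <- function(feature_bins, labels) {
  if (length(feature_bins) != length(labels))
    stop("length mismatch between feature bins and labels")
  n <- length(labels)
  h <- 0
  for (v in unique(feature_bins)) {
    sel <- feature_bins == v
    pv <- sum(sel) / n
    py <- table(labels[sel]) / sum(sel)
    py <- py[py > 0]
    h <- h + pv * (-sum(py * log2(py)))
  }
  as.numeric(h)
}

#' Mark features stable or uncertain by marginal entropy
#'
#' A feature is marked stable when its marginal entropy is strictly below
#' the threshold, uncertain otherwise. Marks are reported metadata; they
#' do not remove features unless explicitly filtered downstream.
#'
#' @param entropies named numeric vector of marginal entropies (bits).
#' @param threshold positive threshold in bits; default 0.9 * log2(k) for
#'   k = 10 quantile bins.
#' @return data frame with feature, marginal_entropy and mark.
#' @export
mark_features <- function(entropies, threshold = 0.9 * log2(10)) {
  if (threshold <= 0) stop("threshold must be positive")
  data.frame(feature = names(entropies),
             marginal_entropy = as.numeric(entropies),
             mark = ifelse(entropies < threshold, "stable", "uncertain"),
             stringsAsFactors = FALSE)
}

#' Entropy-based uncertainty scores per feature
#'
#' The score of a feature is its conditional entropy H(Y|X) against the
#' risk label after quantile discretization; lower scores indicate higher
#' predictive power. Ranking the scores ascending reproduces the
#' screening ordering.
#'
#' @param cohort labeled \code{cohort}.
#' @param k quantile bin count for continuous features.
#' @return named numeric vector of scores (bits), in feature order.
#' @export
uncertainty_scores <- function(cohort, k = 10L) {
  d <- cohort$data
  if (!.label_col %in% names(d)) stop("cohort has no risk labels")
  y <- d[[.label_col]]
  out <- vapply(cohort$feature_order, function(cl) {
    v <- d[[cl]]
    if (is.character(v)) v <- as.integer(factor(v))
    conditional_entropy(discretize(v, k)$assignment, y)
  }, numeric(1))
  out
}

#' Full entropy report for a cohort
#'
#' Per feature: marginal entropy of the discretized distribution, the
#' stable/uncertain mark, and the conditional entropy against the risk
#' label. Computed on the cohort it is given -- screen on the training
#' split only.
#'
#' @param cohort labeled \code{cohort}.
#' @param k quantile bin count.
#' @param threshold stable/uncertain threshold in bits.
#' @return data frame (one row per feature, in feature order) with
#'   feature, marginal_entropy, conditional_entropy, mark.
#' @export
entropy_report <- function(cohort, k = 10L, threshold = 0.9 * log2(k)) {
  d <- cohort$data
  marg <- vapply(cohort$feature_order, function(cl) {
    v <- d[[cl]]
    if (is.character(v)) v <- as.integer(factor(v))
    marginal_entropy(discretize(v, k)$bin_probs)
  }, numeric(1))
  rep <- mark_features(marg, threshold)
  rep$conditional_entropy <- unname(uncertainty_scores(cohort, k))
  rep[, c("feature", "marginal_entropy", "conditional_entropy", "mark")]
}
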