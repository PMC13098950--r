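# Performance metrics, calibration and uncertainty diagnostics.

#' Classification metrics from predicted and true labels
#'
#' Accuracy, per-class precision/recall/F1 computed from the confusion
#' matrix, and their macro averages. A class absent from the truth has
#' undefined recall, reported as 0 and flagged.
#'
#' @param y_true true labels (factor or character over the risk levels).
#' @param y_pred predicted labels, same length.
#' @param levels class levels; defaults to the union of observed labels in
#'   Low/Medium/High order where applicable.
#' @return list with accuracy, per-class data frame, macro precision /
#'   recall / f1 and the confusion matrix (rows = truth).
#' @export
compute_metrics <- function(y_true, y_pred, levels = NULL) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (is.null(levels)) {
    obs <- unique(c(as.character(y_true), as.character(y_pred)))
    levels <- if (all(obs %in% .risk_levels))
      intersect(.risk_levels, obs) else sort(obs)
  }
  yt <- factor(as.character(y_true), levels = levels)
  yp <- factor(as.character(y_pred), levels = levels)
  cm <- table(truth = yt, predicted = yp)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  per <- data.frame(class = levels, precision = NA_real_, recall = NA_real_,
                    f1 = NA_real_, flagged = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(levels)) {
    tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    if (sum(cm[k, ]) == 0) {
      rec <- 0
      per$flagged[k] <- TRUE
    } else rec <- tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    per$precision[k] <- prec; per$recall[k] <- rec; per$f1[k] <- f1
  }
  list(accuracy = acc, per_class = per,
       macro_precision = mean(per$precision), macro_recall = mean(per$recall),
       macro_f1 = mean(per$f1), confusion_matrix = cm)
}

#' One-vs-rest reliability curves
#'
#' Bins each class's predicted probability into equal-width bins and
#' reports the mean predicted probability and empirical class frequency
#' per nonempty bin (the reliability-diagram coordinates).
#'
#' @param y_true true labels.
#' @param y_prob n x K probability matrix with rows summing to 1 (columns
#'   named by class or in level order).
#' @param n_bins number of equal-width probability bins (>= 2).
#' @return data frame with class, bin_center, mean_prob, empirical_freq,
#'   count.
#' @export
calibration_curve <- function(y_true, y_prob, n_bins = 10L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  if (any(abs(rowSums(y_prob) - 1) > 1e-6))
    stop("probability rows must sum to 1")
  levs <- colnames(y_prob)
  if (is.null(levs)) {
    levs <- levels(factor(y_true))
    colnames(y_prob) <- levs
  }
  edges <- seq(0, 1, length.out = n_bins + 1)
  out <- list()
  for (cl in levs) {
    p <- y_prob[, cl]
    hit <- as.integer(as.character(y_true) == cl)
    bin <- findInterval(p, edges, rightmost.closed = TRUE, all.inside = TRUE)
    for (b in sort(unique(bin))) {
      sel <- bin == b
      out[[length(out) + 1L]] <- data.frame(
        class = cl, bin_center = (edges[b] + edges[b + 1]) / 2,
        mean_prob = mean(p[sel]), empirical_freq = mean(hit[sel]),
        count = sum(sel), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Predictive entropy, confidence and rolling diagnostics
#'
#' Per-sample Shannon entropy (bits) of the predicted class distribution
#' and confidence (maximum class probability), with centered rolling means
#' over a window; when labels are supplied, also the rolling error rate
#' and the cumulative accuracy sequence.
#'
#' @param y_prob n x K probability matrix.
#' @param window rolling window length (>= 1).
#' @param y_true optional labels for accuracy curves.
#' @return list with per-sample vectors and rolling curves.
#' @export
uncertainty_curves <- function(y_prob, window = 50L, y_true = NULL) {
  if (window < 1L) stop("window must be >= 1")
  pc <- pmax(y_prob, 1e-15)
  entropy <- -rowSums(pc * log2(pc))
  confidence <- apply(y_prob, 1L, max)
  roll <- function(x) {
    n <- length(x)
    w <- min(window, n)
    half <- (w - 1L) %/% 2L
    vapply(seq_len(n), function(i) {
      lo <- max(1L, i - half); hi <- min(n, lo + w - 1L); lo <- max(1L, hi - w + 1L)
      mean(x[lo:hi])
    }, numeric(1))
  }
  out <- list(entropy = entropy, confidence = confidence,
              rolling_entropy = roll(entropy),
              rolling_confidence = roll(confidence))
  if (!is.null(y_true)) {
    levs <- colnames(y_prob)
    pred <- if (is.null(levs)) max.col(y_prob)
            else levs[max.col(y_prob)]
    err <- as.integer(as.character(y_true) != pred)
    out$rolling_error <- roll(err)
    out$cumulative_accuracy <- cumsum(1 - err) / seq_along(err)
  }
  out
}
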