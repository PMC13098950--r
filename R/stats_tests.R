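# The statistical validation battery: one-way ANOVA, Pearson chi-square,
# Wilcoxon signed rank, Friedman, and Diebold-Mariano, each implemented
# from its sum-of-squares / rank definition (the independent reference
# implementations in base R serve as cross-checks in the test suite), plus
# the per-feature significance battery.

stat_result <- function(test, statistic, p_value, df = NA_real_,
                        flag = NULL) {
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 df = df, flag = flag), class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g%s%s\n", x$test, x$statistic,
              x$p_value,
              if (!is.na(x$df[1])) paste0(", df = ",
                                          paste(x$df, collapse = ",")) else "",
              if (!is.null(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

#' One-way analysis of variance
#'
#' F = (SSb / dfb) / (SSw / dfw) from between- and within-group sums of
#' squares; p from the F distribution.
#'
#' @param values numeric response.
#' @param groups group labels, same length; >= 2 groups of >= 2 members.
#' @return \code{stat_test_result} with df = (dfb, dfw).
#' @export
anova_oneway <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 members")
  gm <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in levels(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - gm)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  dfb <- nlevels(groups) - 1L
  dfw <- length(values) - nlevels(groups)
  if (ssw == 0) {
    return(stat_result("anova", Inf, 0, df = c(dfb, dfw),
                       flag = "zero within-group variance"))
  }
  f <- (ssb / dfb) / (ssw / dfw)
  stat_result("anova", f, stats::pf(f, dfb, dfw, lower.tail = FALSE),
              df = c(dfb, dfw))
}

#' Pearson chi-square test of association
#'
#' chi^2 = sum (O - E)^2 / E over the contingency table of two categorical
#' vectors (or a table given directly), df = (r-1)(c-1), no continuity
#' correction.
#'
#' @param x categorical vector or a contingency table/matrix.
#' @param y categorical vector (ignored when \code{x} is a table).
#' @return \code{stat_test_result}.
#' @export
chi_square_test <- function(x, y = NULL) {
  tab <- if (is.matrix(x) || is.table(x)) as.matrix(x)
         else as.matrix(table(x, y))
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  if (any(E == 0)) {
    bad <- which(E == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("expected count 0 in cell (%d, %d)", bad[1], bad[2]))
  }
  stat <- sum((tab - E)^2 / E)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  stat_result("chi2", stat, stats::pchisq(stat, df, lower.tail = FALSE),
              df = df)
}

#' Wilcoxon signed-rank test
#'
#' W = sum sgn(d_i) R_i over the ranks of |d_i| (zero differences dropped,
#' average ranks on ties). Exact p (via the signed-rank distribution) for
#' n <= 25 without ties, normal approximation with tie correction
#' otherwise. Two-sided.
#'
#' @param x,y paired numeric vectors.
#' @return \code{stat_test_result}; the statistic is the signed rank sum
#'   W, with the z-score in \code{$z} when the normal approximation is
#'   used.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must match in length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    res <- stat_result("wilcoxon", 0, 1, flag = "all differences zero")
    res$z <- 0
    return(res)
  }
  r <- rank(abs(d))
  W <- sum(sign(d) * r)
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (n <= 25L && !has_ties) {
    # V = positive-rank sum relates to W by W = 2V - n(n+1)/2
    V <- (W + n * (n + 1) / 2) / 2
    p <- 2 * min(stats::psignrank(V, n), stats::psignrank(V - 1, n,
                                                          lower.tail = FALSE))
    p <- min(1, p)
    res <- stat_result("wilcoxon", W, p, flag = "exact")
    res$z <- NA_real_
    return(res)
  }
  sig2 <- n * (n + 1) * (2 * n + 1) / 6
  if (has_ties) {
    tl <- as.numeric(table(abs(d)))
    sig2 <- sig2 - sum(tl^3 - tl) / 12
  }
  z <- W / sqrt(sig2)
  res <- stat_result("wilcoxon", W, 2 * stats::pnorm(-abs(z)))
  res$z <- z
  res
}

#' Friedman rank test
#'
#' chi^2_F = 12 / (N k (k+1)) sum_j R_j^2 - 3 N (k+1) over the column rank
#' sums R_j of an N-block x k-treatment matrix (average ranks on ties
#' within a block); p from chi-square with k-1 df.
#'
#' @param x N x k matrix of values (ranked within each row) or of ranks.
#' @return \code{stat_test_result}.
#' @export
friedman_rank_test <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x); N <- nrow(x)
  if (k < 2L) stop("need at least 2 treatments")
  R <- t(apply(x, 1L, rank))
  Rj <- colSums(R)
  stat <- 12 / (N * k * (k + 1)) * sum(Rj^2) - 3 * N * (k + 1)
  stat_result("friedman", stat,
              stats::pchisq(stat, k - 1L, lower.tail = FALSE), df = k - 1L)
}

#' Diebold-Mariano test of equal forecast loss
#'
#' For loss series a and b, d_t = a_t - b_t; DM = dbar / sqrt(lrv / T)
#' where the long-run variance lrv = gamma_0 + 2 sum_{l<h} gamma_l uses
#' autocovariances truncated at lag h-1. Two-sided normal p. Positive DM
#' means series a has the larger loss.
#'
#' @param loss_a,loss_b per-sample loss series, equal length T >= 10.
#' @param horizon truncation horizon h (lags up to h-1 enter the long-run
#'   variance).
#' @return \code{stat_test_result}.
#' @export
diebold_mariano <- function(loss_a, loss_b, horizon = 1L) {
  if (length(loss_a) != length(loss_b)) stop("length mismatch")
  T_ <- length(loss_a)
  if (T_ < 10L) stop("need at least 10 paired losses")
  d <- loss_a - loss_b
  dbar <- mean(d)
  gamma <- function(l) sum((d[(l + 1):T_] - dbar) * (d[1:(T_ - l)] - dbar)) / T_
  lrv <- gamma(0)
  if (horizon > 1L)
    for (l in seq_len(horizon - 1L)) lrv <- lrv + 2 * gamma(l)
  if (lrv <= 0)
    return(stat_result("dm", 0, 1, flag = "degenerate long-run variance"))
  stat <- dbar / sqrt(lrv / T_)
  stat_result("dm", stat, 2 * stats::pnorm(-abs(stat)))
}

# per-sample cross-entropy of predicted probabilities against true labels
per_sample_ce <- function(probs, y_int) {
  -log(pmax(probs[cbind(seq_len(nrow(probs)), y_int)], 1e-12))
}

#' Per-feature statistical significance battery
#'
#' One row per schema feature: continuous features are tested by one-way
#' ANOVA of the feature across the predicted risk classes, categorical
#' features by the chi-square test of association, and every feature by a
#' Diebold-Mariano test comparing the model's per-sample cross-entropy
#' against the loss after permuting that feature (a permutation-importance
#' reading of the per-feature error comparison). Model-level tests are
#' attached: Wilcoxon signed rank on encoded predicted-vs-true labels,
#' Friedman consistency of permutation-importance feature ranks across
#' blocks of the evaluation split, and (when baseline probabilities are
#' supplied) Diebold-Mariano against the baseline's loss.
#'
#' @param model trained \code{caal_model}.
#' @param cohort labeled evaluation cohort.
#' @param baseline_prob optional n x 3 probability matrix of a baseline
#'   model on the same records.
#' @param n_blocks blocks for the Friedman rank-consistency test.
#' @param seed seed for the feature permutations.
#' @return list with \code{feature_tests} (one row per feature) and
#'   \code{model_tests}.
#' @export
feature_significance_battery <- function(model, cohort, baseline_prob = NULL,
                                         n_blocks = 5L, seed = 1L) {
  if (!isTRUE(model$trained)) stop("model is not trained: predictions missing")
  mm <- as_model_matrix(cohort, model)
  if (is.null(mm$y)) stop("cohort has no labels")
  probs <- evaluate_matrix(model, mm$X)$probs
  pred <- max.col(probs)
  loss0 <- per_sample_ce(probs, mm$y)
  set.seed(seed)
  n <- nrow(mm$X)
  feats <- model$feature_order
  rows <- list()
  dloss <- matrix(0, n, length(feats), dimnames = list(NULL, feats))
  for (cl in feats) {
    v <- cohort$data[[cl]]
    if (cl %in% .categorical_features) {
      ft <- chi_square_test(v, .risk_levels[pred])
      test_name <- "chi2"
    } else {
      if (is.character(v)) v <- as.numeric(v)
      ft <- anova_oneway(v, .risk_levels[pred])
      test_name <- "anova"
    }
    Xp <- mm$X
    Xp[, cl] <- Xp[sample.int(n), cl]
    lp <- per_sample_ce(evaluate_matrix(model, Xp)$probs, mm$y)
    dm <- diebold_mariano(lp, loss0)
    dloss[, cl] <- lp - loss0
    rows[[cl]] <- data.frame(feature = cl, test = test_name,
                             statistic = ft$statistic, p_value = ft$p_value,
                             dm_perm = dm$statistic, dm_p = dm$p_value,
                             stringsAsFactors = FALSE)
  }
  feature_tests <- do.call(rbind, rows)
  rownames(feature_tests) <- NULL

  wil <- wilcoxon_signed_rank(pred, mm$y)
  blocks <- cut(seq_len(n), n_blocks, labels = FALSE)
  imp_ranks <- t(vapply(seq_len(n_blocks), function(b)
    rank(-colMeans(dloss[blocks == b, , drop = FALSE])),
    numeric(length(feats))))
  fri <- friedman_rank_test(imp_ranks)
  model_tests <- list(wilcoxon = wil, friedman = fri)
  if (!is.null(baseline_prob))
    model_tests$dm_baseline <- diebold_mariano(
      per_sample_ce(as.matrix(baseline_prob), mm$y), loss0)
  list(feature_tests = feature_tests, model_tests = model_tests)
}
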