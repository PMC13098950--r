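# Explanations: global importance from the cross-attention attribution
# map, LIME-style local surrogates, and the explanation quality metrics
# (local fidelity R^2, contribution scores C+/C-, stability S).

#' Global feature importance from the attribution map
#'
#' Mean of the cross-attention attribution weights A_C over heads and
#' samples, renormalized to sum to 1. Per-instance attribution is also
#' returned.
#'
#' @param model trained E6 \code{caal_model}.
#' @param cohort cohort to average over (typically the test split).
#' @return a \code{global_importance} data frame (feature, score) with the
#'   per-instance weights in \code{attr(, "per_instance")}.
#' @export
caal_attribution <- function(model, cohort) {
  if (!isTRUE(model$trained)) stop("model is not trained")
  if (is.null(model$params$caal))
    stop("model variant has no cross-attention attribution layer")
  X <- if (is.matrix(cohort)) cohort else as_model_matrix(cohort, model)$X
  n <- nrow(X)
  per <- matrix(0, n, model$m)
  for (start in seq(1L, n, by = 512L)) {
    idx <- start:min(start + 511L, n)
    fw <- model_forward(model, X[idx, , drop = FALSE], train = FALSE)
    per[idx, ] <- Reduce(`+`, fw$AC) / length(fw$AC)
  }
  colnames(per) <- model$feature_order
  score <- colMeans(per)
  score <- score / sum(score)
  out <- data.frame(feature = model$feature_order, score = unname(score),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  attr(out, "method") <- "caal"
  attr(out, "per_instance") <- per
  class(out) <- c("global_importance", "data.frame")
  out
}

#' Local surrogate (LIME-style) explanation of one prediction
#'
#' Perturbs the instance (Gaussian noise at the training-split standard
#' deviation for continuous features, category resampling for
#' categoricals), queries the model's probability for the instance's
#' predicted class, and fits a proximity-weighted linear surrogate in the
#' original feature units. Proximity uses the exponential kernel
#' exp(-d^2 / kw^2) on standardized distance with kw = 0.75 sqrt(m).
#'
#' @param model trained \code{caal_model}, or any object when
#'   \code{predict_fn} is supplied.
#' @param instance one-row data frame (or named list) of raw feature
#'   values.
#' @param n_perturb number of perturbed samples (>= 50).
#' @param seed integer seed; explanations are deterministic given it.
#' @param kernel_width proximity kernel width; default 0.75 sqrt(m).
#' @param top_k size of the ranked feature set reported for stability
#'   analysis.
#' @param predict_fn optional function(data.frame) -> numeric target,
#'   overriding the model query (used to explain arbitrary black boxes).
#' @return an \code{explanation_bundle}: surrogate weights and intercept,
#'   local fidelity R^2, C+/C-, and the ranked top features.
#' @export
lime_explain <- function(model, instance, n_perturb = 500L, seed = 1L,
                         kernel_width = NULL, top_k = 5L,
                         predict_fn = NULL) {
  if (n_perturb < 50L) stop("n_perturb must be >= 50")
  inst <- as.data.frame(instance, stringsAsFactors = FALSE)
  feats <- if (!is.null(model$feature_order)) model$feature_order
           else intersect(.schema_features, names(inst))
  m <- length(feats)
  if (is.null(kernel_width)) kernel_width <- 0.75 * sqrt(m)
  # encode categoricals to codes in raw units
  dict <- if (!is.null(model$dictionaries)) model$dictionaries else .dictionaries
  for (cl in intersect(.categorical_features, feats))
    if (is.character(inst[[cl]])) inst[[cl]] <- unname(dict[[cl]][inst[[cl]]])
  x0 <- as.numeric(inst[1, feats])
  names(x0) <- feats

  st <- model$norm_stats
  sds <- stats::setNames(rep(1, m), feats)
  means <- stats::setNames(rep(0, m), feats)
  if (!is.null(st)) {
    sds[st$feature] <- ifelse(st$sd > 0, st$sd, 1)
    means[st$feature] <- st$mean
  }

  set.seed(seed)
  P <- matrix(rep(x0, each = n_perturb), n_perturb, m,
              dimnames = list(NULL, feats))
  for (cl in feats) {
    if (cl %in% .categorical_features) {
      P[, cl] <- sample(unname(dict[[cl]]), n_perturb, replace = TRUE)
    } else {
      P[, cl] <- x0[cl] + stats::rnorm(n_perturb, 0, sds[cl])
    }
  }
  P[1, ] <- x0                                   # keep the instance itself

  Pdf <- as.data.frame(P)
  if (is.null(predict_fn)) {
    if (!isTRUE(model$trained)) stop("model is not trained")
    Z <- sweep(sweep(P, 2L, means[feats], "-"), 2L, sds[feats], "/")
    Z[, intersect(.categorical_features, feats)] <-
      P[, intersect(.categorical_features, feats)]
    probs <- evaluate_matrix(model, Z)$probs
    cls <- which.max(probs[1, ])
    target <- probs[, cls]
  } else {
    target <- as.numeric(predict_fn(Pdf))
    cls <- NA_integer_
  }

  # proximity in standardized space
  Zs <- sweep(sweep(P, 2L, x0, "-"), 2L, sds[feats], "/")
  d2 <- rowSums(Zs^2)
  w <- exp(-d2 / kernel_width^2)

  Xd <- cbind(1, P)
  A <- t(Xd) %*% (w * Xd)
  bvec <- t(Xd) %*% (w * target)
  coefs <- tryCatch(solve(A, bvec), error = function(e) {
    message("singular local design: ridge fallback (1e-6)")
    solve(A + diag(1e-6, ncol(A)), bvec)
  })
  intercept <- coefs[1]
  wts <- stats::setNames(as.numeric(coefs[-1]), feats)
  y_sur <- as.numeric(Xd %*% coefs)
  r2 <- local_fidelity(target, y_sur)
  cs <- contribution_scores(wts, x0)
  contrib <- abs(wts * x0)
  top <- data.frame(feature = names(sort(contrib, decreasing = TRUE)),
                    stringsAsFactors = FALSE)
  top$weight <- wts[top$feature]
  top$sign <- ifelse(top$weight >= 0, "+", "-")
  structure(list(instance = x0, predicted_class = cls,
                 surrogate_weights = wts, surrogate_intercept = intercept,
                 local_fidelity = r2, c_plus = cs$c_plus,
                 c_minus = cs$c_minus, top_features = top,
                 top_set = top$feature[seq_len(min(top_k, m))],
                 n_perturb = n_perturb, seed = seed),
            class = "explanation_bundle")
}

#' @export
print.explanation_bundle <- function(x, ...) {
  cat(sprintf("<explanation: R2 = %.3f, C+ = %.3f, C- = %.3f>\n",
              x$local_fidelity, x$c_plus, x$c_minus))
  print(utils::head(x$top_features, 5))
  invisible(x)
}

#' Local fidelity of a surrogate
#'
#' R^2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2) of the surrogate's
#' predictions against the model outputs; 1 for an exact match, 0 for the
#' mean-only model, and defined as 0 when the model outputs have no
#' variance.
#'
#' @param y_model model outputs over the perturbation sample.
#' @param y_surrogate surrogate predictions, same length (>= 2).
#' @return R^2, at most 1.
#' @export
local_fidelity <- function(y_model, y_surrogate) {
  if (length(y_model) != length(y_surrogate) || length(y_model) < 2L)
    stop("need two aligned vectors of length >= 2")
  sst <- sum((y_model - mean(y_model))^2)
  if (sst == 0) {
    message("constant model output: fidelity defined as 0")
    return(0)
  }
  1 - sum((y_model - y_surrogate)^2) / sst
}

#' Positive and negative contribution scores
#'
#' C+ = sum of w_i x_i over positive weights; C- = the same sum over
#' negative weights.
#'
#' @param weights surrogate weights aligned to the schema.
#' @param values instance feature values.
#' @return list with \code{c_plus} and \code{c_minus}.
#' @export
contribution_scores <- function(weights, values) {
  wx <- weights * values
  list(c_plus = sum(wx[weights > 0]), c_minus = sum(wx[weights < 0]))
}

#' Stability of explanation feature sets
#'
#' Mean pairwise Jaccard index over all unordered pairs of top-k feature
#' sets; 1 when every explanation selects the same features, 0 when all
#' pairs are disjoint. A pair of empty sets scores 0.
#'
#' @param feature_sets list (>= 2) of character vectors.
#' @return stability score in [0, 1].
#' @export
stability_score <- function(feature_sets) {
  if (length(feature_sets) < 2L) stop("need at least 2 feature sets")
  n <- length(feature_sets)
  tot <- 0; np <- 0L
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- feature_sets[[i]]; b <- feature_sets[[j]]
    u <- length(union(a, b))
    if (u == 0L) {
      message("empty set pair: Jaccard defined as 0")
      jac <- 0
    } else jac <- length(intersect(a, b)) / u
    tot <- tot + jac; np <- np + 1L
  }
  tot / np
}

#' Aggregate local explanations into global importance
#'
#' Mean absolute contribution |w_i x_i| per feature across bundles,
#' normalized to sum to 1 and ranked.
#'
#' @param bundles list of \code{explanation_bundle}s (>= 1).
#' @return a \code{global_importance} data frame.
#' @export
aggregate_lime <- function(bundles) {
  if (!length(bundles)) stop("need at least one explanation bundle")
  feats <- names(bundles[[1]]$surrogate_weights)
  agg <- rowMeans(vapply(bundles, function(b)
    abs(b$surrogate_weights[feats] * b$instance[feats]), numeric(length(feats))))
  if (sum(agg) > 0) agg <- agg / sum(agg)
  out <- data.frame(feature = feats, score = unname(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score), ]
  rownames(out) <- NULL
  attr(out, "method") <- "lime-aggregate"
  class(out) <- c("global_importance", "data.frame")
  out
}
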