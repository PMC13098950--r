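# Training loop, optimizers, prediction, forward traces and the
# finite-difference gradient checker.

# Walk two parallel nested lists of numeric arrays, pairing named
# components by name (the gradient tree's ordering may differ from the
# parameter tree's).
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    keys <- if (!is.null(names(a))) names(a) else seq_along(a)
    out <- lapply(keys, function(k) tree_map2(f, a[[k]], b[[k]]))
    names(out) <- names(a)
    out
  } else f(a, b)
}

tree_sumsq <- function(a) {
  if (is.list(a)) sum(vapply(a, tree_sumsq, numeric(1))) else sum(a^2)
}

zeros_like <- function(a) {
  if (is.list(a)) lapply(a, zeros_like) else a * 0
}

clip_grads <- function(g, max_norm) {
  if (max_norm <= 0) return(g)
  nrm <- sqrt(tree_sumsq(g))
  if (is.finite(nrm) && nrm > max_norm)
    g <- tree_map2(function(x, y) x * (max_norm / nrm), g, g)
  g
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      keys <- if (!is.null(names(p))) names(p) else seq_along(p)
      res <- lapply(keys, function(k) walk(p[[k]], g[[k]], m[[k]], v[[k]]))
      names(res) <- names(p)
      list(p = lapply(res, `[[`, "p"),
           m = lapply(res, `[[`, "m"),
           v = lapply(res, `[[`, "v"))
    } else upd(p, g, m, v)
  }
  walk(params, grads, state$m, state$v)
}

#' Training loss: cross-entropy plus attribution-sharpness penalty
#'
#' Categorical cross-entropy (natural log) of the predicted probabilities,
#' plus \code{lambda_xai} times the mean Shannon entropy in bits of the
#' attribution heads. A zero probability at the true class is clamped at
#' 1e-12 (and noted via \code{message}).
#'
#' @param y_hat B x K matrix of class probabilities.
#' @param y integer true classes in 1..K.
#' @param A_C optional list of B x m attribution-weight matrices (one per
#'   head).
#' @param lambda_xai regularizer coefficient; 0 gives plain cross-entropy.
#' @return scalar loss.
#' @export
caal_loss <- function(y_hat, y, A_C = NULL, lambda_xai = 0) {
  if (is.vector(y_hat)) y_hat <- matrix(y_hat, nrow = 1)
  py <- y_hat[cbind(seq_len(nrow(y_hat)), y)]
  if (any(py < 1e-12))
    message("clamping ", sum(py < 1e-12), " zero probabilities at 1e-12")
  caal_loss_forward(y_hat, y, AC = A_C, lambda_xai = lambda_xai)$loss
}

#' Train a model on a cohort
#'
#' Mini-batch gradient optimization of the configured variant. The run is
#' deterministic given the config seed: initialization, batch shuffling and
#' dropout masks all draw from it. The checkpoint with the best validation
#' accuracy is restored at the end, and per-epoch curves (loss, accuracy,
#' mean predictive entropy) are kept in \code{$history}.
#'
#' @param model an untrained \code{caal_model} from \code{\link{build_variant}}.
#' @param train_cohort preprocessed, labeled, ordered training cohort.
#' @param val_cohort optional validation cohort; when \code{NULL} the
#'   training split doubles as the monitoring set.
#' @param verbose print per-epoch progress.
#' @return the trained \code{caal_model}, with \code{$history} (one row per
#'   epoch) and \code{$best_epoch}.
#' @export
train_caal <- function(model, train_cohort, val_cohort = NULL,
                       verbose = FALSE) {
  cfg <- model$config
  tr <- as_model_matrix(train_cohort)
  if (is.null(tr$y)) stop("training cohort has no labels")
  va <- if (is.null(val_cohort)) tr else as_model_matrix(val_cohort)
  model$feature_order <- cohort_order(train_cohort)
  model$norm_stats <- train_cohort$norm_stats
  model$dictionaries <- train_cohort$dictionaries

  n <- nrow(tr$X)
  set.seed(cfg$seed + 1L)
  state <- list(m = zeros_like(model$params), v = zeros_like(model$params))
  step <- 0L
  best <- list(acc = -Inf, epoch = 0L, params = model$params)
  hist <- vector("list", cfg$max_epochs)
  wait <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    # attribution-sharpness coefficient annealed in from zero
    lam <- if (cfg$lambda_warmup > 0)
      cfg$lambda_xai * min(1, (epoch - 1) / cfg$lambda_warmup)
    else cfg$lambda_xai
    model$config$lambda_xai <- lam
    perm <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
      Xb <- tr$X[idx, , drop = FALSE]; yb <- tr$y[idx]
      fw <- model_forward(model, Xb, train = TRUE)
      ls <- caal_loss_forward(fw$p, yb, AC = fw$AC, lambda_xai = lam)
      if (!is.finite(ls$loss))
        stop(sprintf("non-finite loss at epoch %d, batch rows [%s]",
                     epoch, paste(utils::head(idx), collapse = ",")))
      g <- model_backward(model, fw, yb)
      g <- clip_grads(g, cfg$grad_clip)
      step <- step + 1L
      if (cfg$optimizer == "adam") {
        res <- adam_update(model$params, g, state, cfg$learning_rate, step)
        model$params <- res$p; state$m <- res$m; state$v <- res$v
      } else {
        model$params <- tree_map2(function(p, gr) p - cfg$learning_rate * gr,
                                  model$params, g)
      }
      ep_loss <- ep_loss + ls$loss * length(idx)
      ep_correct <- ep_correct + sum(max.col(fw$p) == yb)
    }
    ev <- evaluate_matrix(model, va$X, va$y)
    hist[[epoch]] <- data.frame(
      epoch = epoch, train_loss = ep_loss / n, train_acc = ep_correct / n,
      val_loss = ev$loss, val_acc = ev$acc, val_entropy = ev$entropy)
    if (verbose)
      message(sprintf("epoch %2d  loss %.4f  acc %.3f  val %.3f  H %.3f",
                      epoch, ep_loss / n, ep_correct / n, ev$acc, ev$entropy))
    # checkpoints and patience only count once the annealed objective is
    # fully active; earlier epochs optimize a different loss
    if (epoch >= min(cfg$lambda_warmup, cfg$max_epochs)) {
      if (ev$acc > best$acc + 1e-12) {
        best <- list(acc = ev$acc, epoch = epoch, params = model$params)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  }
  model$config$lambda_xai <- cfg$lambda_xai
  if (best$epoch > 0L) model$params <- best$params
  model$best_epoch <- best$epoch
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
  model$trained <- TRUE
  model
}

# Chunked evaluation pass (no dropout).
evaluate_matrix <- function(model, X, y = NULL, chunk = 512L) {
  n <- nrow(X)
  probs <- matrix(0, n, model$n_classes)
  AC_H <- 0; loss <- 0
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- model_forward(model, X[idx, , drop = FALSE], train = FALSE)
    probs[idx, ] <- fw$p
    if (!is.null(y)) {
      ls <- caal_loss_forward(fw$p, y[idx], AC = fw$AC,
                              lambda_xai = model$config$lambda_xai)
      loss <- loss + ls$loss * length(idx)
    }
  }
  pc <- pmax(probs, 1e-12)
  ent <- mean(-rowSums(pc * log2(pc)))
  list(probs = probs,
       acc = if (is.null(y)) NA_real_ else mean(max.col(probs) == y),
       loss = if (is.null(y)) NA_real_ else loss / n,
       entropy = ent)
}

#' Predict risk classes or probabilities
#'
#' @param object trained \code{caal_model}.
#' @param newdata a cohort (normalized with the model's training statistics
#'   if not already) or an ordered, normalized numeric matrix.
#' @param type \code{"class"} for labels, \code{"prob"} for the probability
#'   matrix.
#' @param ... unused.
#' @export
predict.caal_model <- function(object, newdata,
                               type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata
       else as_model_matrix(newdata, model = object)$X
  ev <- evaluate_matrix(object, X)
  if (type == "prob") {
    colnames(ev$probs) <- object$class_levels
    return(ev$probs)
  }
  factor(object$class_levels[max.col(ev$probs)], levels = object$class_levels)
}

#' Forward trace of a single record
#'
#' Runs one record through the network and returns every intermediate:
#' tokens, post-attention token matrix, per-head attention weights of the
#' last transformer block, position-enhanced tokens, the LSTM summary, the
#' attribution weights of each cross-attention head, the fused vector and
#' the class probabilities.
#'
#' @param model trained \code{caal_model}.
#' @param x a single record: length-m numeric vector (ordered, normalized)
#'   or a 1-row matrix.
#' @return a list of class \code{forward_trace}.
#' @export
forward_trace <- function(model, x) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  fw <- model_forward(model, X, train = FALSE)
  attn <- NULL
  if (!is.null(fw$attn)) {
    last <- fw$attn[[length(fw$attn)]]
    attn <- lapply(seq_len(model$config$n_heads),
                   function(h) matrix(last$P[1, h, , ], model$m, model$m))
  }
  structure(list(
    tokens = matrix(fw$tokens[1, , ], model$m),
    A_T = if (!is.null(fw$AT3)) matrix(fw$AT3[1, , ], model$m),
    attn_weights = attn,
    x_PE = if (!is.null(fw$xpe)) matrix(fw$xpe[1, , ], model$m),
    h_T = if (!is.null(fw$hT)) fw$hT[1, ],
    A_C = if (!is.null(fw$AC)) lapply(fw$AC, function(A) A[1, ]),
    fused = fw$fused[1, ],
    y_hat = fw$p[1, ]), class = "forward_trace")
}

# Finite-difference gradient check on n_checks randomly chosen parameters.
# Returns the worst relative error. Internal; exercised by the test suite.
grad_check <- function(model, X, y, n_checks = 20L, eps = 1e-5, seed = 1L) {
  set.seed(seed)
  loss_at <- function(params) {
    m2 <- model; m2$params <- params
    fw <- model_forward(m2, X, train = FALSE)
    caal_loss_forward(fw$p, y, AC = fw$AC,
                      lambda_xai = model$config$lambda_xai)$loss
  }
  fw <- model_forward(model, X, train = FALSE)
  g <- model_backward(model, fw, y)
  # flatten parameter paths; use names where present so the same path
  # addresses both the parameter tree and the gradient tree
  paths <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      nms <- names(x)
      for (i in seq_along(x)) {
        key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
        walk(x[[i]], c(path, list(key)))
      }
    } else paths[[length(paths) + 1L]] <<- list(path = path, n = length(x))
  }
  walk(model$params, list())
  get_in <- function(tree, path) {
    for (i in path) tree <- tree[[i]]
    tree
  }
  set_in <- function(tree, path, val) {
    if (length(path) == 0L) return(val)
    tree[[path[[1]]]] <- set_in(tree[[path[[1]]]], path[-1], val)
    tree
  }
  worst <- 0
  for (k in seq_len(n_checks)) {
    pk <- paths[[sample.int(length(paths), 1L)]]
    j <- sample.int(pk$n, 1L)
    leaf <- get_in(model$params, pk$path)
    lp <- leaf; lp[j] <- lp[j] + eps
    lm <- leaf; lm[j] <- lm[j] - eps
    fplus <- loss_at(set_in(model$params, pk$path, lp))
    fminus <- loss_at(set_in(model$params, pk$path, lm))
    num <- (fplus - fminus) / (2 * eps)
    ana <- get_in(g, pk$path)[j]
    rel <- abs(num - ana) / max(1e-8, abs(num), abs(ana))
    if (abs(num) < 1e-10 && abs(ana) < 1e-10) rel <- 0
    worst <- max(worst, rel)
  }
  worst
}
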