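# Model assembly: configuration, parameter initialization, the ablation
# ladder E1..E6, and the variant-aware forward/backward dispatch.

#' Model configuration
#'
#' Collects every architectural and optimization choice of the hybrid
#' classifier. Defaults follow the published hyperparameter search spaces
#' (heads 4/8, layers 2/4, FFN 256/512, LSTM units 64/128, attention dim
#' 32/64, CAAL heads 2/4, fusion add/concat, dropout 0.1/0.3,
#' lambda_xai 0.1/0.2); values outside those grids are accepted but flagged
#' in the returned object's \code{off_grid} field.
#'
#' @param d_token token embedding width (even, divisible by \code{n_heads}).
#' @param n_heads transformer attention heads.
#' @param n_layers stacked transformer blocks.
#' @param ffn_dim feed-forward hidden width inside each transformer block.
#' @param lstm_units LSTM hidden-state width.
#' @param attention_dim width of additive-attention / CAAL head projections.
#' @param caal_heads number of cross-attention attribution heads.
#' @param fusion \code{"concat"} or \code{"add"}: how the attribution
#'   context and the LSTM summary are fused before classification.
#' @param dropout dropout rate applied to the fused representation during
#'   training.
#' @param lambda_xai coefficient of the attribution-sharpness (entropy)
#'   regularizer; 0 recovers plain cross-entropy.
#' @param lambda_warmup epochs over which \code{lambda_xai} is annealed
#'   linearly from 0, so cross-entropy gradients select the informative
#'   features before the sharpness penalty locks the attribution in.
#' @param learning_rate optimizer step size.
#' @param batch_size mini-batch size.
#' @param max_epochs training epoch cap.
#' @param patience early-stopping patience on validation accuracy.
#' @param optimizer \code{"adam"} or \code{"sgd"} (the plain gradient rule).
#' @param canonical_pe use the canonical 10000-base sine/cosine positional
#'   encoding instead of the model's own base-10 sine form.
#' @param grad_clip global gradient-norm clip (0 disables).
#' @param res_init_scale multiplier on the initial attention-output and
#'   feed-forward projection weights. Small values start the transformer
#'   blocks near identity, keeping each token dominated by its own feature
#'   early in training -- the property that makes the attribution map
#'   faithful to input features.
#' @param caal_init_scale multiplier on the initial CAAL summary
#'   projections, so attribution weights start near-uniform instead of
#'   reflecting arbitrary initialization magnitudes.
#' @param seed integer seed controlling initialization and batching.
#' @return an object of class \code{caal_config}.
#' @export
caal_config <- function(d_token = 16L, n_heads = 4L, n_layers = 2L,
                        ffn_dim = 256L, lstm_units = 64L, attention_dim = 32L,
                        caal_heads = 2L, fusion = c("concat", "add"),
                        dropout = 0.1, lambda_xai = 0.2, lambda_warmup = 10L,
                        learning_rate = 1e-3, batch_size = 64L,
                        max_epochs = 60L, patience = 10L,
                        optimizer = c("adam", "sgd"),
                        canonical_pe = FALSE, grad_clip = 5,
                        res_init_scale = 0.05, caal_init_scale = 0.1,
                        seed = 1L) {
  fusion <- match.arg(fusion)
  optimizer <- match.arg(optimizer)
  if (d_token %% 2L != 0L)
    stop("d_token must be even (sinusoidal encoding pairs)")
  if (d_token %% n_heads != 0L)
    stop("d_token must be divisible by n_heads")
  grids <- list(n_heads = c(4, 8), n_layers = c(2, 4), ffn_dim = c(256, 512),
                lstm_units = c(64, 128), attention_dim = c(32, 64),
                caal_heads = c(2, 4), dropout = c(0.1, 0.3),
                lambda_xai = c(0, 0.1, 0.2),
                learning_rate = c(5e-5, 1e-4, 5e-4, 1e-3),
                batch_size = c(32, 64, 128))
  vals <- list(n_heads = n_heads, n_layers = n_layers, ffn_dim = ffn_dim,
               lstm_units = lstm_units, attention_dim = attention_dim,
               caal_heads = caal_heads, dropout = dropout,
               lambda_xai = lambda_xai, learning_rate = learning_rate,
               batch_size = batch_size)
  off_grid <- names(vals)[!mapply(function(v, g) v %in% g, vals, grids)]
  structure(list(d_token = as.integer(d_token), n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers), ffn_dim = as.integer(ffn_dim),
                 lstm_units = as.integer(lstm_units),
                 attention_dim = as.integer(attention_dim),
                 caal_heads = as.integer(caal_heads), fusion = fusion,
                 dropout = dropout, lambda_xai = lambda_xai,
                 lambda_warmup = as.integer(lambda_warmup),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), optimizer = optimizer,
                 canonical_pe = canonical_pe, grad_clip = grad_clip,
                 res_init_scale = res_init_scale,
                 caal_init_scale = caal_init_scale,
                 seed = as.integer(seed), off_grid = off_grid),
            class = "caal_config")
}

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

init_params <- function(variant, config, m = 10L, n_classes = 3L) {
  d <- config$d_token; H <- config$lstm_units; a <- config$attention_dim
  p <- list()
  lim <- sqrt(6 / (1 + d))              # per-feature scalar map: fan-in 1
  p$tok <- list(W = matrix(stats::runif(m * d, -lim, lim), m, d),
                b = matrix(0, m, d))
  use_trans <- variant %in% c("E3", "E4", "E5", "E6")
  use_lstm  <- variant %in% c("E1", "E2", "E4", "E5", "E6")
  if (use_trans) {
    p$trans <- lapply(seq_len(config$n_layers), function(l) {
      list(Wq = glorot(d, d), Wk = glorot(d, d), Wv = glorot(d, d),
           Wo = glorot(d, d) * config$res_init_scale,
           W1 = glorot(d, config$ffn_dim), b1 = numeric(config$ffn_dim),
           W2 = glorot(config$ffn_dim, d) * config$res_init_scale,
           b2 = numeric(d))
    })
  }
  if (use_lstm) {
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1          # forget-gate bias, standard stabilizer
    p$lstm <- list(Wx = glorot(d, 4 * H), Wh = glorot(H, 4 * H), b = b)
  }
  if (variant == "E2")
    p$pool_l <- list(Wa = glorot(H, a), ba = numeric(a),
                     va = stats::runif(a, -sqrt(3 / a), sqrt(3 / a)))
  if (variant == "E5") {
    p$pool_t <- list(Wa = glorot(d, a), ba = numeric(a),
                     va = stats::runif(a, -sqrt(3 / a), sqrt(3 / a)))
    p$pool_l <- list(Wa = glorot(H, a), ba = numeric(a),
                     va = stats::runif(a, -sqrt(3 / a), sqrt(3 / a)))
  }
  if (variant == "E6") {
    p$caal <- lapply(seq_len(config$caal_heads), function(h)
      list(WF = glorot(d, a),
           WL = glorot(H, a) * config$caal_init_scale))
    if (config$fusion == "add")
      p$proj <- list(Wp = glorot(H, config$caal_heads * a))
  }
  fused_dim <- switch(variant,
    E1 = H, E2 = H, E3 = d, E4 = d + H, E5 = d + H,
    E6 = if (config$fusion == "concat") config$caal_heads * a + H
         else config$caal_heads * a)
  p$cls <- list(W = glorot(fused_dim, n_classes), b = numeric(n_classes))
  p
}

#' Build an ablation-ladder model variant
#'
#' Constructs an untrained model of one of the six architectures:
#' \describe{
#'   \item{E1}{LSTM over the ordered feature sequence, classifier on the
#'     final hidden state.}
#'   \item{E2}{E1 plus additive temporal-attention pooling over the LSTM
#'     hidden states.}
#'   \item{E3}{feature self-attention (FT-Transformer style) with mean
#'     pooling over tokens.}
#'   \item{E4}{early fusion: mean-pooled transformer output concatenated
#'     with the LSTM summary.}
#'   \item{E5}{E4 with a separate additive-attention pooling head on each
#'     branch.}
#'   \item{E6}{the full hybrid with the Cross-Attention Attribution Layer.}
#' }
#'
#' @param variant one of \code{"E1"}..\code{"E6"}.
#' @param config a \code{\link{caal_config}}.
#' @param n_features number of feature positions (10 for the cohort schema).
#' @param n_classes number of risk classes.
#' @return an object of class \code{caal_model} (untrained).
#' @export
build_variant <- function(variant = "E6", config = caal_config(),
                          n_features = 10L, n_classes = 3L) {
  if (!variant %in% paste0("E", 1:6))
    stop("unknown variant: ", variant)
  set.seed(config$seed)
  params <- init_params(variant, config, m = n_features, n_classes = n_classes)
  structure(list(variant = variant, config = config, params = params,
                 m = as.integer(n_features), n_classes = as.integer(n_classes),
                 trained = FALSE, feature_order = NULL, norm_stats = NULL,
                 dictionaries = NULL, class_levels = c("Low", "Medium", "High")),
            class = "caal_model")
}

#' @export
print.caal_model <- function(x, ...) {
  cat(sprintf("<caal_model %s: %d features -> %d classes, %s, %s params%s>\n",
              x$variant, x$m, x$n_classes,
              paste0("d=", x$config$d_token),
              format(n_params(x), big.mark = ","),
              if (x$trained) ", trained" else ""))
  invisible(x)
}

#' Count learnable parameters of a model
#' @param model a \code{caal_model}.
#' @return integer parameter count.
#' @export
n_params <- function(model) {
  cnt <- 0L
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else cnt <<- cnt + length(x)
    invisible(NULL)
  }
  walk(model$params)
  cnt
}

# Core forward pass on an ordered, normalized B x m value matrix.
# Returns class probabilities plus every intermediate needed for backward
# and for the forward trace.
model_forward <- function(model, X, train = FALSE) {
  if (any(abs(X) > 20))
    warning("input values with |z| > 20: did you normalize the cohort?")
  cfg <- model$config; p <- model$params; v <- model$variant
  B <- nrow(X)
  tokens <- tokenize_forward(X, p$tok)
  fw <- list(tokens = tokens, X = X)

  AT3 <- NULL
  if (!is.null(p$trans)) {
    AT3 <- tokens
    fw$attn <- vector("list", length(p$trans))
    for (l in seq_along(p$trans)) {
      res <- attn_layer_forward(AT3, p$trans[[l]], cfg$n_heads)
      AT3 <- res$out
      fw$attn[[l]] <- res$cache
    }
    fw$AT3 <- AT3
  }
  if (!is.null(p$lstm)) {
    xpe <- positional_encode(tokens, canonical = cfg$canonical_pe)
    fw$xpe <- xpe
    lf <- lstm_forward(xpe, p$lstm)
    fw$lstm <- lf$cache; fw$H_all <- lf$H_all; fw$hT <- lf$hT
  }

  if (v == "E1") {
    fused <- fw$hT
  } else if (v == "E2") {
    pl <- attnpool_forward(fw$H_all, p$pool_l)
    fw$pool_l <- pl$cache
    fused <- pl$pooled
  } else if (v == "E3") {
    fused <- apply(AT3, c(1, 3), mean)
  } else if (v == "E4") {
    fused <- cbind(apply(AT3, c(1, 3), mean), fw$hT)
  } else if (v == "E5") {
    pt <- attnpool_forward(AT3, p$pool_t)
    pl <- attnpool_forward(fw$H_all, p$pool_l)
    fw$pool_t <- pt$cache; fw$pool_l <- pl$cache
    fused <- cbind(pt$pooled, pl$pooled)
  } else {                                            # E6
    cf <- caal_forward(AT3, fw$hT, p$caal)
    fw$caal <- cf$cache; fw$AC <- cf$AC
    fused <- if (cfg$fusion == "concat") cbind(cf$context, fw$hT)
             else cf$context + fw$hT %*% p$proj$Wp
    fw$context <- cf$context
  }

  if (train && cfg$dropout > 0) {
    mask <- matrix(stats::rbinom(length(fused), 1L, 1 - cfg$dropout),
                   nrow(fused)) / (1 - cfg$dropout)
    fused <- fused * mask
    fw$drop_mask <- mask
  }
  fw$fused <- fused
  fw$p <- classify_forward(fused, p$cls)
  fw
}

# Backward pass matching model_forward; y is the 1-based true class vector.
# Returns gradients in the same nested structure as model$params.
model_backward <- function(model, fw, y) {
  cfg <- model$config; p <- model$params; v <- model$variant
  B <- nrow(fw$p); m <- model$m
  g <- list()
  dlogits <- ce_logit_grad(fw$p, y)
  g$cls <- list(W = t(fw$fused) %*% dlogits, b = colSums(dlogits))
  dfused <- dlogits %*% t(p$cls$W)
  if (!is.null(fw$drop_mask)) dfused <- dfused * fw$drop_mask

  dtokens <- array(0, c(B, m, cfg$d_token))
  dAT3 <- NULL; dhT <- NULL; dH_all <- NULL

  if (v == "E1") {
    dhT <- dfused
    dH_all <- array(0, dim(fw$H_all))
  } else if (v == "E2") {
    pb <- attnpool_backward(dfused, fw$H_all, p$pool_l, fw$pool_l)
    g$pool_l <- pb$grads
    dH_all <- pb$dS3
    dhT <- matrix(0, B, cfg$lstm_units)
  } else if (v == "E3") {
    dAT3 <- array(0, c(B, m, cfg$d_token))
    for (i in seq_len(m)) dAT3[, i, ] <- dfused / m
  } else if (v == "E4") {
    d <- cfg$d_token
    dAT3 <- array(0, c(B, m, d))
    for (i in seq_len(m)) dAT3[, i, ] <- dfused[, 1:d, drop = FALSE] / m
    dhT <- dfused[, (d + 1):(d + cfg$lstm_units), drop = FALSE]
    dH_all <- array(0, dim(fw$H_all))
  } else if (v == "E5") {
    d <- cfg$d_token
    pt <- attnpool_backward(dfused[, 1:d, drop = FALSE], fw$AT3,
                            p$pool_t, fw$pool_t)
    pl <- attnpool_backward(dfused[, (d + 1):(d + cfg$lstm_units), drop = FALSE],
                            fw$H_all, p$pool_l, fw$pool_l)
    g$pool_t <- pt$grads; g$pool_l <- pl$grads
    dAT3 <- pt$dS3
    dH_all <- pl$dS3
    dhT <- matrix(0, B, cfg$lstm_units)
  } else {                                            # E6
    ctx_dim <- cfg$caal_heads * cfg$attention_dim
    if (cfg$fusion == "concat") {
      dContext <- dfused[, 1:ctx_dim, drop = FALSE]
      dhT <- dfused[, (ctx_dim + 1):(ctx_dim + cfg$lstm_units), drop = FALSE]
    } else {
      dContext <- dfused
      g$proj <- list(Wp = t(fw$hT) %*% dfused)
      dhT <- dfused %*% t(p$proj$Wp)
    }
    dAC <- entropy_reg_grad(fw$AC, cfg$lambda_xai)
    cb <- caal_backward(dContext, dAC, p$caal, fw$hT, fw$caal)
    g$caal <- cb$grads
    dAT3 <- cb$dAT3
    dhT <- dhT + cb$dhT
    dH_all <- array(0, dim(fw$H_all))
  }

  if (!is.null(p$trans)) {
    dcur <- dAT3
    g$trans <- vector("list", length(p$trans))
    for (l in rev(seq_along(p$trans))) {
      ab <- attn_layer_backward(dcur, p$trans[[l]], fw$attn[[l]])
      g$trans[[l]] <- ab$grads
      dcur <- ab$dX3
    }
    dtokens <- dtokens + dcur
  }
  if (!is.null(p$lstm)) {
    lb <- lstm_backward(dH_all, dhT, p$lstm, fw$lstm)
    g$lstm <- lb$grads
    dtokens <- dtokens + lb$dX3         # positional addend is constant
  }
  g$tok <- tokenize_backward(dtokens, fw$X, p$tok)
  g
}
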