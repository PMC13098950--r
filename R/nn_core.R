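# Numerical core: batched forward/backward passes for every network block.
#
# Conventions: a mini-batch of tokenized records is an array of dim (B, m, d)
# (B samples, m = 10 feature positions, d = token width).  3-d arrays are
# flattened to (B*m) x d matrices for dense products; row b + B*(i-1) holds
# sample b, position i.  All gradients are accumulated analytically; the
# finite-difference check in the test suite guards every path.

row_softmax <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## per-position scalar tokenization: token_i = value_i * w_i + b_i --------

tokenize_forward <- function(X, tok) {
  B <- nrow(X); m <- nrow(tok$W); d <- ncol(tok$W)
  out <- array(0, c(B, m, d))
  for (i in seq_len(m))
    out[, i, ] <- outer(X[, i], tok$W[i, ]) + matrix(tok$b[i, ], B, d, byrow = TRUE)
  out
}

tokenize_backward <- function(dT, X, tok) {
  m <- nrow(tok$W); d <- ncol(tok$W)
  dW <- matrix(0, m, d); db <- matrix(0, m, d)
  for (i in seq_len(m)) {
    dTi <- matrix(dT[, i, ], ncol = d)
    dW[i, ] <- colSums(dTi * X[, i])
    db[i, ] <- colSums(dTi)
  }
  list(W = dW, b = db)
}

## sinusoidal positional-psychological encoding ---------------------------

# Scalar addend for 0-based position i at token width d: sin(i / 10^(2i/d)).
pe_addend <- function(i, d) sin(i / 10^(2 * i / d))

# Canonical transformer encoding (10000-base sine/cosine pairs), offered as
# an alternative to the model's own base-10 scalar sine form.
pe_canonical <- function(i, d) {
  j <- seq_len(d %/% 2) - 1L
  v <- numeric(d)
  v[2L * j + 1L] <- sin(i / 10000^(2 * j / d))
  v[2L * j + 2L] <- cos(i / 10000^(2 * j / d))
  v
}

positional_encode <- function(tokens, canonical = FALSE) {
  m <- dim(tokens)[2]; d <- dim(tokens)[3]
  for (i in seq_len(m)) {
    add <- if (canonical) pe_canonical(i - 1L, d) else pe_addend(i - 1L, d)
    tokens[, i, ] <- sweep(matrix(tokens[, i, ], dim(tokens)[1]), 2L,
                           if (length(add) == 1L) rep(add, d) else add, "+")
  }
  tokens
}

## multi-head self-attention block (attention + FFN, residual) ------------

attn_layer_forward <- function(X3, layer, n_heads) {
  B <- dim(X3)[1]; m <- dim(X3)[2]; d <- dim(X3)[3]
  dk <- d %/% n_heads
  Xm <- matrix(X3, B * m, d)
  Q <- Xm %*% layer$Wq; K <- Xm %*% layer$Wk; V <- Xm %*% layer$Wv
  Q3 <- array(Q, c(B, m, d)); K3 <- array(K, c(B, m, d)); V3 <- array(V, c(B, m, d))
  P <- array(0, c(B, n_heads, m, m))
  O3 <- array(0, c(B, m, d))
  for (b in seq_len(B)) {
    Qb <- matrix(Q3[b, , ], m, d); Kb <- matrix(K3[b, , ], m, d); Vb <- matrix(V3[b, , ], m, d)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      S <- (Qb[, cols, drop = FALSE] %*% t(Kb[, cols, drop = FALSE])) / sqrt(dk)
      Ph <- row_softmax(S)
      P[b, h, , ] <- Ph
      O3[b, , cols] <- Ph %*% Vb[, cols, drop = FALSE]
    }
  }
  Om <- matrix(O3, B * m, d)
  proj <- Om %*% layer$Wo
  R1 <- Xm + proj                       # residual 1
  H1 <- R1 %*% layer$W1
  H1 <- sweep(H1, 2L, layer$b1, "+")
  H1r <- pmax(H1, 0)
  F2 <- H1r %*% layer$W2
  F2 <- sweep(F2, 2L, layer$b2, "+")
  out <- R1 + F2                        # residual 2
  list(out = array(out, c(B, m, d)),
       cache = list(Xm = Xm, Q3 = Q3, K3 = K3, V3 = V3, P = P, Om = Om,
                    R1 = R1, H1r = H1r, B = B, m = m, d = d, dk = dk,
                    n_heads = n_heads))
}

attn_layer_backward <- function(dOut3, layer, cache) {
  B <- cache$B; m <- cache$m; d <- cache$d; dk <- cache$dk; n_heads <- cache$n_heads
  dOut <- matrix(dOut3, B * m, d)
  # FFN sublayer
  dH1r <- dOut %*% t(layer$W2)
  dW2 <- t(cache$H1r) %*% dOut
  db2 <- colSums(dOut)
  dH1 <- dH1r * (cache$H1r > 0)
  dW1 <- t(cache$R1) %*% dH1
  db1 <- colSums(dH1)
  dR1 <- dOut + dH1 %*% t(layer$W1)
  # attention output projection
  dWo <- t(cache$Om) %*% dR1
  dOm <- dR1 %*% t(layer$Wo)
  dO3 <- array(dOm, c(B, m, d))
  dQ3 <- array(0, c(B, m, d)); dK3 <- array(0, c(B, m, d)); dV3 <- array(0, c(B, m, d))
  for (b in seq_len(B)) {
    Kb <- matrix(cache$K3[b, , ], m, d); Qb <- matrix(cache$Q3[b, , ], m, d)
    Vb <- matrix(cache$V3[b, , ], m, d); dOb <- matrix(dO3[b, , ], m, d)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      Ph <- matrix(cache$P[b, h, , ], m, m)
      dOh <- dOb[, cols, drop = FALSE]
      dP <- dOh %*% t(Vb[, cols, drop = FALSE])
      dV3[b, , cols] <- t(Ph) %*% dOh
      dS <- Ph * (dP - rowSums(Ph * dP))
      dQ3[b, , cols] <- (dS %*% Kb[, cols, drop = FALSE]) / sqrt(dk)
      dK3[b, , cols] <- (t(dS) %*% Qb[, cols, drop = FALSE]) / sqrt(dk)
    }
  }
  dQ <- matrix(dQ3, B * m, d); dK <- matrix(dK3, B * m, d); dV <- matrix(dV3, B * m, d)
  dWq <- t(cache$Xm) %*% dQ
  dWk <- t(cache$Xm) %*% dK
  dWv <- t(cache$Xm) %*% dV
  dXm <- dR1 + dQ %*% t(layer$Wq) + dK %*% t(layer$Wk) + dV %*% t(layer$Wv)
  list(dX3 = array(dXm, c(B, m, d)),
       grads = list(Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo,
                    W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

## LSTM over the m ordered feature positions ------------------------------

# Gate order along the 4H axis: input, forget, cell candidate, output.
lstm_forward <- function(X3, lstm) {
  B <- dim(X3)[1]; m <- dim(X3)[2]
  H <- nrow(lstm$Wh)
  h <- matrix(0, B, H); c_ <- matrix(0, B, H)
  steps <- vector("list", m)
  H_all <- array(0, c(B, m, H))
  for (t in seq_len(m)) {
    Xt <- matrix(X3[, t, ], B)
    G <- Xt %*% lstm$Wx + h %*% lstm$Wh
    G <- sweep(G, 2L, lstm$b, "+")
    i_ <- sigmoid(G[, 1:H, drop = FALSE])
    f_ <- sigmoid(G[, (H + 1):(2 * H), drop = FALSE])
    g_ <- tanh(G[, (2 * H + 1):(3 * H), drop = FALSE])
    o_ <- sigmoid(G[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- c_
    c_ <- f_ * c_prev + i_ * g_
    tc <- tanh(c_)
    h_prev <- h
    h <- o_ * tc
    H_all[, t, ] <- h
    steps[[t]] <- list(i = i_, f = f_, g = g_, o = o_, c = c_, tc = tc,
                       c_prev = c_prev, h_prev = h_prev)
  }
  list(H_all = H_all, hT = h, cache = list(steps = steps, X3 = X3, H = H))
}

# dH_all: (B, m, H) upstream gradient on every hidden state (may be zero);
# dhT adds to position m.
lstm_backward <- function(dH_all, dhT, lstm, cache) {
  X3 <- cache$X3; steps <- cache$steps; H <- cache$H
  B <- dim(X3)[1]; m <- dim(X3)[2]; d <- dim(X3)[3]
  dWx <- matrix(0, d, 4 * H); dWh <- matrix(0, H, 4 * H); db <- numeric(4 * H)
  dX3 <- array(0, c(B, m, d))
  dh_next <- dhT
  dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(m))) {
    st <- steps[[t]]
    dh <- dh_next + matrix(dH_all[, t, ], B)
    do_ <- dh * st$tc
    dc <- dc_next + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dc_next <- dc * st$f
    dG <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    Xt <- matrix(X3[, t, ], B)
    dWx <- dWx + t(Xt) %*% dG
    dWh <- dWh + t(st$h_prev) %*% dG
    db <- db + colSums(dG)
    dX3[, t, ] <- dG %*% t(lstm$Wx)
    dh_next <- dG %*% t(lstm$Wh)
  }
  list(dX3 = dX3, grads = list(Wx = dWx, Wh = dWh, b = db))
}

## additive (Bahdanau-style) attention pooling over a sequence ------------

attnpool_forward <- function(S3, pool) {
  B <- dim(S3)[1]; m <- dim(S3)[2]; w <- dim(S3)[3]
  Sm <- matrix(S3, B * m, w)
  E <- tanh(sweep(Sm %*% pool$Wa, 2L, pool$ba, "+"))   # (B*m) x a
  e <- matrix(E %*% pool$va, B, m)
  alpha <- row_softmax(e)
  pooled <- matrix(0, B, w)
  for (i in seq_len(m)) pooled <- pooled + alpha[, i] * matrix(S3[, i, ], B)
  list(pooled = pooled, alpha = alpha,
       cache = list(Sm = Sm, E = E, alpha = alpha, B = B, m = m, w = w))
}

attnpool_backward <- function(dPooled, S3, pool, cache) {
  B <- cache$B; m <- cache$m; w <- cache$w
  alpha <- cache$alpha
  dAlpha <- matrix(0, B, m)
  dS3 <- array(0, c(B, m, w))
  for (i in seq_len(m)) {
    Si <- matrix(S3[, i, ], B)
    dAlpha[, i] <- rowSums(Si * dPooled)
    dS3[, i, ] <- alpha[, i] * dPooled
  }
  de <- alpha * (dAlpha - rowSums(alpha * dAlpha))
  # e[b,i] = E[r, ] %*% va with row r = b + B*(i-1); as.vector(de) follows
  # the same column-major ordering.
  dEm <- outer(as.vector(de), pool$va)
  dva <- as.numeric(t(cache$E) %*% as.vector(de))
  dpre <- dEm * (1 - cache$E^2)
  dWa <- t(cache$Sm) %*% dpre
  dba <- colSums(dpre)
  dSm <- dpre %*% t(pool$Wa)
  dS3 <- dS3 + array(dSm, c(B, m, w))
  list(dS3 = dS3, grads = list(Wa = dWa, ba = dba, va = dva))
}

## Cross-Attention Attribution Layer --------------------------------------

# Per head: score_i = (A_T W_F)_i . (h_T W_L); A_C = softmax over the m
# feature scores; context = sum_i A_C[i] (A_T W_F)_i.  Heads concatenated.
caal_forward <- function(AT3, hT, heads) {
  B <- dim(AT3)[1]; m <- dim(AT3)[2]; d <- dim(AT3)[3]
  ATm <- matrix(AT3, B * m, d)
  n_heads <- length(heads)
  AC <- vector("list", n_heads); ctx <- vector("list", n_heads)
  caches <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    WF <- heads[[h]]$WF; WL <- heads[[h]]$WL
    a <- ncol(WF)
    F3 <- array(ATm %*% WF, c(B, m, a))
    l <- hT %*% WL                                     # B x a
    s <- matrix(0, B, m)
    for (i in seq_len(m)) s[, i] <- rowSums(matrix(F3[, i, ], B) * l)
    A <- row_softmax(s)
    cx <- matrix(0, B, a)
    for (i in seq_len(m)) cx <- cx + A[, i] * matrix(F3[, i, ], B)
    AC[[h]] <- A; ctx[[h]] <- cx
    caches[[h]] <- list(F3 = F3, l = l, A = A)
  }
  list(AC = AC, context = do.call(cbind, ctx),
       cache = list(heads = caches, ATm = ATm, B = B, m = m, d = d))
}

# dContext: gradient on the concatenated context; dAC: list (per head) of
# gradients on the attribution weights (e.g. from the entropy regularizer),
# or NULL.
caal_backward <- function(dContext, dAC, heads, hT, cache) {
  B <- cache$B; m <- cache$m; d <- cache$d
  n_heads <- length(heads)
  dATm <- matrix(0, B * m, d)
  dhT <- matrix(0, B, ncol(hT))
  grads <- vector("list", n_heads)
  col0 <- 0L
  for (h in seq_len(n_heads)) {
    WF <- heads[[h]]$WF; WL <- heads[[h]]$WL
    a <- ncol(WF)
    ch <- cache$heads[[h]]
    dcx <- dContext[, (col0 + 1L):(col0 + a), drop = FALSE]
    col0 <- col0 + a
    dA <- if (is.null(dAC)) matrix(0, B, m) else dAC[[h]]
    dF3 <- array(0, c(B, m, a))
    for (i in seq_len(m)) {
      Fi <- matrix(ch$F3[, i, ], B)
      dA[, i] <- dA[, i] + rowSums(Fi * dcx)
      dF3[, i, ] <- ch$A[, i] * dcx
    }
    ds <- ch$A * (dA - rowSums(ch$A * dA))
    dl <- matrix(0, B, a)
    for (i in seq_len(m)) {
      dF3[, i, ] <- dF3[, i, ] + ds[, i] * ch$l
      dl <- dl + ds[, i] * matrix(ch$F3[, i, ], B)
    }
    dFm <- matrix(dF3, B * m, a)
    grads[[h]] <- list(WF = t(cache$ATm) %*% dFm, WL = t(hT) %*% dl)
    dATm <- dATm + dFm %*% t(WF)
    dhT <- dhT + dl %*% t(WL)
  }
  list(dAT3 = array(dATm, c(B, m, d)), dhT = dhT, grads = grads)
}

## softmax classifier head and loss ---------------------------------------

classify_forward <- function(fused, cls) {
  logits <- sweep(fused %*% cls$W, 2L, cls$b, "+")
  row_softmax(logits)
}

# Mean cross-entropy (natural log) plus lambda_xai times the mean Shannon
# entropy (bits) of the attribution heads.  y: integer class in 1..K.
caal_loss_forward <- function(p, y, AC = NULL, lambda_xai = 0) {
  B <- nrow(p)
  py <- p[cbind(seq_len(B), y)]
  if (any(py <= 0)) py <- pmax(py, 1e-12)
  ce <- -mean(log(py))
  reg <- 0
  if (lambda_xai > 0 && length(AC)) {
    hb <- vapply(AC, function(A) {
      Ac <- pmax(A, 1e-12)
      mean(-rowSums(Ac * log2(Ac)))
    }, numeric(1))
    reg <- lambda_xai * mean(hb)
  }
  list(loss = ce + reg, ce = ce, reg = reg)
}

# Gradient of the mean CE w.r.t. the classifier logits.
ce_logit_grad <- function(p, y) {
  B <- nrow(p)
  d <- p
  d[cbind(seq_len(B), y)] <- d[cbind(seq_len(B), y)] - 1
  d / B
}

# Gradient of the attribution-entropy regularizer w.r.t. each head's A_C.
entropy_reg_grad <- function(AC, lambda_xai) {
  if (lambda_xai <= 0 || !length(AC)) return(NULL)
  B <- nrow(AC[[1]])
  k <- length(AC)
  lapply(AC, function(A) {
    Ac <- pmax(A, 1e-12)
    -(log2(Ac) + 1 / log(2)) * lambda_xai / (k * B)
  })
}
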