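test_that("scalar tokenization is linear and feature-local", {
  cfg <- tiny_config()
  m <- build_variant("E6", cfg)
  tok <- m$params$tok              # biases initialize to zero
  Z <- caalrisk:::tokenize_forward(matrix(0, 2, 10), tok)
  expect_equal(max(abs(Z)), 0)
  x <- matrix(rnorm(10), 1, 10)
  t1 <- caalrisk:::tokenize_forward(x, tok)
  x2 <- x; x2[1, 4] <- 2 * x2[1, 4]
  t2 <- caalrisk:::tokenize_forward(x2, tok)
  expect_equal(t2[1, 4, ], 2 * t1[1, 4, ])
  expect_equal(t2[1, -4, ], t1[1, -4, ])
  cfg32 <- caal_config(d_token = 32L, n_heads = 4L)
  m32 <- build_variant("E6", cfg32)
  t32 <- caalrisk:::tokenize_forward(matrix(rnorm(10), 1, 10), m32$params$tok)
  expect_equal(dim(t32), c(1L, 10L, 32L))
})

test_that("positional addend follows the base-10 sine form exactly", {
  expect_equal(caalrisk:::pe_addend(0, 8), 0)
  expect_equal(caalrisk:::pe_addend(1, 4), sin(1 / 10^0.5))
  expect_equal(caalrisk:::pe_addend(1, 4), 0.31097, tolerance = 1e-4)
  # additive, not idempotent
  tk <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  once <- caalrisk:::positional_encode(tk)
  twice <- caalrisk:::positional_encode(once)
  expect_false(isTRUE(all.equal(once[, 2, ], twice[, 2, ])))
  expect_equal(twice[, 2, ] - once[, 2, ],
               matrix(caalrisk:::pe_addend(1, 4), 2, 4))
  # canonical variant differs and fills sine/cosine pairs
  can <- caalrisk:::pe_canonical(3, 8)
  expect_equal(can[1], sin(3))
  expect_equal(can[2], cos(3))
})

test_that("self-attention obeys the softmax contracts", {
  cfg <- tiny_config()
  layer <- build_variant("E6", cfg)$params$trans[[1]]
  # identical tokens give uniform attention rows
  X3 <- array(rep(rnorm(8), each = 2 * 10), c(2, 10, 8))
  for (i in 1:10) X3[, i, ] <- X3[, 1, ]
  res <- caalrisk:::attn_layer_forward(X3, layer, cfg$n_heads)
  expect_equal(max(abs(res$cache$P - 0.1)), 0, tolerance = 1e-12)
  # any input: rows sum to 1
  X3 <- array(rnorm(2 * 10 * 8), c(2, 10, 8))
  res <- caalrisk:::attn_layer_forward(X3, layer, cfg$n_heads)
  sums <- apply(res$cache$P, c(1, 2, 3), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-6)
  # hand case: zero Q/K, identity V and output, no FFN -> the attention
  # contribution (out - residual) is the token column mean at every row
  d <- 8
  layer0 <- list(Wq = matrix(0, d, d), Wk = matrix(0, d, d), Wv = diag(d),
                 Wo = diag(d), W1 = matrix(0, d, 4), b1 = numeric(4),
                 W2 = matrix(0, 4, d), b2 = numeric(d))
  res0 <- caalrisk:::attn_layer_forward(X3, layer0, 1L)
  mean_tok <- apply(X3[1, , ], 2, mean)
  for (i in 1:10)
    expect_equal(res0$out[1, i, ] - X3[1, i, ], mean_tok, tolerance = 1e-12)
})

test_that("d_token must divide evenly into heads", {
  expect_error(caal_config(d_token = 10L, n_heads = 4L), "divisible")
  expect_error(caal_config(d_token = 15L, n_heads = 5L), "even")
})

test_that("the LSTM matches a hand-unrolled gate computation", {
  # 1 unit, 1-wide input, 2 steps, fixed weights
  lstm <- list(Wx = matrix(c(0.5, -0.3, 0.8, 0.2), 1, 4),
               Wh = matrix(c(0.1, 0.4, -0.2, 0.3), 1, 4),
               b = c(0.05, -0.1, 0.2, 0))
  x <- c(1, -0.5)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- 0; cc <- 0
  for (t in 1:2) {
    g <- x[t] * lstm$Wx[1, ] + h * lstm$Wh[1, ] + lstm$b
    i_ <- sig(g[1]); f_ <- sig(g[2]); gg <- tanh(g[3]); o_ <- sig(g[4])
    cc <- f_ * cc + i_ * gg
    h <- o_ * tanh(cc)
  }
  X3 <- array(x, c(1, 2, 1))
  out <- caalrisk:::lstm_forward(X3, lstm)
  expect_equal(out$hT[1, 1], h, tolerance = 1e-12)
  # zero input and zero biases fix the zero state
  lstm0 <- lstm; lstm0$b <- numeric(4)
  z <- caalrisk:::lstm_forward(array(0, c(1, 5, 1)), lstm0)
  expect_equal(max(abs(z$hT)), 0)
  # order sensitivity for generic weights
  cfg <- tiny_config()
  mp <- build_variant("E1", cfg)$params$lstm
  X <- array(rnorm(1 * 10 * 8), c(1, 10, 8))
  Xp <- X[, 10:1, , drop = FALSE]
  h1 <- caalrisk:::lstm_forward(X, mp)$hT
  h2 <- caalrisk:::lstm_forward(Xp, mp)$hT
  expect_gt(max(abs(h1 - h2)), 1e-6)
})

test_that("cross-attention attribution weights form a simplex", {
  cfg <- tiny_config()
  m <- build_variant("E6", cfg)
  AT3 <- array(rnorm(4 * 10 * 8), c(4, 10, 8))
  hT <- matrix(rnorm(4 * 6), 4, 6)
  cf <- caalrisk:::caal_forward(AT3, hT, m$params$caal)
  for (A in cf$AC) {
    expect_equal(rowSums(A), rep(1, 4), tolerance = 1e-6)
    expect_true(all(A >= 0))
  }
  # zero summary projection makes every score equal: uniform attribution
  heads0 <- lapply(m$params$caal, function(h) {
    h$WL <- h$WL * 0; h
  })
  cf0 <- caalrisk:::caal_forward(AT3, hT, heads0)
  expect_equal(max(abs(cf0$AC[[1]] - 0.1)), 0, tolerance = 1e-12)
  # a +30 logit dominates the softmax
  s <- c(30, rep(0, 9))
  p <- caalrisk:::row_softmax(matrix(s, 1))
  expect_gt(p[1], 0.999)
})

test_that("the classifier head produces calibrated softmax outputs", {
  cls0 <- list(W = matrix(0, 5, 3), b = numeric(3))
  p <- caalrisk:::classify_forward(matrix(rnorm(5), 1), cls0)
  expect_equal(as.numeric(p), rep(1 / 3, 3))
  cls1 <- list(W = matrix(0, 5, 3), b = c(10, 0, 0))
  p1 <- caalrisk:::classify_forward(matrix(rnorm(5), 1), cls1)
  expect_gt(p1[1], 0.9999)
  expect_equal(rowSums(p1), 1, tolerance = 1e-12)
  expect_true(all(p1 > 0))
})

test_that("the loss combines cross-entropy with the attribution penalty", {
  expect_equal(caal_loss(matrix(c(1, 0, 0), 1), 1L), 0)
  expect_equal(caal_loss(matrix(1 / 3, 1, 3), 2L), log(3), tolerance = 1e-12)
  AC <- list(matrix(0.1, 1, 10))
  expect_equal(caal_loss(matrix(c(1, 0, 0), 1), 1L, A_C = AC,
                         lambda_xai = 0.1),
               0.1 * log2(10), tolerance = 1e-12)
  expect_message(caal_loss(matrix(c(0, 1, 0), 1), 1L), "clamping")
})

test_that("backpropagation matches finite differences on every variant", {
  set.seed(99)
  X <- matrix(rnorm(3 * 10), 3, 10)
  y <- c(1L, 3L, 2L)
  for (v in paste0("E", 1:6)) {
    m <- build_variant(v, tiny_config(lambda_xai = 0.1))
    err <- caalrisk:::grad_check(m, X, y, n_checks = 25, seed = 7)
    expect_lt(err, 1e-3)
  }
  madd <- build_variant("E6", tiny_config(fusion = "add", lambda_xai = 0.2))
  expect_lt(caalrisk:::grad_check(madd, X, y, n_checks = 25, seed = 8), 1e-3)
})

test_that("ablation variants have the documented structure", {
  cfg <- tiny_config()
  e1 <- build_variant("E1", cfg)
  expect_null(e1$params$trans)
  expect_false(is.null(e1$params$lstm))
  e3 <- build_variant("E3", cfg)
  expect_null(e3$params$lstm)
  e4 <- build_variant("E4", cfg)
  e6 <- build_variant("E6", cfg)
  expect_gt(n_params(e6), n_params(e4))
  expect_error(build_variant("E7", cfg), "unknown variant")
})

test_that("all six variants run the training harness on a small fixture", {
  ps <- prep_split(generator_spec(n = 200, seed = 21))
  for (v in paste0("E", 1:6)) {
    cfg <- tiny_config(seed = 21, max_epochs = 2L, batch_size = 32L)
    m <- train_caal(build_variant(v, cfg), ps$train, ps$test)
    expect_true(m$trained)
    expect_equal(nrow(m$history), 2L)
    pred <- predict(m, ps$test)
    expect_equal(length(pred), cohort_size(ps$test))
  }
})

test_that("training reduces the loss and is seed-deterministic", {
  ps <- prep_split(generator_spec(n = 600, seed = 31))
  cfg <- tiny_config(seed = 31, max_epochs = 10L, patience = 10L,
                     lambda_xai = 0)   # plain cross-entropy: comparable epochs
  m <- train_caal(build_variant("E6", cfg), ps$train)
  expect_lt(m$history$train_loss[nrow(m$history)], m$history$train_loss[1])
  m2 <- train_caal(build_variant("E6", cfg), ps$train)
  expect_identical(m$params, m2$params)
  expect_identical(m$history, m2$history)
})

test_that("a strong sharpness penalty lowers the attribution entropy", {
  ps <- prep_split(generator_spec(n = 200, seed = 41))
  mk <- function(lam) {
    cfg <- tiny_config(seed = 41, max_epochs = 8L, lambda_xai = lam,
                       lambda_warmup = 0L)
    train_caal(build_variant("E6", cfg), ps$train)
  }
  m0 <- mk(0); mH <- mk(10)
  ac_entropy <- function(m) {
    X <- caalrisk:::as_model_matrix(ps$test, m)$X
    fw <- caalrisk:::model_forward(m, X)
    mean(vapply(fw$AC, function(A) {
      A <- pmax(A, 1e-12); mean(-rowSums(A * log2(A)))
    }, numeric(1)))
  }
  expect_lt(ac_entropy(mH), ac_entropy(m0))
})

test_that("forward traces expose every intermediate with valid simplices", {
  ps <- prep_split(generator_spec(n = 200, seed = 51))
  cfg <- tiny_config(seed = 51, max_epochs = 2L)
  m <- train_caal(build_variant("E6", cfg), ps$train)
  X <- caalrisk:::as_model_matrix(ps$test, m)$X
  tr <- forward_trace(m, X[1, ])
  expect_equal(dim(tr$tokens), c(10L, 8L))
  expect_equal(dim(tr$A_T), c(10L, 8L))
  for (P in tr$attn_weights) expect_equal(rowSums(P), rep(1, 10),
                                          tolerance = 1e-6)
  for (a in tr$A_C) expect_equal(sum(a), 1, tolerance = 1e-6)
  expect_equal(sum(tr$y_hat), 1, tolerance = 1e-6)
  expect_equal(length(tr$h_T), 6L)
  # tokens outside the normalized range raise the contract warning
  expect_warning(caalrisk:::model_forward(m, matrix(25, 1, 10)), "normalize")
})

test_that("off-grid hyperparameters are flagged, not rejected", {
  cfg <- caal_config(learning_rate = 3e-3)
  expect_true("learning_rate" %in% cfg$off_grid)
  expect_false("n_heads" %in% cfg$off_grid)
})
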