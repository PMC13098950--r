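test_that("one-way ANOVA matches the sum-of-squares oracle and base R", {
  # hand fixture: groups (0,0,2,2) vs (2,2,4,4) -> SSb known
  r <- anova_oneway(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r$statistic, 0)
  set.seed(1)
  for (rep_i in 1:30) {
    g <- rep(letters[1:3], times = sample(3:8, 3, replace = TRUE))
    v <- rnorm(length(g), mean = as.integer(factor(g)) * runif(1))
    mine <- anova_oneway(v, g)
    ref <- summary(aov(v ~ factor(g)))[[1]]
    expect_equal(mine$statistic, ref[["F value"]][1], tolerance = 1e-8)
    expect_equal(mine$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-8)
  }
  sep <- anova_oneway(c(0, 0, 0, 1, 1, 1) + rnorm(6, 0, 1e-9),
                      rep(c("a", "b"), each = 3))
  expect_lt(sep$p_value, 0.001)
  r0 <- anova_oneway(c(0, 0, 0, 1, 1, 1), rep(c("a", "b"), each = 3))
  expect_true(is.infinite(r0$statistic))
  expect_error(anova_oneway(1:4, rep("a", 4)), "2 groups")
})

test_that("ANOVA reproduces a hand-computed F from its pieces", {
  # groups a=(1,3), b=(5,7), c=(2,4): grand mean 22/6
  v <- c(1, 3, 5, 7, 2, 4)
  g <- rep(c("a", "b", "c"), each = 2)
  gm <- mean(v)
  ssb <- sum(2 * (tapply(v, g, mean) - gm)^2)
  ssw <- sum((v - rep(tapply(v, g, mean), each = 2))^2)
  expect_equal(anova_oneway(v, g)$statistic, (ssb / 2) / (ssw / 3))
})

test_that("chi-square matches hand values and base R without correction", {
  expect_equal(chi_square_test(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  expect_equal(chi_square_test(matrix(c(20, 0, 0, 20), 2))$statistic, 40)
  set.seed(2)
  for (rep_i in 1:30) {
    x <- sample(letters[1:3], 80, replace = TRUE)
    y <- sample(LETTERS[1:4], 80, replace = TRUE)
    tab <- table(x, y)
    if (any(outer(rowSums(tab), colSums(tab)) == 0)) next
    mine <- chi_square_test(x, y)
    ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
    expect_equal(mine$df, unname(ref$parameter))
  }
  # permutation invariance
  tab <- matrix(c(5, 9, 7, 11, 3, 6), 2)
  expect_equal(chi_square_test(tab)$statistic,
               chi_square_test(tab[2:1, c(2, 3, 1)])$statistic)
  expect_error(chi_square_test(matrix(c(1, 1, 0, 0), 2)), "expected count 0")
})

test_that("Wilcoxon signed ranks match the definition and base R", {
  r <- wilcoxon_signed_rank(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$statistic, 6)        # differences +1,+2,+3: all ranks +
  same <- wilcoxon_signed_rank(1:5, 1:5)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  set.seed(3)
  for (rep_i in 1:30) {
    n <- sample(c(8, 15, 40), 1)
    x <- rnorm(n); y <- rnorm(n, 0.3)
    mine <- wilcoxon_signed_rank(x, y)
    d <- x - y
    # W = 2V - n(n+1)/2 against base R's V
    ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = TRUE,
                                        correct = FALSE))
    expect_equal(mine$statistic,
                 2 * unname(ref$statistic) - n * (n + 1) / 2,
                 tolerance = 1e-8)
    if (n <= 25) expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
  }
  # antisymmetry
  set.seed(4)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(x, y)$statistic,
               -wilcoxon_signed_rank(y, x)$statistic)
})

test_that("Friedman statistic follows the rank-sum plug-in formula", {
  # identical rankings in 10 blocks of 3 treatments
  R <- matrix(rep(c(1, 2, 3), 10), 10, byrow = TRUE)
  expect_equal(friedman_rank_test(R)$statistic,
               12 / (10 * 3 * 4) * (100 + 400 + 900) - 3 * 10 * 4)
  expect_equal(friedman_rank_test(R)$statistic, 20)
  # balanced column sums: zero statistic
  Rb <- rbind(c(1, 2, 3), c(2, 3, 1), c(3, 1, 2))
  expect_equal(friedman_rank_test(Rb)$statistic, 0, tolerance = 1e-12)
  # block-permutation invariance
  set.seed(5)
  X <- matrix(rnorm(8 * 4), 8)
  expect_equal(friedman_rank_test(X)$statistic,
               friedman_rank_test(X[sample(8), ])$statistic)
  # against base R on random data
  for (rep_i in 1:30) {
    X <- matrix(rnorm(6 * 3), 6)
    mine <- friedman_rank_test(X)
    ref <- friedman.test(X)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-8)
  }
  expect_error(friedman_rank_test(matrix(1, 3, 1)), "2 treatments")
})

test_that("Diebold-Mariano standardizes the mean loss differential", {
  x <- rnorm(50)
  expect_equal(diebold_mariano(x, x)$statistic, 0)
  # CLT oracle: iid differences with known mean and sd
  set.seed(6)
  T_ <- 1e4
  a <- rnorm(T_, 0.2, 1); b <- rnorm(T_, 0, 1)
  dm <- diebold_mariano(a, b)
  d <- a - b
  expect_lt(abs(dm$statistic - mean(d) * sqrt(T_) / sd(d)), 0.01)
  # antisymmetry
  expect_equal(diebold_mariano(a, b)$statistic,
               -diebold_mariano(b, a)$statistic)
  # longer horizon includes autocovariances
  set.seed(7)
  e <- as.numeric(arima.sim(list(ma = 0.8), 500))
  dm1 <- diebold_mariano(e + 0.1, numeric(500), horizon = 1)
  dm3 <- diebold_mariano(e + 0.1, numeric(500), horizon = 3)
  expect_false(isTRUE(all.equal(dm1$statistic, dm3$statistic)))
  expect_error(diebold_mariano(1:5, 1:5), "at least 10")
  deg <- diebold_mariano(rep(1, 20), rep(0, 20))
  expect_equal(deg$flag, "degenerate long-run variance")
})

test_that("the per-feature battery covers the schema and finds the signal", {
  ps <- prep_split(generator_spec(n = 400, seed = 91))
  cfg <- tiny_config(seed = 91, max_epochs = 15L)
  m <- train_caal(build_variant("E6", cfg), ps$train)
  bl <- baseline_logistic(ps$train, ps$test)
  bat <- feature_significance_battery(m, ps$test, baseline_prob = bl$prob,
                                      seed = 2)
  expect_equal(nrow(bat$feature_tests), 10L)
  expect_setequal(bat$feature_tests$feature, cohort_order(ps$train))
  expect_equal(bat$feature_tests$test[bat$feature_tests$feature == "gender"],
               "chi2")
  cont <- bat$feature_tests[bat$feature_tests$test == "anova", ]
  top <- cont$feature[order(-cont$statistic)][1:2]
  expect_setequal(top, c("anxiety", "depression"))
  expect_true(all(c("wilcoxon", "friedman", "dm_baseline") %in%
                  names(bat$model_tests)))
  expect_true(all(vapply(bat$model_tests, function(t)
    t$p_value >= 0 && t$p_value <= 1, logical(1))))
})
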