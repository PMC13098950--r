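test_that("CSV round trip preserves records and values exactly", {
  df <- tiny_cohort_df(5)
  path <- write_tiny_csv(df)
  co <- read_cohort(path)
  expect_s3_class(co, "cohort")
  expect_equal(cohort_size(co), 5L)
  out <- tempfile(fileext = ".csv")
  write_cohort(co, out)
  co2 <- read_cohort(out)
  for (cl in c("anxiety", "depression", "sleep_hours"))
    expect_identical(co$data[[cl]], co2$data[[cl]])
  expect_identical(co$data$gender, co2$data$gender)
})

test_that("schema violations are rejected with useful messages", {
  df <- tiny_cohort_df(4)
  df$gender[2] <- "robot"
  expect_error(read_cohort(write_tiny_csv(df)), "row 2.*robot")
  df2 <- tiny_cohort_df(4)[, -1]
  expect_error(read_cohort(write_tiny_csv(df2)), "anxiety")
  empty <- tempfile(fileext = ".csv")
  writeLines(paste(names(tiny_cohort_df(1)), collapse = ","), empty)
  expect_error(read_cohort(empty), "empty")
})

test_that("unparseable numerics are flagged and set missing", {
  df <- tiny_cohort_df(3)
  df$sleep_hours <- as.character(df$sleep_hours)
  df$sleep_hours[2] <- "eight"
  expect_warning(co <- read_cohort(write_tiny_csv(df)), "row.*2")
  expect_true(is.na(co$data$sleep_hours[2]))
})

test_that("imputation fills continuous gaps with the fitted median", {
  df <- tiny_cohort_df(3)
  df$sleep_hours <- c(7, NA, 9)
  co <- new_cohort(df)
  enc <- impute_and_encode(co)
  expect_equal(enc$data$sleep_hours, c(7, 8, 9))
  # training medians applied to held-out data
  df2 <- tiny_cohort_df(2, seed = 9)
  df2$sleep_hours <- c(NA, 5)
  enc2 <- impute_and_encode(new_cohort(df2), medians = enc$medians)
  expect_equal(enc2$data$sleep_hours[1], 8)
  all_na <- tiny_cohort_df(3)
  all_na$anxiety <- NA_real_
  expect_error(impute_and_encode(new_cohort(all_na)), "anxiety")
})

test_that("categorical encoding follows the fixed dictionaries", {
  df <- tiny_cohort_df(3)
  df$gender <- c("female", "male", "male")
  enc <- impute_and_encode(new_cohort(df))
  expect_equal(enc$data$gender, c(0L, 1L, 1L))
  df$gender <- c("female", "male", "male")
  enc_again <- impute_and_encode(new_cohort(df))
  expect_identical(enc$data$gender, enc_again$data$gender)
})

test_that("normalization standardizes on the fitting split only", {
  df <- tiny_cohort_df(20)
  tr <- normalize_cohort(impute_and_encode(new_cohort(df)))
  for (cl in c("anxiety", "depression", "age")) {
    expect_lt(abs(mean(tr$data[[cl]])), 1e-9)
    expect_lt(abs(sd(tr$data[[cl]]) - 1), 1e-9)
  }
  # hand z-score on a fresh column
  dfx <- tiny_cohort_df(3)
  dfx$anxiety <- c(1, 2, 3)
  trx <- normalize_cohort(impute_and_encode(new_cohort(dfx)))
  expect_equal(trx$data$anxiety, c(-1, 0, 1), tolerance = 1e-12)
  # held-out transform reuses training stats, never refits
  te <- tiny_cohort_df(7, seed = 5)
  ten <- normalize_cohort(impute_and_encode(new_cohort(te)),
                          stats = tr$norm_stats)
  k <- match("anxiety", tr$norm_stats$feature)
  expect_equal(ten$data$anxiety,
               (te$anxiety - tr$norm_stats$mean[k]) / tr$norm_stats$sd[k])
  # categorical codes are never z-scaled
  expect_true(all(tr$data$gender %in% 0:3))
})

test_that("zero-variance features are centered with a warning", {
  df <- tiny_cohort_df(5)
  df$stress_level <- rep(5, 5)
  expect_warning(tr <- normalize_cohort(impute_and_encode(new_cohort(df))),
                 "stress_level")
  expect_equal(tr$data$stress_level, rep(0, 5))
})

test_that("percentile labels split distinct composites into exact terciles", {
  df <- tiny_cohort_df(9)
  df$anxiety <- 1:9
  df$depression <- 1:9          # composite strictly increasing
  co <- assign_percentile_labels(new_cohort(df))
  expect_equal(as.numeric(table(co$data$risk_label)), c(3, 3, 3))
  expect_equal(as.character(co$data$risk_label[1:3]), rep("Low", 3))
  expect_equal(as.character(co$data$risk_label[7:9]), rep("High", 3))
})

test_that("degenerate and small labeling cases are handled", {
  df <- tiny_cohort_df(5)
  df$anxiety <- rep(3, 5)
  df$depression <- rep(4, 5)
  expect_warning(co <- assign_percentile_labels(new_cohort(df)), "degenerate")
  expect_equal(length(unique(co$data$risk_label)), 1L)
  expect_error(assign_percentile_labels(new_cohort(tiny_cohort_df(2))),
               "fewer than 3")
})

test_that("percentile labeling is invariant to monotone composite transforms", {
  df <- tiny_cohort_df(60, seed = 7)
  base <- assign_percentile_labels(new_cohort(df))
  mono <- assign_percentile_labels(new_cohort(df),
    composite = function(za, zd, d) exp((za + zd) / 2))
  expect_identical(base$data$risk_label, mono$data$risk_label)
})

test_that("stratified split respects per-class proportions and determinism", {
  df <- tiny_cohort_df(300, seed = 2)
  co <- assign_percentile_labels(new_cohort(df))
  sp <- stratified_split(co, 0.2, seed = 42)
  expect_equal(cohort_size(sp$train) + cohort_size(sp$test), 300L)
  cls_all <- table(co$data$risk_label)
  cls_test <- table(sp$test$data$risk_label)
  for (cl in names(cls_all))
    expect_lte(abs(cls_test[[cl]] - 0.2 * cls_all[[cl]]), 1)
  sp2 <- stratified_split(co, 0.2, seed = 42)
  expect_identical(sp$test$data, sp2$test$data)
  sp0 <- stratified_split(co, 0, seed = 1)
  expect_equal(cohort_size(sp0$test), 0L)
  tiny <- co; tiny$data <- tiny$data[c(1, which(co$data$risk_label == "High")[1:2]), ]
  expect_error(stratified_split(tiny, 0.2), "at least 2")
})

test_that("the three orderings permute category blocks as documented", {
  co <- new_cohort(tiny_cohort_df(3))
  o3 <- order_features(co, "order3")
  expect_equal(cohort_order(o3)[1], "anxiety")
  expect_equal(cohort_order(o3),
               c("anxiety", "depression", "stress_level", "social_support",
                 "productivity", "sleep_hours", "physical_activity_days",
                 "age", "gender", "employment"))
  o1 <- order_features(co, "order1")
  # order1 reverses the category blocks of order3
  expect_equal(cohort_order(o1),
               c(cohort_order(o3)[8:10], cohort_order(o3)[5:7],
                 cohort_order(o3)[1:4]))
  expect_identical(cohort_order(order_features(o3, "order3")),
                   cohort_order(o3))
  expect_error(order_features(co, "order9"), "unknown ordering")
})

test_that("preprocessing sidecar round-trips through JSON", {
  tr <- normalize_cohort(impute_and_encode(new_cohort(tiny_cohort_df(10))))
  path <- tempfile(fileext = ".json")
  save_preprocess(tr, path)
  js <- load_preprocess(path)
  expect_equal(js$norm_stats$mean, tr$norm_stats$mean)
  expect_equal(js$dictionaries$gender[["male"]], 1)
})
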