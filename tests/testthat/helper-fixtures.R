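# Shared fixtures: tiny cohorts and a small model configuration used by
# several test files. Everything is generated in code, seeded.

tiny_config <- function(seed = 3L, ...) {
  caal_config(d_token = 8L, n_heads = 2L, n_layers = 2L, ffn_dim = 16L,
              lstm_units = 6L, attention_dim = 5L, caal_heads = 2L,
              dropout = 0, seed = seed, ...)
}

# a small labeled raw cohort data frame in schema form
tiny_cohort_df <- function(n = 30L, seed = 1L) {
  set.seed(seed)
  data.frame(
    anxiety = round(runif(n, 0, 21), 1),
    depression = round(runif(n, 0, 27), 1),
    productivity = round(runif(n, 0, 10), 1),
    social_support = round(runif(n, 0, 10), 1),
    sleep_hours = round(runif(n, 3, 12), 1),
    age = sample(18:60, n, replace = TRUE),
    stress_level = round(runif(n, 0, 10), 1),
    physical_activity_days = sample(0:7, n, replace = TRUE),
    employment = sample(c("employed", "student", "unemployed"), n, TRUE),
    gender = sample(c("female", "male", "non-binary", "prefer-not-to-say"),
                    n, TRUE),
    stringsAsFactors = FALSE)
}

write_tiny_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# preprocessed train/test pair from the generator
prep_split <- function(spec, test_fraction = 0.2, ordering = "order3") {
  co <- order_features(generate_cohort(spec), ordering)
  sp <- stratified_split(co, test_fraction, seed = spec$seed)
  tr <- normalize_cohort(impute_and_encode(sp$train))
  te <- normalize_cohort(impute_and_encode(sp$test, medians = tr$medians),
                         stats = tr$norm_stats)
  list(train = tr, test = te)
}
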