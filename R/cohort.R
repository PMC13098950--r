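# Cohort container and preprocessing: schema, CSV I/O, imputation and
# encoding, z-normalization, percentile risk labeling, stratified
# splitting, and the three psychological feature orderings.

.schema_features <- c("anxiety", "depression", "productivity",
                      "social_support", "sleep_hours", "age", "stress_level",
                      "physical_activity_days", "employment", "gender")
.continuous_features <- c("anxiety", "depression", "productivity",
                          "social_support", "sleep_hours", "stress_level",
                          "physical_activity_days", "age")
.categorical_features <- c("gender", "employment")
.label_col <- "risk_label"
.risk_levels <- c("Low", "Medium", "High")

# fixed alphabetical code dictionaries, persisted with trained models
.dictionaries <- list(
  gender = c("female" = 0L, "male" = 1L, "non-binary" = 2L,
             "prefer-not-to-say" = 3L),
  employment = c("employed" = 0L, "student" = 1L, "unemployed" = 2L))

# category blocks behind the named orderings
.blocks <- list(
  emotional = c("anxiety", "depression", "stress_level", "social_support"),
  behavioral = c("productivity", "sleep_hours", "physical_activity_days"),
  demographic = c("age", "gender", "employment"))

#' Canonical feature schema
#'
#' The ten psychological, behavioral and demographic features of a student
#' record, with expected ranges. Feature positions are 0-based wherever an
#' index enters a computation (positional encoding).
#'
#' @return data frame with feature, type and expected range.
#' @export
feature_schema <- function() {
  data.frame(
    feature = .schema_features,
    type = ifelse(.schema_features %in% .categorical_features,
                  "categorical", "continuous"),
    min = c(0, 0, 0, 0, 0, 18, 0, 0, NA, NA)[match(.schema_features,
          c("anxiety", "depression", "productivity", "social_support",
            "sleep_hours", "age", "stress_level", "physical_activity_days",
            "employment", "gender"))],
    max = c(21, 27, 10, 10, 14, 80, 10, 7, NA, NA)[match(.schema_features,
          c("anxiety", "depression", "productivity", "social_support",
            "sleep_hours", "age", "stress_level", "physical_activity_days",
            "employment", "gender"))],
    stringsAsFactors = FALSE)
}

#' The three named feature orderings
#'
#' \code{order3} (the model's default) places emotional features first,
#' then behavioral, then demographic; \code{order1} reverses the category
#' blocks (demographic first); \code{order2} starts from the behavioral
#' block.
#'
#' @return named list of three feature-name permutations.
#' @export
feature_orderings <- function() {
  list(order1 = c(.blocks$demographic, .blocks$behavioral, .blocks$emotional),
       order2 = c(.blocks$behavioral, .blocks$emotional, .blocks$demographic),
       order3 = c(.blocks$emotional, .blocks$behavioral, .blocks$demographic))
}

new_cohort <- function(data, feature_order = .schema_features,
                       norm_stats = NULL, dictionaries = .dictionaries,
                       encoded = FALSE, normalized = FALSE, medians = NULL) {
  structure(list(data = data, feature_order = feature_order,
                 norm_stats = norm_stats, dictionaries = dictionaries,
                 encoded = encoded, normalized = normalized,
                 medians = medians),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  lbl <- if (.label_col %in% names(x$data))
    paste(" labeled:", paste(table(x$data[[.label_col]]), collapse = "/"))
  else ""
  cat(sprintf("<cohort: %d records%s%s%s%s>\n", nrow(x$data),
              if (x$encoded) ", encoded" else "",
              if (x$normalized) ", normalized" else "", lbl, ""))
  invisible(x)
}

#' Number of records in a cohort
#' @param x a cohort.
#' @export
cohort_size <- function(x) nrow(x$data)

#' Current feature ordering of a cohort
#' @param x a cohort.
#' @export
cohort_order <- function(x) x$feature_order

#' Read a cohort from CSV
#'
#' Validates the header against the canonical schema (the risk label column
#' is optional), parses numerics, and rejects categorical values outside
#' the closed category sets, naming the offending rows. Unparseable
#' numeric entries are flagged with a warning and set missing so that
#' \code{\link{impute_and_encode}} can fill them.
#'
#' @param path CSV file with a header row.
#' @return a \code{cohort}.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L) stop("input error: empty cohort file ", path)
  missing_cols <- setdiff(.schema_features, names(raw))
  if (length(missing_cols))
    stop("schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- raw
  num_cols <- .continuous_features
  for (cl in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(!is.na(raw[[cl]]) & nzchar(raw[[cl]]) & is.na(v))
    if (length(bad))
      warning(sprintf("column '%s': unparseable numeric at row(s) %s; set missing",
                      cl, paste(bad, collapse = ",")))
    v[!nzchar(raw[[cl]])] <- NA
    out[[cl]] <- v
  }
  for (cl in .categorical_features) {
    v <- raw[[cl]]
    ok <- v %in% names(.dictionaries[[cl]]) | is.na(v) | !nzchar(v)
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(sprintf("closed-set violation in '%s' at row %d: \"%s\"",
                   cl, i, v[i]))
    }
    v[!nzchar(v)] <- NA
    out[[cl]] <- v
  }
  if (.label_col %in% names(raw)) {
    v <- raw[[.label_col]]
    if (!all(v %in% .risk_levels))
      stop("invalid risk labels: ",
           paste(unique(setdiff(v, .risk_levels)), collapse = ", "))
    out[[.label_col]] <- factor(v, levels = .risk_levels)
  }
  new_cohort(out[c(.schema_features,
                   intersect(.label_col, names(out)),
                   setdiff(names(out), c(.schema_features, .label_col)))])
}

#' Write a cohort to CSV
#'
#' Numeric fields are written with 17 significant digits so that a
#' read/write/read round trip reproduces every value exactly.
#'
#' @param cohort a \code{cohort}.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  d <- cohort$data
  for (cl in names(d))
    if (is.numeric(d[[cl]]))
      d[[cl]] <- ifelse(is.na(d[[cl]]), "", sprintf("%.17g", d[[cl]]))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Impute missing values and encode categoricals
#'
#' Continuous gaps are filled with the per-feature median (of the cohort
#' the statistics are fitted on -- pass \code{medians} to apply training
#' medians to held-out data); gender and employment are mapped to integer
#' codes by the package's fixed alphabetical dictionaries. Missing
#' categories take the modal category.
#'
#' @param cohort a \code{cohort}.
#' @param medians optional named numeric vector of training medians.
#' @return the encoded cohort, carrying the medians used.
#' @export
impute_and_encode <- function(cohort, medians = NULL) {
  d <- cohort$data
  used <- if (is.null(medians)) c() else medians
  for (cl in .continuous_features) {
    if (is.null(medians)) {
      md <- stats::median(d[[cl]], na.rm = TRUE)
      if (is.na(md)) stop("feature entirely missing, median undefined: ", cl)
      used[cl] <- md
    } else md <- medians[[cl]]
    d[[cl]][is.na(d[[cl]])] <- md
  }
  for (cl in .categorical_features) {
    dict <- cohort$dictionaries[[cl]]
    v <- d[[cl]]
    if (is.numeric(v)) next                      # already encoded
    if (anyNA(v)) {
      tab <- table(v)
      v[is.na(v)] <- names(tab)[which.max(tab)]
    }
    d[[cl]] <- unname(dict[v])
  }
  out <- cohort
  out$data <- d
  out$encoded <- TRUE
  out$medians <- used
  out
}

#' Z-normalize continuous features
#'
#' Standardizes each continuous feature with mean/sd fitted on the cohort
#' itself (the training split) or, when \code{stats} is supplied, with
#' previously fitted training statistics -- held-out data is never used to
#' fit. Encoded categorical codes are left untouched. A zero-variance
#' feature is centered only, with a warning.
#'
#' @param cohort an encoded \code{cohort}.
#' @param stats optional statistics (data frame feature/mean/sd) fitted on
#'   a training split.
#' @return normalized cohort carrying \code{$norm_stats}.
#' @export
normalize_cohort <- function(cohort, stats = NULL) {
  if (!cohort$encoded) stop("impute_and_encode the cohort first")
  d <- cohort$data
  if (is.null(stats)) {
    stats <- data.frame(feature = .continuous_features,
                        mean = vapply(.continuous_features,
                                      function(cl) mean(d[[cl]]), 0),
                        sd = vapply(.continuous_features,
                                    function(cl) stats::sd(d[[cl]]), 0),
                        stringsAsFactors = FALSE)
  }
  for (k in seq_len(nrow(stats))) {
    cl <- stats$feature[k]
    if (stats$sd[k] == 0 || is.na(stats$sd[k])) {
      warning("zero-variance feature left centered only: ", cl)
      d[[cl]] <- d[[cl]] - stats$mean[k]
    } else {
      d[[cl]] <- (d[[cl]] - stats$mean[k]) / stats$sd[k]
    }
  }
  out <- cohort
  out$data <- d
  out$norm_stats <- stats
  out$normalized <- TRUE
  out
}

#' Assign Low/Medium/High risk labels by percentile stratification
#'
#' The composite distress score is the arithmetic mean of the z-scored
#' anxiety and depression values. Records below the lower tercile cut of
#' the empirical composite distribution are labeled Low, above the upper
#' cut High, Medium otherwise; ties at a cut point go to the lower class.
#'
#' @param cohort a \code{cohort} with anxiety and depression available.
#' @param composite optional function(z_anxiety, z_depression, data) giving
#'   a custom composite score.
#' @return cohort with a \code{risk_label} factor column.
#' @export
assign_percentile_labels <- function(cohort, composite = NULL) {
  d <- cohort$data
  if (nrow(d) < 3L) stop("fewer than 3 rows: percentiles degenerate")
  zs <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) x - mean(x) else (x - mean(x)) / s
  }
  z_anx <- if (cohort$normalized) d$anxiety else zs(d$anxiety)
  z_dep <- if (cohort$normalized) d$depression else zs(d$depression)
  comp <- if (is.null(composite)) (z_anx + z_dep) / 2
          else composite(z_anx, z_dep, d)
  q <- stats::quantile(comp, c(1 / 3, 2 / 3), names = FALSE, type = 7)
  if (q[1] == q[2]) warning("degenerate composite: cut points coincide")
  lab <- ifelse(comp < q[1], "Low", ifelse(comp > q[2], "High", "Medium"))
  out <- cohort
  out$data[[.label_col]] <- factor(lab, levels = .risk_levels)
  out
}

#' Stratified train/test split
#'
#' Draws a seeded test sample per class so that every class's test
#' proportion matches \code{test_fraction} within one record. Train and
#' test are disjoint and exhaustive.
#'
#' @param cohort labeled \code{cohort}.
#' @param test_fraction test proportion in [0, 1); 0 gives an empty test
#'   split.
#' @param seed integer seed; identical seeds reproduce the split.
#' @return list with \code{train} and \code{test} cohorts.
#' @export
stratified_split <- function(cohort, test_fraction = 0.2, seed = 1L) {
  d <- cohort$data
  if (!.label_col %in% names(d)) stop("labels not assigned")
  if (test_fraction < 0 || test_fraction >= 1)
    stop("test_fraction must be in [0, 1)")
  y <- d[[.label_col]]
  if (any(table(y) < 2L)) stop("every class needs at least 2 members")
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    k <- round(length(idx) * test_fraction)
    if (k > 0) test_idx <- c(test_idx, sample(idx, k))
  }
  test_idx <- sort(test_idx)
  mk <- function(rows) {
    out <- cohort
    out$data <- d[rows, , drop = FALSE]
    rownames(out$data) <- NULL
    out
  }
  list(train = mk(setdiff(seq_len(nrow(d)), test_idx)), test = mk(test_idx))
}

#' Apply one of the named feature orderings
#'
#' @param cohort a \code{cohort}.
#' @param ordering \code{"order1"}, \code{"order2"} or \code{"order3"}
#'   (emotional first; the model default), or an explicit permutation of
#'   the ten schema names.
#' @return cohort with \code{feature_order} set (idempotent).
#' @export
order_features <- function(cohort, ordering = "order3") {
  if (is.character(ordering) && length(ordering) == 1L) {
    ords <- feature_orderings()
    if (!ordering %in% names(ords)) stop("unknown ordering: ", ordering)
    ord <- ords[[ordering]]
  } else {
    if (!setequal(ordering, .schema_features) ||
        length(ordering) != length(.schema_features))
      stop("ordering must be a permutation of the 10 schema features")
    ord <- ordering
  }
  cohort$feature_order <- ord
  cohort
}

# Ordered, normalized design matrix plus integer labels (1..3) for the
# network. When a trained model is supplied its stored preprocessing is
# applied to raw cohorts.
as_model_matrix <- function(cohort, model = NULL) {
  co <- cohort
  if (!co$encoded) co <- impute_and_encode(co,
      medians = if (!is.null(model)) NULL else NULL)
  if (!co$normalized) {
    st <- if (!is.null(model)) model$norm_stats else NULL
    co <- normalize_cohort(co, stats = st)
  }
  ord <- if (!is.null(model) && !is.null(model$feature_order))
    model$feature_order else co$feature_order
  X <- as.matrix(co$data[, ord])
  storage.mode(X) <- "double"
  y <- if (.label_col %in% names(co$data))
    as.integer(co$data[[.label_col]]) else NULL
  list(X = X, y = y)
}

#' Persist preprocessing state as a JSON sidecar
#'
#' Writes normalization statistics, imputation medians, category
#' dictionaries and the feature ordering next to a cohort or model so that
#' encodings are stable across runs.
#'
#' @param cohort a preprocessed \code{cohort}.
#' @param path output JSON path.
#' @export
save_preprocess <- function(cohort, path) {
  jsonlite::write_json(list(
    feature_order = cohort$feature_order,
    norm_stats = cohort$norm_stats,
    medians = as.list(cohort$medians),
    dictionaries = lapply(cohort$dictionaries, as.list)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a preprocessing sidecar written by \code{save_preprocess}
#' @param path JSON path.
#' @return list with feature order, normalization stats, medians and
#'   dictionaries.
#' @export
load_preprocess <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  js$norm_stats <- as.data.frame(js$norm_stats)
  js$medians <- unlist(js$medians)
  js$dictionaries <- lapply(js$dictionaries, unlist)
  js
}
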