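# Model persistence: a trained model is written as a single JSON document
# holding the config, every named parameter array (with dimensions), the
# preprocessing state (normalization statistics, imputation medians,
# category dictionaries, feature ordering) and the training history, so a
# checkpoint restores predictions exactly and encodings stay stable across
# runs.

pack_arrays <- function(x) {
  if (is.list(x)) return(lapply(x, pack_arrays))
  list(dim = if (is.null(dim(x))) length(x) else dim(x),
       data = as.numeric(x))
}

unpack_arrays <- function(x) {
  if (is.list(x) && identical(sort(names(x)), c("data", "dim"))) {
    d <- unlist(x$dim)
    v <- unlist(x$data)
    if (length(d) == 1L) return(v)
    return(array(v, dim = d))
  }
  lapply(x, unpack_arrays)
}

# list of per-row lists (unsimplified JSON) -> data frame
rows_to_df <- function(rows) {
  if (is.null(rows) || !length(rows)) return(NULL)
  do.call(rbind, lapply(rows, function(r)
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                  stringsAsFactors = FALSE)))
}

#' Save a trained model checkpoint
#'
#' @param model a trained \code{caal_model}.
#' @param path output JSON path.
#' @export
save_caal <- function(model, path) {
  payload <- list(
    package = "caalrisk", format = 1L,
    variant = model$variant,
    config = unclass(model$config),
    m = model$m, n_classes = model$n_classes,
    trained = model$trained,
    best_epoch = model$best_epoch,
    feature_order = model$feature_order,
    norm_stats = model$norm_stats,
    dictionaries = lapply(model$dictionaries, as.list),
    class_levels = model$class_levels,
    params = pack_arrays(model$params),
    history = model$history)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint written by \code{save_caal}
#'
#' @param path JSON checkpoint path.
#' @return a \code{caal_model} whose predictions match the saved model.
#' @export
load_caal <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(js$package, "caalrisk")) stop("not a caalrisk checkpoint")
  cfg <- lapply(js$config, function(v)
    if (is.list(v)) unlist(v) else v)
  class(cfg) <- "caal_config"
  model <- structure(list(
    variant = js$variant, config = cfg,
    params = unpack_arrays(js$params),
    m = as.integer(js$m), n_classes = as.integer(js$n_classes),
    trained = isTRUE(js$trained),
    best_epoch = js$best_epoch,
    feature_order = unlist(js$feature_order),
    norm_stats = rows_to_df(js$norm_stats),
    dictionaries = lapply(js$dictionaries, function(d) unlist(d)),
    class_levels = unlist(js$class_levels)), class = "caal_model")
  model$history <- rows_to_df(js$history)
  model
}
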