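#' Composite run configuration
#'
#' Bundles the model, search, split and metric parameters together with the
#' global seed and file paths, and round-trips through YAML so a run can be
#' reproduced from its emitted manifest. Per-stage seeds are derived from the
#' global seed with [derive_seed()].
#'
#' @param model A [model_config()].
#' @param search A [shift_search_config()].
#' @param split_scheme,split_index,n_splits Split parameters.
#' @param min_cells,score_threshold,folds Filtering parameters.
#' @param hvg_k,epsilon Metric parameters.
#' @param seed Global seed.
#' @param log_level `"info"` or `"quiet"`.
#' @return A `run_config` list.
#' @export
run_config <- function(model = benchmark_config(),
                       search = shift_search_config(),
                       split_scheme = "out_of_distribution",
                       split_index = 0, n_splits = 5,
                       min_cells = 200, score_threshold = 0.6, folds = 5,
                       hvg_k = 50, epsilon = 0, seed = 1,
                       log_level = "info") {
  structure(list(model = unclass(model), search = unclass(search),
                 split_scheme = split_scheme, split_index = split_index,
                 n_splits = n_splits, min_cells = min_cells,
                 score_threshold = score_threshold, folds = folds,
                 hvg_k = hvg_k, epsilon = epsilon, seed = seed,
                 log_level = log_level),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config()
  cfg[names(raw)] <- raw
  cfg$model <- utils::modifyList(unclass(benchmark_config()), raw$model %||% list())
  class(cfg$model) <- "model_config"
  cfg$search <- utils::modifyList(unclass(shift_search_config()), raw$search %||% list())
  class(cfg$search) <- "shift_search_config"
  cfg
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, drop_nulls)
}

# digest used to stamp artifacts with the config that produced them;
# NULL entries are dropped first so the digest survives YAML round-trips
config_digest <- function(config) {
  ser <- jsonlite::toJSON(drop_nulls(unclass(config)), auto_unbox = TRUE,
                          digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(ser))
  sprintf("%08x", sum(bytes * (seq_along(bytes) %% 997)) %% 4294967296)
}

write_manifest <- function(dir, config, seed, inputs = character(0)) {
  digests <- if (length(inputs) > 0) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("perturbscm")),
         seed = seed, config_digest = config_digest(config),
         config = unclass(config), input_digests = digests),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}
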