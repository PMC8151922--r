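#' Whole-pipeline configuration
#'
#' One object (round-trippable through YAML) drives the full chain:
#' simulate -> extract -> train/evaluate.
#'
#' @param cohort A [cohort_spec()].
#' @param preprocess A [preprocess_config()].
#' @param features A [feature_config()].
#' @param network A [network_config()].
#' @param output_dir Where artifacts land.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            preprocess = preprocess_config(),
                            features = feature_config(),
                            network = network_config(),
                            output_dir = "renotex_output") {
  structure(list(cohort = cohort, preprocess = preprocess,
                 features = features, network = network,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Only keys that differ from the defaults need to appear in the file.
#'
#' @param path YAML file.
#' @return A [pipeline_config()] (read); `path` invisibly (write).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  take <- function(builder, block, extra = list()) {
    args <- block[names(block) %in% names(formals(builder))]
    do.call(builder, utils::modifyList(args %||% list(), extra))
  }
  cohort_block <- y$cohort %||% list()
  if (!is.null(cohort_block$counts))
    cohort_block$counts <- unlist(cohort_block$counts)
  if (!is.null(cohort_block$image_dims))
    cohort_block$image_dims <- unlist(cohort_block$image_dims)
  if (!is.null(y$network$split_fractions))
    y$network$split_fractions <- unlist(y$network$split_fractions)
  pipeline_config(
    cohort = take(cohort_spec, cohort_block),
    preprocess = take(preprocess_config, y$preprocess %||% list()),
    features = take(feature_config, y$features %||% list()),
    network = take(network_config, y$network %||% list()),
    output_dir = y$output_dir %||% "renotex_output")
}

#' @rdname read_pipeline_config
#' @param config A [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(list(
    cohort = cohort_spec_to_list(config$cohort)[
      c("counts", "image_dims", "roi_side", "seed")],
    preprocess = unclass(config$preprocess),
    features = unclass(config$features),
    network = unclass(config$network),
    output_dir = config$output_dir), path)
  invisible(path)
}

#' Simulate and materialize a cohort directory
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress the per-class count summary.
#' @return Path of the manifest CSV, invisibly.
#' @export
run_simulate <- function(config = pipeline_config(), quiet = FALSE) {
  cohort <- generate_cohort(config$cohort)
  dir <- file.path(config$output_dir, "cohort")
  write_cohort(cohort, dir, spec = config$cohort)
  if (!quiet) {
    counts <- table(factor(vapply(cohort, `[[`, "", "label"), CLASS_LEVELS))
    message(sprintf("simulated %d kidneys: %s", length(cohort),
                    paste(names(counts), as.integer(counts),
                          sep = "=", collapse = ", ")))
  }
  invisible(file.path(dir, "manifest.csv"))
}

#' Extract the fused feature table of a cohort directory
#'
#' @param config A [pipeline_config()].
#' @param manifest Manifest CSV path (defaults to the simulate output).
#' @return Path of the feature CSV, invisibly.
#' @export
run_extract <- function(config = pipeline_config(),
                        manifest = file.path(config$output_dir,
                                             "cohort", "manifest.csv")) {
  tab <- extract_cohort_features(manifest, config$preprocess,
                                 config$features, seed = config$cohort$seed)
  path <- file.path(config$output_dir, "features.csv")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(tab, path)
  invisible(path)
}

#' Split, train and evaluate on a feature table
#'
#' Writes the serialized model and one JSON report per partition
#' (train / val / test), and returns the reports.
#'
#' @param config A [pipeline_config()].
#' @param features_path Feature CSV (defaults to the extract output).
#' @return Named list of `eval_report`s, invisibly.
#' @export
run_train_eval <- function(config = pipeline_config(),
                           features_path = file.path(config$output_dir,
                                                     "features.csv")) {
  tab <- read_feature_table(features_path)
  split <- split_data(tab, config$network)
  net <- train_network(tab, split, config$network)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  save_model(net, file.path(config$output_dir, "model.json"))
  reports <- list()
  for (p in c("train", "val", "test")) {
    if (!any(split == p)) next
    reports[[p]] <- evaluate_network(net, tab, p)
    write_eval_report(reports[[p]],
                      file.path(config$output_dir,
                                sprintf("report_%s.json", p)))
  }
  invisible(reports)
}

#' Run the full chain: simulate, extract, train and evaluate
#'
#' In-memory variant (no cohort directory is written unless
#' `materialize = TRUE`), so the end-to-end experiment is a pure function
#' of the configuration.
#'
#' @param config A [pipeline_config()].
#' @param materialize Also write the cohort images and manifest to disk.
#' @return List with the feature `table`, the trained `network` and the
#'   per-partition `reports`.
#' @export
run_all <- function(config = pipeline_config(), materialize = FALSE) {
  cohort <- generate_cohort(config$cohort)
  if (materialize)
    write_cohort(cohort, file.path(config$output_dir, "cohort"),
                 spec = config$cohort)
  tab <- extract_cohort_features(cohort, config$preprocess, config$features,
                                 seed = config$cohort$seed)
  split <- split_data(tab, config$network)
  net <- train_network(tab, split, config$network)
  reports <- list()
  for (p in c("train", "val", "test"))
    if (any(split == p)) reports[[p]] <- evaluate_network(net, tab, p)
  list(table = tab, network = net, reports = reports)
}
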