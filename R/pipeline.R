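#' Assemble a pipeline configuration
#'
#' Collects every stage parameter and seed in one serializable list so a
#' run is fully described by its config: the manifest records the config
#' hash and two runs with equal configs are byte-identical.
#'
#' @param dataset A [planted_dataset_spec()] (or arguments for one, via
#'   `...` when `dataset` is `NULL`).
#' @param provider_args Arguments for [toy_attention_provider()]; the
#'   provider seed defaults to the config seed.
#' @param alpha FDR level.
#' @param min_instances,min_motif_length,merge_threshold,layer_strategy
#'   Discovery parameters.
#' @param bin_width,smooth_window Positional parameters.
#' @param shap_min_count,shap_n_coalitions SHAP parameters
#'   (`shap_n_coalitions = NULL` uses the per-record default).
#' @param seed Master seed; stage seeds derive from it.
#' @param ... Passed to [planted_dataset_spec()] when `dataset` is `NULL`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dataset = NULL, provider_args = list(),
                            alpha = 0.01, min_instances = 3,
                            min_motif_length = 4, merge_threshold = 0.8,
                            layer_strategy = "mid_final",
                            bin_width = 100, smooth_window = 3,
                            shap_min_count = 5, shap_n_coalitions = NULL,
                            seed = 1, ...) {
  dataset <- dataset %||% planted_dataset_spec(seed = seed, ...)
  stopifnot(inherits(dataset, "planted_dataset_spec"))
  structure(list(dataset = dataset, provider_args = provider_args,
                 alpha = alpha, min_instances = min_instances,
                 min_motif_length = min_motif_length,
                 merge_threshold = merge_threshold,
                 layer_strategy = layer_strategy,
                 bin_width = bin_width, smooth_window = smooth_window,
                 shap_min_count = shap_min_count,
                 shap_n_coalitions = shap_n_coalitions, seed = seed),
            class = "pipeline_config")
}

config_json <- function(config) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = NA)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> hash", fnv1a_hex(as.character(config_json(x))), "\n")
  invisible(x)
}

pipeline_provider <- function(config) {
  args <- config$provider_args
  args$seed <- args$seed %||% config$seed
  do.call(toy_attention_provider, args)
}

#' Simulate the pipeline's input dataset
#'
#' @param config A [pipeline_config()].
#' @return Record tibble from [generate_planted_dataset()].
#' @export
pipeline_simulate <- function(config) {
  generate_planted_dataset(config$dataset)
}

#' Run motif discovery under a pipeline configuration
#'
#' @param records Record tibble.
#' @param config A [pipeline_config()].
#' @param source Source tag for the result.
#' @return A `motif_discovery`.
#' @export
pipeline_discover <- function(records, config, source = "ModelA") {
  discover_motifs(records, pipeline_provider(config),
                  layer_strategy = config$layer_strategy,
                  alpha = config$alpha,
                  min_instances = config$min_instances,
                  min_motif_length = config$min_motif_length,
                  merge_threshold = config$merge_threshold,
                  source = source)
}

#' Positional profile stage
#'
#' @param discovery A `motif_discovery`.
#' @param records The records it ran on.
#' @param config A [pipeline_config()].
#' @return A `positional_profile` or `NULL`.
#' @export
pipeline_positions <- function(discovery, records, config) {
  positional_profile(discovery, records, bin_width = config$bin_width,
                     smooth_window = config$smooth_window)
}

#' One-row summary of a discovery result
#'
#' Empty-safe: an empty motif table yields a valid all-zero report.
#'
#' @param discovery A `motif_discovery`.
#' @return One-row tibble.
#' @export
pipeline_report <- function(discovery) {
  tibble::tibble(source = discovery$params$source,
                 n_candidates = nrow(discovery$candidates),
                 n_tested = nrow(discovery$motifs),
                 n_significant = sum(discovery$motifs$significant),
                 n_merged = nrow(discovery$merged),
                 alpha = discovery$params$alpha)
}

#' Run the toy pipeline end to end
#'
#' simulate -> discover -> positions, with optional artifact output:
#' motif table TSV, instance TSV, positional profile TSV, and a JSON
#' manifest recording the config, its hash, and the package version.
#' Deterministic: identical configs give byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory.
#' @return List with `records`, `discovery`, `profile`, `report`,
#'   `manifest` (and `paths` when written).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  records <- pipeline_simulate(config)
  discovery <- pipeline_discover(records, config)
  profile <- pipeline_positions(discovery, records, config)
  cjson <- as.character(config_json(config))
  manifest <- list(config = jsonlite::fromJSON(cjson),
                   config_hash = fnv1a_hex(cjson),
                   package_version = as.character(utils::packageVersion("promotif")),
                   n_records = nrow(records),
                   n_significant = sum(discovery$motifs$significant))
  out <- list(records = records, discovery = discovery, profile = profile,
              report = pipeline_report(discovery), manifest = manifest)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(motifs = file.path(outdir, "motifs.tsv"),
               instances = file.path(outdir, "instances.tsv"),
               manifest = file.path(outdir, "manifest.json"))
    readr::write_tsv(discovery$motifs, paths[["motifs"]])
    readr::write_tsv(discovery$instances, paths[["instances"]])
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    if (!is.null(profile)) {
      paths <- c(paths, profile = file.path(outdir, "positional_profile.tsv"))
      readr::write_tsv(profile$bins, paths[["profile"]])
    }
    out$paths <- paths
  }
  out
}

#' Motifs specific to the matched-null model (B minus A)
#'
#' Runs discovery under both negative-set designs represented by two
#' record tibbles and returns the merged significant motifs of model B
#' absent from model A — the candidates for tissue-specific (rather than
#' general promoter) signals.
#'
#' @param records_a,records_b Labeled record tibbles for the two designs.
#' @param config A [pipeline_config()].
#' @param matching Passed to [motif_set_difference()].
#' @return List with both discoveries and `b_specific` motifs.
#' @export
pipeline_diff <- function(records_a, records_b, config,
                          matching = "exact") {
  da <- pipeline_discover(records_a, config, source = "ModelA")
  db <- pipeline_discover(records_b, config, source = "ModelB")
  list(model_a = da, model_b = db,
       b_specific = motif_set_difference(db$merged$consensus,
                                         da$merged$consensus,
                                         matching = matching,
                                         threshold = config$merge_threshold))
}
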