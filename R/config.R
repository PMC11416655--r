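#' Pipeline configuration
#'
#' Builds the run configuration with the pipeline defaults. All downstream
#' functions take their tunables from this object; every value can be
#' overridden here, from a YAML/JSON config file ([read_config()]), or per
#' call.
#'
#' Defaults reflect the published analysis: signature sets of the top/bottom
#' `set_size = 20` genes, CAMERA inter-gene correlation 0.01, `drop_count = 3`
#' of the 10 inducer profiles removed at predictor selection, UMAP with
#' `min_dist = 0.05` and default `n_neighbors = 15`, anchor neighborhoods of
#' `neighborhood_k = 75` genes, 500 reseeded projections for stability,
#' correlation threshold 0.65, and the text-mining scan over the top 50 genes
#' against 2000 random sets of 100 genes.
#'
#' @param ... named overrides of any default listed above.
#' @return a named list of class `ft_config`.
#' @examples
#' cfg <- pipeline_config(master_seed = 7, neighborhood_k = 50)
#' cfg$umap_min_dist
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    set_size               = 20L,
    inter_gene_correlation = 0.01,
    drop_count             = 3L,
    umap_min_dist          = 0.05,
    umap_n_neighbors       = 15L,
    neighborhood_k         = 75L,
    n_stability_seeds      = 500L,
    gsea_permutations      = 1000L,
    ssgsea_alpha           = 0.25,
    correlation_threshold  = 0.65,
    top_n_textmine         = 50L,
    random_sets            = 2000L,
    random_set_size        = 100L,
    down_aggregate         = "max",
    master_seed            = 1L
  )
  dots <- list(...)
  if (length(dots) == 1L && is.list(dots[[1L]]) && is.null(names(dots)))
    dots <- dots[[1L]]
  unknown <- setdiff(names(dots), names(cfg))
  ft_assert(length(unknown) == 0,
            sprintf("unknown config fields: %s", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "ft_config")
}

validate_config <- function(cfg) {
  ft_assert(cfg$set_size >= 1, "set_size must be >= 1")
  ft_assert(cfg$inter_gene_correlation >= 0 && cfg$inter_gene_correlation < 1,
            "inter_gene_correlation must be in [0, 1)")
  ft_assert(cfg$drop_count >= 0, "drop_count must be >= 0")
  ft_assert(cfg$umap_min_dist > 0, "umap_min_dist must be > 0")
  ft_assert(cfg$correlation_threshold > 0 && cfg$correlation_threshold < 1,
            "correlation_threshold must be in (0, 1)")
  ft_assert(cfg$down_aggregate %in% c("max", "min"),
            "down_aggregate must be 'max' or 'min'")
  counts <- c("umap_n_neighbors", "neighborhood_k", "n_stability_seeds",
              "gsea_permutations", "top_n_textmine", "random_sets",
              "random_set_size")
  for (f in counts)
    ft_assert(cfg[[f]] >= 1, sprintf("%s must be a positive integer", f))
  invisible(cfg)
}

#' Read a pipeline configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`); unknown keys are rejected, missing
#' keys fall back to the defaults of [pipeline_config()].
#'
#' @param path path to the config file.
#' @param overrides optional named list applied on top of the file (CLI flags).
#' @export
read_config <- function(path, overrides = list()) {
  ft_assert(file.exists(path), sprintf("config file not found: %s", path))
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, as.list(vals))
}

#' Write the effective configuration to a file
#'
#' @param cfg an `ft_config`.
#' @param path output path (`.yaml` or `.json` decides the format).
#' @export
write_config <- function(cfg, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(unclass(cfg), path)
  }
  invisible(path)
}
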