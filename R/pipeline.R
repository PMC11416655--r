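# End-to-end orchestration: viability -> AUCs -> correlation predictors;
# profiles -> consensus selection -> similarity predictors; integration,
# anchor ranking, filters and reports. Deterministic given the config's
# master seed.

#' Run the full target-discovery pipeline
#'
#' Executes every stage on an in-memory world (a [generate_world()] result or
#' any list with the same elements): dose-response AUCs, the 6 correlation
#' predictors, consensus-based profile selection, CAMERA-based transcriptomic
#' similarity, predictor-matrix assembly, UMAP embedding, anchor-distance
#' ranking, the aggregate predictor score, candidate filtering, and a
#' neighborhood validation GSEA against the first drug's AUC axis. All
#' randomness derives from `config$master_seed`.
#'
#' @param world list with `viability`, `expression`, `dependency`, `profiles`,
#'   `compendium`, `citations` (citations may be `NULL`).
#' @param config a [pipeline_config()].
#' @param anchor anchor gene id; defaults to `world$truth$anchor` when
#'   present.
#' @param outdir optional output directory; when given, all artifacts and the
#'   effective config are written there.
#' @return list of class `ft_result` with all intermediate and final tables.
#' @export
run_pipeline <- function(world, config = pipeline_config(), anchor = NULL,
                         outdir = NULL) {
  validate_config(config)
  anchor <- anchor %||% world$truth$anchor
  ft_assert(!is.null(anchor), "no anchor gene given and none in world$truth")
  seeds <- derive_seeds(config$master_seed, 4L, salt = 7919L)

  ft_log("fitting dose-response curves and extracting AUCs")
  auc <- auc_table(world$viability)
  ft_log("computing correlation predictors for %d genes", nrow(world$expression))
  corr <- correlation_predictors(world$expression, world$dependency, auc)

  ft_log("consensus scoring of %d profiles", length(world$profiles))
  cons <- consensus_scores(world$profiles)
  retained <- select_profiles(cons, config$drop_count)
  ft_log("retained %d/%d profiles", length(retained), length(world$profiles))

  sets <- extract_signature_sets(world$compendium, config$set_size)
  ft_log("scoring %d signature set pairs against %d retained profiles",
         length(sets), length(retained))
  raw_scores <- score_signatures(world$profiles[retained], sets,
                                 rho = config$inter_gene_correlation,
                                 meta = world$compendium$meta)
  gene_scores <- aggregate_by_gene(raw_scores,
                                   down_aggregate = config$down_aggregate)
  sim <- similarity_predictors(gene_scores)

  pm <- build_predictor_matrix(corr, sim, retained)
  ft_log("predictor matrix: %d genes x %d predictors", nrow(pm), ncol(pm))
  emb <- embed_predictors(pm, min_dist = config$umap_min_dist,
                          n_neighbors = config$umap_n_neighbors,
                          seed = seeds[1L])
  nb <- anchor_neighbors(emb, anchor, config$neighborhood_k)
  agg <- aggregate_score(pm)
  candidates <- filter_candidates(nb, world$dependency, world$citations)

  validation <- NULL
  if (!is.null(world$expression) && ncol(auc) >= 1) {
    target <- auc[, 1L]
    names(target) <- rownames(auc)
    validation <- tryCatch(
      neighbor_validation(nb$top, world$expression, target,
                          n_perm = config$gsea_permutations, seed = seeds[2L]),
      error = function(e) NULL)
  }

  res <- structure(list(
    auc = auc, correlation = corr, consensus = cons, retained = retained,
    similarity = sim, gene_scores = gene_scores, predictor_matrix = pm,
    embedding = emb, neighbors = nb, aggregate = agg,
    candidates = candidates, validation = validation, config = config,
    anchor = anchor), class = "ft_result")

  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

#' Write all pipeline artifacts to a directory
#' @param res an `ft_result`.
#' @param outdir output directory.
#' @export
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  write_matrix(res$auc, p("auc.tsv"), id_name = "cell_line")
  utils::write.table(as.data.frame(res$correlation), p("correlation_predictors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(res$consensus), p("consensus_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(res$retained, p("retained_profiles.txt"))
  utils::write.table(similarity_long(res$similarity, res$gene_scores),
                     p("similarity_predictors.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_matrix(unclass(res$predictor_matrix), p("predictor_matrix.tsv"),
               id_name = "gene")
  utils::write.table(res$embedding, p("embedding.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_report(res$candidates, p("candidates.tsv"), format = "tsv")
  write_report(res$candidates, p("candidates.json"), format = "json")
  utils::write.table(res$aggregate, p("aggregate_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(res$validation))
    jsonlite::write_json(unclass(res$validation)[c("es", "nes", "p_value", "m")],
                         p("neighbor_validation.json"), auto_unbox = TRUE,
                         digits = NA)
  write_config(res$config, p("effective_config.yaml"))
  invisible(outdir)
}

#' @export
print.ft_result <- function(x, ...) {
  cat(sprintf("ferrotarget run: anchor %s, %d genes embedded, %d retained profiles\n",
              x$anchor, nrow(x$embedding), length(x$retained)))
  cat("top neighbors:\n")
  print(utils::head(x$neighbors$ranking, 5))
  invisible(x)
}
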