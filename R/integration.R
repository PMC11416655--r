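# Predictor integration: assemble the genes x 13 predictor matrix, embed it
# in 2-D with UMAP, rank genes by Euclidean distance to an anchor suppressor,
# and run the stability / fidelity / candidate-filter analyses.

#' Assemble the normalized predictor matrix
#'
#' The gene universe is the intersection of genes carried by both predictor
#' modules; genes with any missing predictor are dropped (and counted in a log
#' message). Each column is independently normalized to \[0, 1\] by fractional
#' ranks (average ties), which neutralizes the scale mismatch between
#' correlation predictors (\[-1, 1\]) and rank-difference similarity
#' predictors (±(N-1)). Column order is fixed: the 6 correlation predictors
#' (`expr_*` then `dep_*`), then the retained similarity profiles.
#'
#' @param corr a [correlation_predictors()] result.
#' @param sim a [similarity_predictors()] result.
#' @param retained character vector of retained profile ids
#'   ([select_profiles()]); defaults to all profiles in `sim`.
#' @return numeric gene x predictor matrix of class `predictor_matrix`, values
#'   in \[0, 1\], with attributes `raw` (same cells before normalization) and
#'   `provenance` (column origin).
#' @export
build_predictor_matrix <- function(corr, sim, retained = NULL) {
  retained <- retained %||% colnames(sim$final)
  missing_prof <- setdiff(retained, colnames(sim$final))
  ft_assert(length(missing_prof) == 0,
            sprintf("retained profiles absent from similarity predictors: %s",
                    paste(missing_prof, collapse = ", ")))
  corr_cols <- c(grep("^expr_", names(corr), value = TRUE),
                 grep("^dep_", names(corr), value = TRUE))
  genes <- intersect(corr$gene, rownames(sim$final))
  if (length(genes) == 0)
    stop("no genes shared between correlation and similarity modules", call. = FALSE)
  cm <- as.matrix(corr[match(genes, corr$gene), corr_cols, drop = FALSE])
  sm <- sim$final[genes, retained, drop = FALSE]
  colnames(sm) <- paste0("sim_", retained)
  raw <- cbind(cm, sm)
  rownames(raw) <- genes
  complete <- rowSums(is.na(raw)) == 0
  if (!all(complete))
    ft_log("dropping %d gene(s) with missing predictors", sum(!complete))
  raw <- raw[complete, , drop = FALSE]
  ft_assert(nrow(raw) > 0, "no genes with complete predictors")
  norm <- apply(raw, 2L, rank_unit)
  dimnames(norm) <- dimnames(raw)
  structure(norm, raw = raw,
            provenance = c(rep("correlation", length(corr_cols)),
                           rep("similarity", length(retained))),
            class = c("predictor_matrix", class(norm)))
}

#' 2-D UMAP embedding of the predictor matrix
#'
#' Euclidean input metric, `min_dist = 0.05` by default and all other UMAP
#' parameters at their defaults. Single-threaded with a fixed seed, so the
#' same matrix and seed give identical coordinates.
#'
#' @param matrix a `predictor_matrix` (or any numeric gene x feature matrix).
#' @param min_dist UMAP min_dist.
#' @param n_neighbors UMAP n_neighbors.
#' @param seed integer seed.
#' @return data.frame `gene`, `x`, `y` with attributes `seed` and `params`.
#' @export
embed_predictors <- function(matrix, min_dist = 0.05, n_neighbors = 15L,
                             seed = 1L) {
  x <- unclass(matrix)
  attr(x, "raw") <- NULL; attr(x, "provenance") <- NULL
  ft_assert(nrow(x) >= n_neighbors + 1,
            sprintf("need >= n_neighbors + 1 = %d genes, got %d",
                    n_neighbors + 1, nrow(x)))
  coords <- with_seed(as.integer(seed),
    uwot::umap(x, n_neighbors = n_neighbors, min_dist = min_dist,
               metric = "euclidean", n_threads = 1, n_sgd_threads = 0,
               verbose = FALSE))
  out <- data.frame(gene = rownames(x), x = coords[, 1L], y = coords[, 2L],
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "params") <- list(min_dist = min_dist, n_neighbors = n_neighbors)
  out
}

#' Rank genes by Euclidean distance to an anchor gene
#'
#' @param embedding result of [embed_predictors()] (or any `gene`,`x`,`y`
#'   table).
#' @param anchor anchor gene id; must be present in the embedding.
#' @param k neighborhood size for the extracted top-k set (default 75).
#' @return list with `ranking` (data.frame `gene`, `distance`, `rank`, anchor
#'   excluded, ties by gene id) and `top` (a [gene_set()] of the k closest
#'   genes), plus the anchor id.
#' @export
anchor_neighbors <- function(embedding, anchor, k = 75L) {
  ai <- match(anchor, embedding$gene)
  if (is.na(ai))
    stop(sprintf("anchor gene '%s' not found in the embedding", anchor),
         call. = FALSE)
  dx <- embedding$x - embedding$x[ai]
  dy <- embedding$y - embedding$y[ai]
  d <- sqrt(dx^2 + dy^2)
  keep <- seq_len(nrow(embedding)) != ai
  ord <- order(d[keep], embedding$gene[keep])
  ranking <- data.frame(gene = embedding$gene[keep][ord],
                        distance = d[keep][ord],
                        rank = seq_len(sum(keep)),
                        stringsAsFactors = FALSE)
  k <- min(k, nrow(ranking))
  list(anchor = anchor, ranking = ranking,
       top = gene_set(sprintf("%s_top%d_neighbors", anchor, k),
                      ranking$gene[seq_len(k)]))
}

#' Aggregate predictor score (the "blue hue" metric)
#'
#' From the raw (pre-normalization) predictor values: `a` = mean of the 3
#' expression correlations, `b` = mean of the 3 dependency correlations,
#' `m = max(a, b)`; `r1` = ascending rank of `m`, `r2` = ascending rank of the
#' mean of the retained similarity predictors; score = `(r1 + r2) / 2`. Higher
#' means a stronger candidate. Genes with missing components are dropped.
#'
#' @param matrix a `predictor_matrix` (its `raw` attribute is used).
#' @return data.frame `gene`, `corr_mean_max`, `sim_mean`, `score`, sorted by
#'   descending score.
#' @export
aggregate_score <- function(matrix) {
  raw <- attr(matrix, "raw")
  ft_assert(!is.null(raw), "matrix lacks the raw predictor attribute")
  ec <- grep("^expr_", colnames(raw)); dc <- grep("^dep_", colnames(raw))
  sc <- grep("^sim_", colnames(raw))
  ft_assert(length(ec) > 0 && length(dc) > 0 && length(sc) > 0,
            "raw matrix must carry expr_*, dep_* and sim_* columns")
  a <- rowMeans(raw[, ec, drop = FALSE])
  b <- rowMeans(raw[, dc, drop = FALSE])
  m <- pmax(a, b)
  sim_mean <- rowMeans(raw[, sc, drop = FALSE])
  ok <- is.finite(m) & is.finite(sim_mean)
  r1 <- rank(m[ok], ties.method = "average")
  r2 <- rank(sim_mean[ok], ties.method = "average")
  out <- data.frame(gene = rownames(raw)[ok], corr_mean_max = m[ok],
                    sim_mean = sim_mean[ok], score = (r1 + r2) / 2,
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$gene), , drop = FALSE]
}

#' Neighborhood stability across reseeded UMAP projections
#'
#' Re-embeds the predictor matrix `n_seeds` times (seeds derived
#' deterministically from `master_seed`), recomputes the anchor's top-k
#' neighborhood each time, and reports for every gene the fraction of seeds in
#' which it was retained.
#'
#' @param matrix a `predictor_matrix`.
#' @param anchor anchor gene id.
#' @param k neighborhood size.
#' @param n_seeds number of projections (default 500).
#' @param master_seed master seed the per-projection seeds derive from.
#' @inheritParams embed_predictors
#' @return data.frame `gene`, `retention` in \[0, 1\], anchor excluded, sorted
#'   by descending retention.
#' @export
stability_analysis <- function(matrix, anchor, k = 75L, n_seeds = 500L,
                               min_dist = 0.05, n_neighbors = 15L,
                               master_seed = 1L) {
  seeds <- derive_seeds(master_seed, n_seeds, salt = 104729L)
  genes <- setdiff(rownames(matrix), anchor)
  hits <- stats::setNames(integer(length(genes)), genes)
  for (s in seeds) {
    emb <- embed_predictors(matrix, min_dist = min_dist,
                            n_neighbors = n_neighbors, seed = s)
    top <- anchor_neighbors(emb, anchor, k)$top$members
    hits[top] <- hits[top] + 1L
  }
  out <- data.frame(gene = genes, retention = unname(hits) / n_seeds,
                    stringsAsFactors = FALSE)
  out[order(-out$retention, out$gene), , drop = FALSE]
}

#' Embedding fidelity: predictor-space vs. embedding-space distances
#'
#' Samples `n_pairs` random gene pairs and reports the Spearman correlation
#' between their Euclidean distances in normalized predictor space and in the
#' 2-D embedding. Values near 1 mean local neighborhoods in the projection
#' reflect true predictor similarity.
#'
#' @param matrix a `predictor_matrix`.
#' @param embedding result of [embed_predictors()] on the same genes.
#' @param n_pairs number of sampled pairs (>= 10).
#' @param seed sampling seed.
#' @return Spearman rank correlation (single number).
#' @export
embedding_fidelity <- function(matrix, embedding, n_pairs = 10000L, seed = 1L) {
  ft_assert(n_pairs >= 10, "n_pairs must be >= 10")
  genes <- intersect(rownames(matrix), embedding$gene)
  n <- length(genes)
  ft_assert(n >= 3, "need >= 3 shared genes")
  x <- unclass(matrix)[genes, , drop = FALSE]
  ei <- match(genes, embedding$gene)
  ex <- embedding$x[ei]; ey <- embedding$y[ei]
  pair <- with_seed(seed, {
    i <- sample.int(n, n_pairs, replace = TRUE)
    j <- sample.int(n, n_pairs, replace = TRUE)
    keep <- i != j
    cbind(i[keep], j[keep])
  })
  dp <- sqrt(rowSums((x[pair[, 1L], , drop = FALSE] - x[pair[, 2L], , drop = FALSE])^2))
  de <- sqrt((ex[pair[, 1L]] - ex[pair[, 2L]])^2 + (ey[pair[, 1L]] - ey[pair[, 2L]])^2)
  stats::cor(dp, de, method = "spearman")
}

#' Annotate and filter candidate genes
#'
#' Flags each ranked gene without silently removing anything: `pan_essential`
#' (dependency below `essentiality_threshold` in at least `essential_fraction`
#' of cell lines), `previously_cited` (any nonzero citation count with the
#' supplied terms) and `druggable` (membership in an optional list). Ordered
#' by anchor distance.
#'
#' @param neighbors result of [anchor_neighbors()].
#' @param dependency genes x cell lines dependency matrix (CERES-like; more
#'   negative = more essential).
#' @param citations a [citation_table()] (or `NULL` to skip the flag).
#' @param druggable optional character vector of druggable gene ids.
#' @param essentiality_threshold dependency cutoff (default -0.5).
#' @param essential_fraction fraction of lines below the cutoff that marks a
#'   gene pan-essential (default 0.9).
#' @return data.frame: the neighbor ranking plus logical flag columns and
#'   `candidate` (close neighbor that fails no filter).
#' @export
filter_candidates <- function(neighbors, dependency, citations = NULL,
                              druggable = NULL, essentiality_threshold = -0.5,
                              essential_fraction = 0.9) {
  tab <- neighbors$ranking
  di <- match(tab$gene, rownames(dependency))
  ess_frac <- rep(NA_real_, nrow(tab))
  has <- !is.na(di)
  if (any(has)) {
    dm <- dependency[di[has], , drop = FALSE]
    ess_frac[has] <- rowMeans(dm < essentiality_threshold, na.rm = TRUE)
  }
  tab$pan_essential <- !is.na(ess_frac) & ess_frac >= essential_fraction
  if (!is.null(citations)) {
    cited_genes <- unique(citations$gene[citations$count > 0])
    tab$previously_cited <- tab$gene %in% cited_genes
  } else {
    tab$previously_cited <- NA
  }
  tab$druggable <- if (!is.null(druggable)) tab$gene %in% druggable else NA
  tab$candidate <- !tab$pan_essential & !(tab$previously_cited %in% TRUE)
  tab
}
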