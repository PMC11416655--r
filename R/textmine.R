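# Offline citation-based validation: cited-percentage scoring of gene sets,
# the exhaustive predictor-combination scan, and the random-set null. The
# citation table is a required offline input (gene x term counts); no network
# access anywhere.

#' Percentage of a gene set cited with each term
#'
#' For each term, `100 * |{g in set : count(g, term) > 0}| / |set|`. Genes
#' absent from the citation table count as uncited.
#'
#' @param genes a [gene_set()] or character vector.
#' @param table a [citation_table()].
#' @param terms terms to score; default: the table's full vocabulary.
#' @return named numeric vector of percentages in \[0, 100\].
#' @export
cited_fraction <- function(genes, table, terms = NULL) {
  members <- if (inherits(genes, "gene_set")) genes$members else
    unique(as.character(genes))
  if (length(members) == 0) stop("empty gene set", call. = FALSE)
  terms <- terms %||% attr(table, "terms")
  unknown <- setdiff(terms, attr(table, "terms"))
  ft_assert(length(unknown) == 0,
            sprintf("terms not in vocabulary: %s", paste(unknown, collapse = ", ")))
  vapply(terms, function(tm) {
    cited <- table$gene[table$term == tm & table$count > 0]
    100 * sum(members %in% cited) / length(members)
  }, numeric(1))
}

#' Exhaustive predictor-combination citation scan
#'
#' Enumerates every non-empty subset of the M similarity predictors (2^M - 1
#' combinations); for each, the correlation predictors (always all included)
#' and the selected similarity columns are rank-normalized, combined per gene
#' (mean of the normalized columns by default, or worst rank with
#' `strategy = "min_rank"`), and the top `top_n` genes are scored with
#' [cited_fraction()].
#'
#' @param corr a [correlation_predictors()] result.
#' @param sim a [similarity_predictors()] result over all M profiles.
#' @param table a [citation_table()].
#' @param top_n number of top genes per combination (default 50).
#' @param terms terms to score (default: full vocabulary).
#' @param strategy `"mean"` (default) or `"min_rank"`.
#' @return data.frame: one row per combination with `combination` (profile ids
#'   joined by `+`), `n_similarity`, one percentage column per term, and
#'   `top_genes` (comma-joined).
#' @export
combination_scan <- function(corr, sim, table, top_n = 50L, terms = NULL,
                             strategy = c("mean", "min_rank")) {
  strategy <- match.arg(strategy)
  pm <- build_predictor_matrix(corr, sim)
  M <- sum(attr(pm, "provenance") == "similarity")
  ft_assert(M >= 1 && M <= 20, "combination scan supports 1 <= M <= 20 profiles")
  if (top_n > nrow(pm))
    stop(sprintf("top_n = %d exceeds the %d-gene universe", top_n, nrow(pm)),
         call. = FALSE)
  terms <- terms %||% attr(table, "terms")
  norm <- unclass(pm)
  corr_cols <- which(attr(pm, "provenance") == "correlation")
  sim_cols <- which(attr(pm, "provenance") == "similarity")
  sim_ids <- sub("^sim_", "", colnames(norm)[sim_cols])
  genes <- rownames(norm)
  corr_sum <- rowSums(norm[, corr_cols, drop = FALSE])
  n_comb <- 2L^M - 1L
  rows <- vector("list", n_comb)
  for (mask in seq_len(n_comb)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(M) - 1L)) > 0)
    cols <- sim_cols[sel]
    score <- if (strategy == "mean") {
      (corr_sum + rowSums(norm[, cols, drop = FALSE])) /
        (length(corr_cols) + length(sel))
    } else {
      apply(norm[, c(corr_cols, cols), drop = FALSE], 1L, min)
    }
    top <- genes[order(-score, genes)[seq_len(top_n)]]
    pct <- cited_fraction(top, table, terms)
    rows[[mask]] <- c(list(combination = paste(sim_ids[sel], collapse = "+"),
                           n_similarity = length(sel)),
                      as.list(pct),
                      list(top_genes = paste(top, collapse = ",")))
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE,
                                                        stringsAsFactors = FALSE)))
}

#' Random-set citation null
#'
#' Draws `n_sets` uniform without-replacement gene sets of size `set_size`
#' from a universe and scores each with [cited_fraction()]. The returned
#' object also provides an empirical p-value function using the add-one rule:
#' `p(x) = (1 + #{null >= x}) / (1 + n_sets)`.
#'
#' @param universe character vector of candidate gene ids.
#' @param table a [citation_table()].
#' @param n_sets number of random sets (default 2000).
#' @param set_size genes per set (default 100).
#' @param terms terms to score.
#' @param seed sampling seed.
#' @return list of class `citation_null`: `null` (n_sets x terms matrix of
#'   percentages), `empirical_p(observed)` and the draw parameters.
#' @export
random_null <- function(universe, table, n_sets = 2000L, set_size = 100L,
                        terms = NULL, seed = 1L) {
  ft_assert(set_size <= length(universe),
            "set_size exceeds the gene universe")
  terms <- terms %||% attr(table, "terms")
  # precompute cited indicator per term for speed
  cited <- vapply(terms, function(tm) {
    universe %in% table$gene[table$term == tm & table$count > 0]
  }, logical(length(universe)))
  null <- with_seed(seed, t(vapply(seq_len(n_sets), function(i) {
    idx <- sample.int(length(universe), set_size)
    100 * colSums(cited[idx, , drop = FALSE]) / set_size
  }, numeric(length(terms)))))
  colnames(null) <- terms
  empirical_p <- function(observed) {
    ft_assert(all(names(observed) %in% terms) || is.null(names(observed)),
              "observed names must match the scored terms")
    obs <- if (is.null(names(observed))) stats::setNames(observed, terms) else observed
    vapply(names(obs), function(tm)
      (1 + sum(null[, tm] >= obs[[tm]])) / (1 + n_sets), numeric(1))
  }
  structure(list(null = null, empirical_p = empirical_p,
                 n_sets = as.integer(n_sets), set_size = as.integer(set_size),
                 seed = as.integer(seed)),
            class = "citation_null")
}
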