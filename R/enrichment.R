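# Preranked GSEA and single-sample GSEA (ssGSEA), used to validate the
# inducer-response signature and anchor neighborhoods.

# Enrichment score of a set given its (1-based) positions in the ranked list.
# Weighted Kolmogorov-Smirnov walk: hits add |stat|^p / sum_in(|stat|^p),
# misses subtract 1/(G - m). The running extremum only changes at hit
# positions, so the walk is evaluated there: just after each hit for the
# maximum, just before for the minimum. O(m) per set.
.es_walk <- function(pos, w, G) {
  m <- length(pos)
  nr <- sum(w)
  hit_cum <- cumsum(w) / (if (nr > 0) nr else 1)
  miss_before <- (pos - seq_len(m)) / (G - m)       # misses seen before hit i
  after <- hit_cum - miss_before                     # running sum just after hit i
  before <- c(0, hit_cum[-m])[seq_len(m)] - miss_before  # just before hit i
  es_max <- max(after, 0)
  es_min <- min(before, 0)
  # tail after the last hit only decreases towards 0, never a new extremum
  if (es_max >= abs(es_min)) es_max else es_min
}

#' Preranked gene set enrichment analysis
#'
#' Classic weighted-KS GSEA on a preranked list: genes are ordered by
#' descending statistic; walking down the list, set members increment the
#' running sum by `|stat|^weight_exponent` (normalized by the in-set total)
#' and non-members decrement it by `1/(G - m)`. ES is the signed extremum of
#' the walk. The permutation null draws random m-gene sets; NES divides ES by
#' the mean |ES| of same-sign permutations, and the p-value is
#' `(1 + #{same-sign perms with |ES| >= |ES_obs|}) / (1 + #same-sign perms)`
#' so that null p-values are uniform and never zero.
#'
#' @param ranking named numeric vector of gene-level statistics (any order;
#'   sorted internally, descending, ties by gene id).
#' @param set a [gene_set()] or character vector.
#' @param weight_exponent the GSEA weight p (default 1).
#' @param n_perm number of set permutations.
#' @param seed permutation seed.
#' @return list of class `gsea_result`: `es`, `nes`, `p_value`, `m`,
#'   `n_perm`, `seed`.
#' @export
preranked_gsea <- function(ranking, set, weight_exponent = 1, n_perm = 1000L,
                           seed = 1L) {
  members <- if (inherits(set, "gene_set")) set$members else as.character(set)
  ft_assert(!is.null(names(ranking)), "ranking must be a named vector")
  ok <- is.finite(ranking)
  stat <- ranking[ok]
  ord <- order(-stat, names(stat))
  stat <- stat[ord]
  G <- length(stat)
  pos <- which(names(stat) %in% members)
  m <- length(pos)
  if (m == 0) stop("set has no members in the ranking", call. = FALSE)
  ft_assert(m < G, "set must not cover the whole ranking")
  wstat <- abs(stat)^weight_exponent
  es <- .es_walk(pos, wstat[pos], G)
  perm_es <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sort(sample.int(G, m))
    .es_walk(p, wstat[p], G)
  }, numeric(1)))
  same <- if (es >= 0) perm_es[perm_es >= 0] else perm_es[perm_es < 0]
  nes <- if (length(same) > 0 && mean(abs(same)) > 0) es / mean(abs(same)) else NA_real_
  p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  structure(list(es = es, nes = nes, p_value = p, m = m,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA: ES=%.3f NES=%.3f p=%.4g (m=%d, %d permutations)\n",
              x$es, x$nes, x$p_value, x$m, x$n_perm))
  invisible(x)
}

#' Single-sample GSEA (ssGSEA)
#'
#' Per sample, genes are ranked by expression (average ties, higher expression
#' = higher rank) and the score is the sum over the ranked list of the
#' difference between the weighted in-set ECDF (weights `rank^alpha`) and the
#' unweighted out-of-set ECDF. With `normalize = TRUE`, scores are divided by
#' the range (max - min) across samples.
#'
#' @param expression genes x samples numeric matrix.
#' @param set a [gene_set()] or character vector.
#' @param alpha rank weight exponent (default 0.25).
#' @param normalize divide scores by their range across samples.
#' @return named numeric vector of per-sample scores.
#' @export
ssgsea <- function(expression, set, alpha = 0.25, normalize = FALSE) {
  members <- if (inherits(set, "gene_set")) set$members else as.character(set)
  genes <- rownames(expression)
  in_set <- genes %in% members
  if (!any(in_set)) stop("set has no members in the expression matrix", call. = FALSE)
  G <- nrow(expression)
  scores <- apply(expression, 2L, function(v) {
    r <- rank(v, ties.method = "average")
    ord <- order(-r, genes)                # walk from highest expression down
    hit <- in_set[ord]
    w <- abs(r[ord])^alpha
    w[!hit] <- 0
    ecdf_in <- cumsum(w) / sum(w)
    ecdf_out <- cumsum(!hit) / (G - sum(in_set))
    sum(ecdf_in - ecdf_out)
  })
  if (normalize) {
    rng <- diff(range(scores))
    if (rng > 0) scores <- scores / rng
  }
  scores
}

#' Validate a neighborhood against an external vulnerability axis
#'
#' Ranks every gene by the Pearson correlation (pairwise-complete) of its
#' expression across cell lines with a target vector (an anchor's dependency
#' scores or a drug's AUCs), then tests the neighbor set against that ranking
#' with [preranked_gsea()]. A positive NES means the neighborhood is enriched
#' among the genes most positively correlated with the target.
#'
#' @param neighbor_set a [gene_set()] (e.g. the top-k anchor neighborhood).
#' @param expression genes x cell lines matrix.
#' @param target named per-cell-line numeric vector.
#' @param n_perm,seed passed to [preranked_gsea()].
#' @return a `gsea_result`, with the ranking attached as attribute `ranking`.
#' @export
neighbor_validation <- function(neighbor_set, expression, target,
                                n_perm = 1000L, seed = 1L) {
  shared <- intersect(colnames(expression), names(target))
  ft_assert(length(shared) >= 3, "need >= 3 shared cell lines")
  y <- target[shared]
  if (stats::var(y, na.rm = TRUE) == 0)
    stop("target vector is constant; correlation ranking undefined", call. = FALSE)
  m <- expression[, shared, drop = FALSE]
  r <- suppressWarnings(as.vector(stats::cor(t(m), y, use = "pairwise.complete.obs")))
  names(r) <- rownames(m)
  r <- r[is.finite(r)]
  res <- preranked_gsea(r, neighbor_set, n_perm = n_perm, seed = seed)
  attr(res, "ranking") <- r
  res
}
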