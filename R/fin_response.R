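# Processing of the ferroptosis-inducer (FIN) response profiles: mean
# fold-change ranking, recurrent DEG counting, query-set extraction, and the
# consensus-based predictor-selection step.

profiles_gene_universe <- function(profiles) {
  sort(unique(unlist(lapply(profiles, function(p) p$gene))))
}

#' Rank genes by mean log2 fold change across inducer profiles
#'
#' The mean is taken over the profiles in which the gene is present; rank 1 is
#' the highest mean fold change, ties broken lexicographically by gene id.
#'
#' @param profiles list of [fc_profile()] objects.
#' @return data.frame `gene`, `mean_log2fc`, `n_profiles`, `rank`, sorted by
#'   rank.
#' @export
mean_fc_ranking <- function(profiles) {
  ft_assert(length(profiles) >= 1, "need at least one profile")
  genes <- profiles_gene_universe(profiles)
  ft_assert(length(genes) > 0, "empty gene universe")
  sums <- stats::setNames(numeric(length(genes)), genes)
  n <- stats::setNames(integer(length(genes)), genes)
  for (p in profiles) {
    idx <- match(p$gene, genes)
    sums[idx] <- sums[idx] + p$log2fc
    n[idx] <- n[idx] + 1L
  }
  mean_fc <- sums / n
  ord <- order(-mean_fc, genes)
  data.frame(gene = genes[ord], mean_log2fc = mean_fc[ord],
             n_profiles = n[ord], rank = seq_along(genes),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Recurrently differential genes across profiles
#'
#' Genes significant (`p < p_cut`) with the requested fold-change sign in at
#' least `min_datasets` profiles.
#'
#' @param profiles list of [fc_profile()] objects carrying p-values.
#' @param p_cut p-value cutoff (strict).
#' @param min_datasets minimum number of qualifying profiles.
#' @param direction `"up"` (log2fc > 0) or `"down"` (log2fc < 0).
#' @return a [gene_set()] of the recurrent genes (empty universe -> error from
#'   the constructor is avoided by returning a zero-row record via `NULL` when
#'   no gene qualifies; callers receive a `gene_set` with the qualifying genes
#'   or `NULL`).
#' @export
recurrent_degs <- function(profiles, p_cut = 0.05, min_datasets = 3L,
                           direction = c("up", "down")) {
  direction <- match.arg(direction)
  has_p <- vapply(profiles, function(p) "p_value" %in% names(p), logical(1))
  if (!all(has_p))
    stop("all profiles must carry p-values for recurrent DEG counting", call. = FALSE)
  genes <- profiles_gene_universe(profiles)
  hits <- stats::setNames(integer(length(genes)), genes)
  for (p in profiles) {
    sig <- !is.na(p$p_value) & p$p_value < p_cut &
      (if (direction == "up") p$log2fc > 0 else p$log2fc < 0)
    idx <- match(p$gene[sig], genes)
    hits[idx] <- hits[idx] + 1L
  }
  members <- names(hits)[hits >= min_datasets]
  if (length(members) == 0) return(NULL)
  gene_set(sprintf("recurrent_%s_p%g_min%d", direction, p_cut, min_datasets),
           members, direction = direction)
}

#' Top-n / bottom-n query sets from a mean fold-change ranking
#'
#' @param ranking result of [mean_fc_ranking()].
#' @param n set size; must satisfy `n <= G/2` so the sets are disjoint.
#' @return list with `up` and `down` [gene_set()] objects.
#' @export
top_bottom_sets <- function(ranking, n) {
  g <- nrow(ranking)
  if (n > g / 2)
    stop(sprintf("n = %d exceeds half the universe (G = %d)", n, g), call. = FALSE)
  list(up = gene_set(sprintf("top%d_mean_fc", n), ranking$gene[seq_len(n)],
                     direction = "up"),
       down = gene_set(sprintf("bottom%d_mean_fc", n),
                       ranking$gene[seq(g - n + 1L, g)], direction = "down"))
}

#' Consensus scores for predictor selection
#'
#' Pairwise Pearson correlations between profiles are computed on the log2
#' fold changes of the genes shared by each pair. For profile i the raw score
#' is `s_i = sum_{j != i} max(r_ij, 0)` and the normalized score is
#' `n_i = 100 * (s_i - min s) / (max s - min s)`; if all raw scores are equal,
#' all normalized scores are 100 (degenerate rule, warned about downstream).
#'
#' @param profiles list of >= 3 [fc_profile()] objects.
#' @return data.frame `profile_id`, `raw`, `normalized` plus attribute
#'   `cor_matrix` (the pairwise correlation matrix).
#' @export
consensus_scores <- function(profiles) {
  m <- length(profiles)
  if (m < 3) stop("need >= 3 profiles for consensus scoring", call. = FALSE)
  ids <- vapply(profiles, function(p) attr(p, "profile_id"), "")
  check_unique(ids, "profile ids")
  cm <- diag(1, m)
  dimnames(cm) <- list(ids, ids)
  for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
    pi <- profiles[[i]]; pj <- profiles[[j]]
    shared <- intersect(pi$gene, pj$gene)
    r <- if (length(shared) >= 3)
      stats::cor(pi$log2fc[match(shared, pi$gene)],
                 pj$log2fc[match(shared, pj$gene)]) else NA_real_
    cm[i, j] <- cm[j, i] <- r
  }
  pos <- pmax(cm, 0)
  diag(pos) <- 0
  s <- rowSums(pos, na.rm = TRUE)
  rng <- range(s)
  normalized <- if (rng[1] == rng[2]) rep(100, m) else
    100 * (s - rng[1]) / (rng[2] - rng[1])
  structure(data.frame(profile_id = ids, raw = unname(s),
                       normalized = unname(normalized),
                       stringsAsFactors = FALSE),
            cor_matrix = cm, class = c("consensus_scores", "data.frame"))
}

#' Retain the most consensual profiles
#'
#' Drops the `drop_count` profiles with the lowest normalized consensus score
#' (ties broken lexicographically by profile id; a fully degenerate score
#' vector triggers a warning since the drop is then by id order only).
#'
#' @param scores result of [consensus_scores()].
#' @param drop_count number of profiles to drop (`d < M`).
#' @return character vector of retained profile ids, in original order.
#' @export
select_profiles <- function(scores, drop_count) {
  m <- nrow(scores)
  if (drop_count >= m)
    stop(sprintf("drop_count (%d) must be smaller than the number of profiles (%d)",
                 drop_count, m), call. = FALSE)
  if (drop_count == 0) return(scores$profile_id)
  if (length(unique(scores$normalized)) == 1L)
    warning("all consensus scores identical; dropping by profile id order",
            call. = FALSE)
  ord <- order(scores$normalized, scores$profile_id)
  dropped <- scores$profile_id[ord][seq_len(drop_count)]
  scores$profile_id[!scores$profile_id %in% dropped]
}
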