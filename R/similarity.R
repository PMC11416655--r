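# Transcriptomic similarity scoring: every knockdown signature's top/bottom
# gene sets are tested against every retained inducer profile with a
# competitive (CAMERA-style) test, scores are aggregated per knocked-down
# gene across its cell contexts, and up/down enrichment ranks are combined
# into the final rank-difference similarity predictor.

#' Extract up/down query sets from a signature compendium
#'
#' For each signature, the top `K` and bottom `K` genes by z-score (ties broken
#' lexicographically by gene id) form its up- and down-regulated sets.
#' Signatures with fewer than `2K` non-missing genes are skipped with a
#' warning.
#'
#' @param compendium a [signature_compendium()].
#' @param K set size (default 20).
#' @return named list (by signature id) of lists with elements `signature_id`,
#'   `up`, `down` ([gene_set()]s of size K each, disjoint).
#' @export
extract_signature_sets <- function(compendium, K = 20L) {
  m <- compendium$matrix
  genes <- rownames(m)
  out <- vector("list", ncol(m))
  skipped <- character(0)
  for (j in seq_len(ncol(m))) {
    z <- m[, j]
    ok <- !is.na(z)
    if (sum(ok) < 2L * K) {
      skipped <- c(skipped, colnames(m)[j])
      next
    }
    g <- genes[ok]; zz <- z[ok]
    up_idx <- order(-zz, g)[seq_len(K)]
    dn_idx <- order(zz, g)[seq_len(K)]
    sid <- colnames(m)[j]
    out[[j]] <- list(
      signature_id = sid,
      up = gene_set(paste0(sid, "_up"), g[up_idx], direction = "up"),
      down = gene_set(paste0(sid, "_down"), g[dn_idx], direction = "down"))
  }
  if (length(skipped) > 0)
    warning(sprintf("%d signature(s) with < 2K non-missing genes skipped: %s",
                    length(skipped), paste(utils::head(skipped, 5), collapse = ", ")),
            call. = FALSE)
  out <- out[!vapply(out, is.null, logical(1))]
  names(out) <- vapply(out, `[[`, "", "signature_id")
  out
}

# Core of the competitive test, vectorized over sets: given the gene-level
# statistic vector and a list of index vectors into it, return the signed
# t statistics and two-sided p-values. Uses the within-group pooled variance
# (total SS minus between-group SS), i.e. exactly limma's cameraPR moment
# formula, with variance inflation VIF = 1 + (m - 1) * rho.
.camera_core <- function(stat, idx_list, rho) {
  G <- length(stat)
  mean_all <- mean(stat)
  var_all <- stats::var(stat)
  t_out <- p_out <- rep(NA_real_, length(idx_list))
  m_out <- integer(length(idx_list))
  for (k in seq_along(idx_list)) {
    idx <- idx_list[[k]]
    m <- length(idx)
    m_out[k] <- m
    if (m < 2 || m >= G) next
    if (var_all == 0) { t_out[k] <- 0; p_out[k] <- 1; next }
    m2 <- G - m
    delta <- G / m2 * (mean(stat[idx]) - mean_all)   # = mean_in - mean_out
    var_pooled <- ((G - 1) * var_all - delta^2 * m * m2 / G) / (G - 2)
    vif <- 1 + (m - 1) * rho
    tt <- delta / sqrt(var_pooled * (vif / m + 1 / m2))
    t_out[k] <- tt
    p_out[k] <- 2 * stats::pt(-abs(tt), df = G - 2)
  }
  list(statistic = t_out, p_value = p_out, m = m_out)
}

#' Competitive preranked gene-set test (CAMERA-style)
#'
#' Compares the gene-level statistics of set members against the rest of the
#' universe with a two-sample t statistic whose variance is inflated by
#' `VIF = 1 + (m - 1) * rho` to account for inter-gene correlation:
#' `t = (mean_in - mean_out) / (s * sqrt(VIF/m + 1/(G - m)))` with `G - 2`
#' degrees of freedom and the within-group pooled variance `s^2`. With
#' `rho = 0` this is exactly an ordinary pooled two-sample t-test.
#'
#' @param gene_stats named numeric vector of per-gene statistics (e.g. log2
#'   fold changes of one inducer profile).
#' @param set a [gene_set()] or character vector of member ids.
#' @param rho fixed inter-gene correlation (default 0.01).
#' @return list with `statistic` (signed t; positive = set up-shifted),
#'   `p_value` (two-sided) and `m` (set size used after intersection).
#' @export
camera_pr <- function(gene_stats, set, rho = 0.01) {
  members <- if (inherits(set, "gene_set")) set$members else as.character(set)
  ft_assert(!is.null(names(gene_stats)), "gene_stats must be a named vector")
  ok <- is.finite(gene_stats)
  stat <- gene_stats[ok]
  idx <- which(names(stat) %in% members)
  if (length(idx) < 2)
    stop(sprintf("set has %d member(s) in the universe; need >= 2", length(idx)),
         call. = FALSE)
  ft_assert(length(idx) < length(stat), "set must not cover the whole universe")
  res <- .camera_core(stat, list(idx), rho)
  list(statistic = res$statistic[1L], p_value = res$p_value[1L], m = res$m[1L])
}

#' Score all signature sets against all retained profiles
#'
#' Runs [camera_pr()] of each signature's up and down set against each
#' profile's gene-level statistic (log2 fold change). Sets that shrink below 2
#' members in a profile's universe get `NA`.
#'
#' @param profiles list of retained [fc_profile()] objects.
#' @param sets result of [extract_signature_sets()].
#' @param rho inter-gene correlation for the competitive test.
#' @param meta the compendium metadata (carried through for aggregation).
#' @return list of class `signature_scores`: `up` and `down` are
#'   signature x profile matrices of signed statistics, plus `up_p`/`down_p`
#'   and `meta`.
#' @export
score_signatures <- function(profiles, sets, rho = 0.01, meta = NULL) {
  ft_assert(length(profiles) >= 1, "need at least one profile")
  ft_assert(length(sets) >= 1, "need at least one signature set pair")
  ids <- names(sets)
  pids <- vapply(profiles, function(p) attr(p, "profile_id"), "")
  mk <- function() matrix(NA_real_, length(sets), length(profiles),
                          dimnames = list(ids, pids))
  up <- dn <- up_p <- dn_p <- mk()
  any_overlap <- FALSE
  for (j in seq_along(profiles)) {
    p <- profiles[[j]]
    ok <- is.finite(p$log2fc)
    stat <- stats::setNames(p$log2fc[ok], p$gene[ok])
    gidx <- seq_along(stat)
    names(gidx) <- names(stat)
    idx_up <- lapply(sets, function(s) unname(gidx[s$up$members[s$up$members %in% names(gidx)]]))
    idx_dn <- lapply(sets, function(s) unname(gidx[s$down$members[s$down$members %in% names(gidx)]]))
    if (any(lengths(idx_up) > 0) || any(lengths(idx_dn) > 0)) any_overlap <- TRUE
    r_up <- .camera_core(stat, idx_up, rho)
    r_dn <- .camera_core(stat, idx_dn, rho)
    up[, j] <- r_up$statistic; up_p[, j] <- r_up$p_value
    dn[, j] <- r_dn$statistic; dn_p[, j] <- r_dn$p_value
  }
  if (!any_overlap)
    stop("signature sets share no genes with any profile universe", call. = FALSE)
  structure(list(up = up, down = dn, up_p = up_p, down_p = dn_p, meta = meta),
            class = "signature_scores")
}

#' Aggregate signature scores per knocked-down gene
#'
#' A knocked-down gene typically has one signature per cell context; its
#' scores are collapsed to one value per profile. The published rule takes the
#' maximum for both streams; `down_aggregate = "min"` is provided as the
#' directionally conservative alternative for the down-stream.
#'
#' @param scores a `signature_scores` object (with `meta` populated).
#' @param down_aggregate `"max"` (literal published rule, default) or `"min"`.
#' @return list of class `gene_scores` with `up`/`down` gene x profile
#'   matrices.
#' @export
aggregate_by_gene <- function(scores, down_aggregate = c("max", "min")) {
  down_aggregate <- match.arg(down_aggregate)
  meta <- scores$meta
  ft_assert(!is.null(meta), "scores must carry signature metadata")
  sig_gene <- meta$perturbed_gene[match(rownames(scores$up), meta$signature_id)]
  ft_assert(!anyNA(sig_gene), "every signature needs a perturbed_gene")
  agg_fun <- function(x, f) {
    if (all(is.na(x))) return(NA_real_)
    f(x, na.rm = TRUE)
  }
  agg <- function(mat, f) {
    out <- do.call(rbind, lapply(split(seq_len(nrow(mat)), sig_gene), function(rows) {
      apply(mat[rows, , drop = FALSE], 2L, agg_fun, f = f)
    }))
    out
  }
  up <- agg(scores$up, max)
  dn <- agg(scores$down, if (down_aggregate == "max") max else min)
  dead <- rowSums(!is.na(up)) == 0 & rowSums(!is.na(dn)) == 0
  if (any(dead)) {
    warning(sprintf("%d knocked-down gene(s) with no surviving signatures dropped",
                    sum(dead)), call. = FALSE)
    up <- up[!dead, , drop = FALSE]
    dn <- dn[!dead, , drop = FALSE]
  }
  structure(list(up = up, down = dn, down_aggregate = down_aggregate),
            class = "gene_scores")
}

#' Final rank-difference transcriptomic similarity predictors
#'
#' Within each profile, the aggregated up-scores and down-scores are ranked
#' ascending (average ties; missing scores are assigned the median rank for
#' that profile, with a log message) and the final predictor is
#' `up_rank - down_rank`. For N knocked-down genes the final score lies in
#' `[-(N-1), N-1]`: a large positive score marks a knockdown whose signature
#' mimics the inducer response — a candidate death suppressor.
#'
#' @param gene_scores result of [aggregate_by_gene()].
#' @return list of class `similarity_predictors` with `final`, `up_rank`,
#'   `down_rank` (gene x profile matrices).
#' @export
similarity_predictors <- function(gene_scores) {
  up <- gene_scores$up; dn <- gene_scores$down
  ft_assert(nrow(up) >= 2, "need >= 2 knocked-down genes to rank")
  rank_col <- function(x) {
    r <- rank(x, ties.method = "average", na.last = "keep")
    if (anyNA(r)) {
      ft_log("assigning median rank to %d missing score(s)", sum(is.na(r)),
             level = "debug")
      r[is.na(r)] <- stats::median(r, na.rm = TRUE)
    }
    r
  }
  up_rank <- apply(up, 2L, rank_col)
  dn_rank <- apply(dn, 2L, rank_col)
  dimnames(up_rank) <- dimnames(dn_rank) <- dimnames(up)
  structure(list(final = up_rank - dn_rank, up_rank = up_rank,
                 down_rank = dn_rank), class = "similarity_predictors")
}

#' Long-format export of similarity predictors
#' @param sim a `similarity_predictors` object.
#' @param gene_scores the matching [aggregate_by_gene()] result.
#' @return data.frame gene, profile, up_score, down_score, up_rank, down_rank,
#'   final.
#' @export
similarity_long <- function(sim, gene_scores) {
  genes <- rownames(sim$final); profs <- colnames(sim$final)
  data.frame(
    gene = rep(genes, times = length(profs)),
    profile = rep(profs, each = length(genes)),
    up_score = as.vector(gene_scores$up),
    down_score = as.vector(gene_scores$down),
    up_rank = as.vector(sim$up_rank),
    down_rank = as.vector(sim$down_rank),
    final = as.vector(sim$final),
    stringsAsFactors = FALSE)
}
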