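# Dose-response fitting, AUC extraction and the six correlation predictors.
#
# Viability (% of untreated control) is modeled with the 4-parameter
# log-logistic curve
#   f(x) = c + (d - c) / (1 + exp(b * (ln x - ln e)))
# so for b > 0, d is the low-dose asymptote, c the high-dose asymptote and e
# the inflection dose. The AUC summarizes the fitted curve over the tested
# log10-dose range, normalized to [0, 1]: constant 100% viability gives 1,
# and high AUC means a resistant line.

ll4 <- function(x, b, c, d, e) c + (d - c) / (1 + exp(b * (log(x) - log(e))))

#' Fit a 4-parameter log-logistic dose-response curve
#'
#' Least-squares fit with multi-start initialization (inflection dose seeded at
#' every observed dose, both slope signs), bounded asymptotes c, d in
#' \[0, 120\]. The fit is canonicalized so that `c <= d` (the curve is
#' invariant under `(b, c, d) -> (-b, d, c)`). Deterministic given the data.
#'
#' @param dose positive concentrations (replicates allowed).
#' @param viability viability as % of control, >= 0.
#' @return object of class `dose_response_fit` with elements `b`, `c`, `d`,
#'   `e`, `rss`, `converged`, `degenerate`, and the observed dose range.
#' @examples
#' d <- 10^seq(-2, 1, length.out = 8)
#' fit <- fit_dose_response(d, ll4_curve(d, b = 1, c = 0, d = 100, e = 1))
#' round(fit$e, 4)
#' @export
fit_dose_response <- function(dose, viability) {
  ft_assert(length(dose) == length(viability), "dose/viability length mismatch")
  ok <- is.finite(dose) & is.finite(viability)
  dose <- dose[ok]; viability <- viability[ok]
  ft_assert(all(dose > 0), "doses must be positive")
  ft_assert(all(viability >= 0), "viability must be non-negative")
  dd <- sort(unique(dose))
  if (length(dd) < 4)
    stop(sprintf("need >= 4 distinct doses, got %d", length(dd)), call. = FALSE)

  if (stats::var(viability) == 0) {
    v <- viability[1L]
    return(structure(list(b = 1, c = v, d = v, e = stats::median(dd), rss = 0,
                          converged = TRUE, degenerate = TRUE,
                          dose_range = range(dose)),
                     class = "dose_response_fit"))
  }

  obj <- function(par) {
    f <- ll4(dose, par[1L], par[2L], par[3L], exp(par[4L]))
    sum((viability - f)^2)
  }
  lo <- c(-50, 0, 0, log(min(dd)) - 4)
  hi <- c(50, 120, 120, log(max(dd)) + 4)
  e_starts <- log(stats::quantile(dd, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE))
  c0 <- max(0, min(viability)); d0 <- min(120, max(viability))
  best <- NULL
  for (b0 in c(0.5, 1, 2, -1)) {
    for (le0 in e_starts) {
      fit <- tryCatch(
        stats::nlminb(c(b0, c0, d0, le0), obj, lower = lo, upper = hi,
                      control = list(rel.tol = 1e-12, iter.max = 500)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
  }
  ft_assert(!is.null(best), "dose-response optimization failed from all starts")
  par <- best$par
  b <- par[1L]; cc <- par[2L]; dd4 <- par[3L]; e <- exp(par[4L])
  if (cc > dd4) { tmp <- cc; cc <- dd4; dd4 <- tmp; b <- -b }
  structure(list(b = b, c = cc, d = dd4, e = e, rss = best$objective,
                 converged = is.finite(best$objective) && best$convergence %in% c(0L, 1L),
                 degenerate = FALSE, dose_range = range(dose)),
            class = "dose_response_fit")
}

#' Evaluate a 4-parameter log-logistic curve
#' @param x doses.
#' @param b,c,d,e curve parameters (see [fit_dose_response()]).
#' @export
ll4_curve <- function(x, b, c, d, e) ll4(x, b, c, d, e)

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("LL.4 fit: b=%.4g c=%.4g d=%.4g e=%.4g rss=%.4g%s\n",
              x$b, x$c, x$d, x$e, x$rss,
              if (x$degenerate) " (degenerate flat fit)" else ""))
  invisible(x)
}

#' Normalized area under a dose-response curve
#'
#' Integrates viability over log10 dose by the trapezoid rule and normalizes
#' by `(log10 dose range) * 100`, so constant 100% viability gives AUC = 1.
#' Viability is clipped to \[0, 100\] before integration. High AUC means a
#' resistant (non-vulnerable) line. Accepts either a fitted curve (sampled on
#' `n_grid` points) or a raw `data.frame(dose, viability)` (trapezoid on the
#' observed points, replicates averaged per dose).
#'
#' @param fit a `dose_response_fit` or a data.frame with `dose`, `viability`.
#' @param dose_range integration range; defaults to the observed range.
#' @param n_grid number of curve samples (>= 100) when `fit` is a fitted curve.
#' @return AUC in \[0, 1\].
#' @export
compute_auc <- function(fit, dose_range = NULL, n_grid = 201L) {
  if (inherits(fit, "dose_response_fit")) {
    dose_range <- dose_range %||% fit$dose_range
    ft_assert(diff(log10(dose_range)) > 0, "zero-width dose range")
    n_grid <- max(100L, as.integer(n_grid))
    lx <- seq(log10(dose_range[1L]), log10(dose_range[2L]), length.out = n_grid)
    v <- ll4(10^lx, fit$b, fit$c, fit$d, fit$e)
  } else {
    ft_assert(is.data.frame(fit) && all(c("dose", "viability") %in% names(fit)),
              "expected a dose_response_fit or data.frame(dose, viability)")
    agg <- stats::aggregate(viability ~ dose, fit, mean)
    ft_assert(nrow(agg) >= 2, "need >= 2 distinct doses")
    if (!is.null(dose_range)) agg <- agg[agg$dose >= dose_range[1L] & agg$dose <= dose_range[2L], ]
    lx <- log10(agg$dose)
    ft_assert(diff(range(lx)) > 0, "zero-width dose range")
    ord <- order(lx)
    lx <- lx[ord]; v <- agg$viability[ord]
  }
  v <- pmin(pmax(v, 0), 100)
  area <- sum(diff(lx) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
  area / (diff(range(lx)) * 100)
}

#' AUC table from a long viability table
#'
#' Fits one curve per (cell line, drug) and extracts normalized AUCs.
#'
#' @param viability data.frame with columns `cell_line`, `drug`, `dose`,
#'   `viability`.
#' @return numeric cell_line x drug matrix of AUCs in \[0, 1\]
#'   (a `VulnerabilityProfile`).
#' @export
auc_table <- function(viability) {
  need <- c("cell_line", "drug", "dose", "viability")
  ft_assert(all(need %in% names(viability)),
            sprintf("viability table needs columns: %s", paste(need, collapse = ", ")))
  lines <- sort(unique(viability$cell_line))
  drugs <- sort(unique(viability$drug))
  out <- matrix(NA_real_, length(lines), length(drugs),
                dimnames = list(lines, drugs))
  for (l in lines) for (dr in drugs) {
    sub <- viability[viability$cell_line == l & viability$drug == dr, ]
    if (nrow(sub) == 0) next
    fit <- fit_dose_response(sub$dose, sub$viability)
    out[l, dr] <- compute_auc(fit)
  }
  out
}

#' Correlation predictors: expression/dependency vs. drug AUCs
#'
#' For every gene and every drug, the Pearson correlation (on pairwise-complete
#' cell lines) between the gene's expression (or dependency) across cell lines
#' and that drug's AUC vector. With three drugs this yields the six correlation
#' predictors per gene. Genes with fewer than 3 complete pairs get `NA`.
#'
#' @param expression genes x cell lines matrix.
#' @param dependency genes x cell lines matrix.
#' @param auc cell_line x drug AUC matrix from [auc_table()].
#' @return data.frame with `gene` plus columns `expr_<drug>` and `dep_<drug>`.
#' @export
correlation_predictors <- function(expression, dependency, auc) {
  corr_block <- function(mat, what) {
    shared <- intersect(colnames(mat), rownames(auc))
    if (length(shared) < 3)
      stop(sprintf(
        "no usable shared cell lines between %s matrix and AUC table\n  matrix: %s\n  auc: %s",
        what, paste(utils::head(colnames(mat), 10), collapse = ", "),
        paste(utils::head(rownames(auc), 10), collapse = ", ")), call. = FALSE)
    m <- mat[, shared, drop = FALSE]
    out <- sapply(colnames(auc), function(dr) {
      y <- auc[shared, dr]
      r <- suppressWarnings(as.vector(stats::cor(t(m), y, use = "pairwise.complete.obs")))
      n_ok <- rowSums(!is.na(m) & rep(!is.na(y), each = nrow(m)))
      r[n_ok < 3] <- NA_real_
      r
    })
    colnames(out) <- paste(what, colnames(auc), sep = "_")
    out
  }
  e <- corr_block(expression, "expr")
  d <- corr_block(dependency, "dep")
  genes <- union(rownames(expression), rownames(dependency))
  res <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (cn in colnames(e)) res[[cn]] <- e[match(genes, rownames(expression)), cn]
  for (cn in colnames(d)) res[[cn]] <- d[match(genes, rownames(dependency)), cn]
  structure(res, drugs = colnames(auc), class = c("correlation_predictors", "data.frame"))
}

#' Threshold gene lists from one predictor block
#'
#' Per drug, the genes with r strictly above `threshold` (high list) and
#' strictly below `-threshold` (low list), plus the intersections across all
#' drugs.
#'
#' @param block genes x drugs matrix of correlations (e.g. the `expr_*` or
#'   `dep_*` columns of [correlation_predictors()]).
#' @param threshold correlation cutoff in (0, 1); strict inequality.
#' @return list with `high`, `low` (named per-drug lists of gene ids),
#'   `high_all`, `low_all` (all-drug intersections).
#' @export
threshold_gene_lists <- function(block, threshold = 0.65) {
  ft_assert(threshold > 0 && threshold < 1, "threshold must be in (0, 1)")
  ft_assert(is.matrix(block) && !is.null(rownames(block)), "block must be a named matrix")
  high <- apply(block, 2L, function(r) rownames(block)[!is.na(r) & r > threshold],
                simplify = FALSE)
  low <- apply(block, 2L, function(r) rownames(block)[!is.na(r) & r < -threshold],
               simplify = FALSE)
  list(high = high, low = low,
       high_all = sort(Reduce(intersect, high)),
       low_all = sort(Reduce(intersect, low)))
}

#' Extract one predictor block from correlation predictors
#' @param preds a [correlation_predictors()] result.
#' @param what `"expr"` or `"dep"`.
#' @return genes x drugs correlation matrix.
#' @export
predictor_block <- function(preds, what = c("expr", "dep")) {
  what <- match.arg(what)
  cols <- grep(paste0("^", what, "_"), names(preds), value = TRUE)
  m <- as.matrix(preds[, cols, drop = FALSE])
  rownames(m) <- preds$gene
  colnames(m) <- sub(paste0("^", what, "_"), "", cols)
  m
}
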