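make_predictors <- function(n = 60, n_prof = 7, seed = 41) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n))
  corr <- data.frame(gene = genes,
                     expr_erastin = rnorm(n), expr_RSL3 = rnorm(n),
                     expr_FIN56 = rnorm(n), dep_erastin = rnorm(n),
                     dep_RSL3 = rnorm(n), dep_FIN56 = rnorm(n),
                     stringsAsFactors = FALSE)
  final <- matrix(rnorm(n * n_prof), n, n_prof,
                  dimnames = list(genes, sprintf("p%02d", seq_len(n_prof))))
  sim <- structure(list(final = final, up_rank = final, down_rank = final * 0),
                   class = "similarity_predictors")
  list(corr = corr, sim = sim)
}

test_that("predictor matrix assembly: column count, normalization, oracle", {
  pr <- make_predictors(n = 60, n_prof = 7)
  pm <- build_predictor_matrix(pr$corr, pr$sim)
  expect_equal(ncol(pm), 13L)                         # 6 + (10 - 3)
  expect_equal(nrow(pm), 60L)
  expect_equal(unname(apply(pm, 2, min)), rep(0, 13))
  expect_equal(unname(apply(pm, 2, max)), rep(1, 13))

  # fractional-rank oracle per column
  raw <- attr(pm, "raw")
  for (j in seq_len(ncol(raw))) {
    r <- rank(raw[, j], ties.method = "average")
    expect_equal(unname(pm[, j]), unname((r - min(r)) / (max(r) - min(r))),
                 tolerance = 1e-12)
  }

  # monotone-transform invariance of the normalized matrix
  pr2 <- pr
  pr2$corr$expr_erastin <- exp(3 * pr$corr$expr_erastin)
  pm2 <- build_predictor_matrix(pr2$corr, pr2$sim)
  expect_equal(pm2[, ], pm[, ], tolerance = 1e-12)  # values only, not raw attr

  # genes with any missing predictor are dropped
  pr3 <- pr
  pr3$corr$dep_RSL3[5] <- NA
  pm3 <- build_predictor_matrix(pr3$corr, pr3$sim)
  expect_equal(nrow(pm3), 59L)
  expect_false(pr$corr$gene[5] %in% rownames(pm3))

  bad_corr <- pr$corr; bad_corr$gene <- paste0("x", bad_corr$gene)
  expect_error(build_predictor_matrix(bad_corr, pr$sim), "no genes shared")
})

test_that("embedding is deterministic, well-shaped, and respects duplicates", {
  pr <- make_predictors(n = 200)
  pm <- build_predictor_matrix(pr$corr, pr$sim)
  # plant an exact duplicate pair
  pm_dup <- unclass(pm)
  pm_dup["g002", ] <- pm_dup["g001", ]
  e1 <- embed_predictors(pm_dup, seed = 5)
  e2 <- embed_predictors(pm_dup, seed = 5)
  expect_identical(e1, e2)                            # same seed, same coords
  expect_equal(dim(e1), c(200L, 3L))
  expect_true(all(is.finite(e1$x)) && all(is.finite(e1$y)))

  d_dup <- sqrt(diff(e1$x[1:2])^2 + diff(e1$y[1:2])^2)
  all_d <- as.vector(dist(cbind(e1$x, e1$y)))
  expect_lte(d_dup, quantile(all_d, 0.01))            # duplicate-row probe

  expect_error(embed_predictors(pm_dup[1:10, ], n_neighbors = 15), "n_neighbors")
})

test_that("anchor ranking matches brute force and is isometry-invariant", {
  set.seed(43)
  emb <- data.frame(gene = sprintf("g%02d", 1:10), x = rnorm(10), y = rnorm(10))
  nb <- anchor_neighbors(emb, "g03", k = 4)
  d_oracle <- sqrt((emb$x - emb$x[3])^2 + (emb$y - emb$y[3])^2)
  names(d_oracle) <- emb$gene
  d_oracle <- sort(d_oracle[-3])
  expect_equal(nb$ranking$gene, names(d_oracle))
  expect_equal(nb$ranking$distance, unname(d_oracle))
  expect_false("g03" %in% nb$ranking$gene)            # anchor excluded
  expect_length(nb$top$members, 4)

  # rotation + translation leave the ranking unchanged
  th <- 0.77
  emb2 <- data.frame(gene = emb$gene,
                     x = cos(th) * emb$x - sin(th) * emb$y + 5,
                     y = sin(th) * emb$x + cos(th) * emb$y - 2)
  nb2 <- anchor_neighbors(emb2, "g03", k = 4)
  expect_equal(nb2$ranking$gene, nb$ranking$gene)
  expect_equal(nb2$ranking$distance, nb$ranking$distance, tolerance = 1e-12)

  expect_error(anchor_neighbors(emb, "nope"), "nope")
})

test_that("aggregate score reproduces the hand-computed recipe", {
  genes <- c("A", "B", "C", "D", "E")
  corr <- data.frame(gene = genes,
                     expr_d1 = c(0.9, 0.1, 0.5, -0.2, 0.3),
                     expr_d2 = c(0.8, 0.2, 0.4, -0.1, 0.2),
                     expr_d3 = c(0.7, 0.0, 0.6, -0.3, 0.1),
                     dep_d1 = c(0.1, 0.85, 0.2, 0.0, 0.5),
                     dep_d2 = c(0.2, 0.8, 0.3, 0.1, 0.4),
                     dep_d3 = c(0.0, 0.7, 0.1, -0.1, 0.6))
  final <- matrix(c(5, 4, 3, 2, 1,
                    5, 3, 4, 2, 1), 5, 2,
                  dimnames = list(genes, c("p1", "p2")))
  sim <- structure(list(final = final), class = "similarity_predictors")
  pm <- build_predictor_matrix(corr, sim)
  got <- aggregate_score(pm)

  # spreadsheet oracle
  a <- rowMeans(corr[, 2:4]); b <- rowMeans(corr[, 5:7])
  m <- pmax(a, b)
  r1 <- rank(m); r2 <- rank(rowMeans(final))
  oracle <- (r1 + r2) / 2
  expect_equal(got$score[match(genes, got$gene)], unname(oracle))

  # a gene top-ranked in both streams scores N
  expect_equal(max(got$score), got$score[got$gene == "A"])
  expect_equal(got$score[got$gene == "A"], 5)

  # max symmetry: swapping a and b when both below the max changes nothing
  corr2 <- corr
  corr2[3, 2:4] <- corr[3, 5:7]; corr2[3, 5:7] <- corr[3, 2:4]
  got2 <- aggregate_score(build_predictor_matrix(corr2, sim))
  expect_equal(got2$score, got$score)
})

test_that("stability analysis retains a duplicate of the anchor's row", {
  pr <- make_predictors(n = 60)
  pm <- unclass(build_predictor_matrix(pr$corr, pr$sim))
  pm["g002", ] <- pm["g001", ]                        # g002 duplicates anchor g001
  st <- stability_analysis(pm, "g001", k = 10, n_seeds = 50, master_seed = 9)
  expect_false("g001" %in% st$gene)
  expect_true(all(st$retention >= 0 & st$retention <= 1))
  expect_gte(st$retention[st$gene == "g002"], 0.95)

  st1 <- stability_analysis(pm, "g001", k = 10, n_seeds = 1, master_seed = 9)
  expect_true(all(st1$retention %in% c(0, 1)))        # degenerate n_seeds = 1
})

test_that("embedding fidelity: identity is 1, noise is ~0, resampling is stable", {
  set.seed(44)
  genes <- sprintf("g%03d", 1:200)
  m2 <- matrix(rnorm(400), 200, 2, dimnames = list(genes, c("c1", "c2")))
  emb_id <- data.frame(gene = genes, x = m2[, 1], y = m2[, 2])
  expect_equal(embedding_fidelity(m2, emb_id, n_pairs = 2000), 1.0)

  emb_rnd <- data.frame(gene = genes, x = rnorm(200), y = rnorm(200))
  expect_lt(abs(embedding_fidelity(m2, emb_rnd, n_pairs = 10000)), 0.1)

  f1 <- embedding_fidelity(m2, emb_id, n_pairs = 10000, seed = 1)
  f2 <- embedding_fidelity(m2, emb_id, n_pairs = 10000, seed = 2)
  expect_lt(abs(f1 - f2), 0.05)
})

test_that("candidate filters match an exhaustive scan of the world", {
  w <- small_world(3)
  pr <- make_predictors(n = 50)
  genes <- rownames(w$dependency)[1:50]
  emb <- data.frame(gene = genes, x = rnorm(50), y = rnorm(50))
  nb <- anchor_neighbors(emb, genes[1], k = 10)
  out <- filter_candidates(nb, w$dependency, w$citations,
                           druggable = genes[1:5],
                           essentiality_threshold = -0.5,
                           essential_fraction = 0.9)
  expect_equal(nrow(out), 49L)                        # nothing silently removed
  cited_genes <- unique(w$citations$gene[w$citations$count > 0])
  for (i in seq_len(nrow(out))) {
    g <- out$gene[i]
    expect_equal(out$pan_essential[i],
                 mean(w$dependency[g, ] < -0.5) >= 0.9)
    expect_equal(out$previously_cited[i], g %in% cited_genes)
    expect_equal(out$druggable[i], g %in% genes[1:5])
  }

  # explicit pan-essential case
  dep <- matrix(-1, 2, 20, dimnames = list(c("ess", "fine"), sprintf("l%02d", 1:20)))
  dep["fine", ] <- 0
  emb2 <- data.frame(gene = c("ess", "fine", "anch"), x = c(1, 2, 0), y = 0)
  nb2 <- anchor_neighbors(emb2, "anch", k = 2)
  out2 <- filter_candidates(nb2, dep, citations = NULL)
  expect_true(out2$pan_essential[out2$gene == "ess"])
  expect_false(out2$pan_essential[out2$gene == "fine"])
})
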