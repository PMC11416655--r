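make_compendium <- function(n_genes = 60, n_sigs = 6, seed = 31) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  sigs <- sprintf("sig%02d", seq_len(n_sigs))
  m <- matrix(rnorm(n_genes * n_sigs), n_genes, n_sigs,
              dimnames = list(genes, sigs))
  signature_compendium(m, data.frame(
    signature_id = sigs, perturbed_gene = sprintf("KD%02d", seq_len(n_sigs)),
    cell_line = "A375", perturbation_type = "trt_sh.cgs",
    stringsAsFactors = FALSE))
}

test_that("signature set extraction matches the sort-and-slice oracle", {
  comp <- make_compendium()
  sets <- extract_signature_sets(comp, K = 10)
  expect_length(sets, 6)
  for (s in sets) {
    z <- comp$matrix[, s$signature_id]
    expect_equal(sort(s$up$members),
                 sort(names(sort(z, decreasing = TRUE))[1:10]))
    expect_equal(sort(s$down$members), sort(names(sort(z))[1:10]))
    expect_length(intersect(s$up$members, s$down$members), 0)
  }
  # a signature with < 2K usable genes is skipped with a warning
  comp$matrix[1:45, 2] <- NA
  expect_warning(sets2 <- extract_signature_sets(comp, K = 10), "sig02")
  expect_length(sets2, 5)
})

test_that("camera_pr handles degenerate input and basic sign structure", {
  stat <- setNames(rep(2, 10), sprintf("g%02d", 1:10))
  r <- camera_pr(stat, c("g01", "g02"), rho = 0.01)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  stat2 <- setNames(c(5, 4, 3, 2, 1, 0), sprintf("g%02d", 1:6))
  expect_gt(camera_pr(stat2, c("g01", "g02"), rho = 0)$statistic, 0)
  expect_error(camera_pr(stat2, "g01"), ">= 2")
})

test_that("camera_pr with rho = 0 is an ordinary pooled two-sample t-test", {
  set.seed(33)
  for (i in 1:20) {
    G <- sample(30:200, 1); m <- sample(2:10, 1)
    stat <- setNames(rnorm(G), sprintf("g%03d", 1:G))
    members <- sample(names(stat), m)
    got <- camera_pr(stat, members, rho = 0)
    tt <- t.test(stat[members], stat[!names(stat) %in% members],
                 var.equal = TRUE)
    expect_equal(got$statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("camera_pr agrees with limma::cameraPR at the default rho", {
  set.seed(34)
  G <- 150
  stat <- setNames(rnorm(G), sprintf("g%03d", 1:G))
  for (m in c(5, 20, 50)) {
    members <- sample(names(stat), m)
    got <- camera_pr(stat, members, rho = 0.01)
    ref <- limma::cameraPR(stat, list(set = members), inter.gene.cor = 0.01,
                           sort = FALSE)
    expect_equal(got$p_value, ref$PValue[1], tolerance = 1e-10)
    expect_equal(ref$Direction[1], if (got$statistic > 0) "Up" else "Down")
  }
})

test_that("camera_pr invariances: location shift, positive scaling, VIF monotonicity", {
  set.seed(35)
  stat <- setNames(rnorm(100), sprintf("g%03d", 1:100))
  members <- sample(names(stat), 12)
  base <- camera_pr(stat, members, rho = 0.01)
  expect_equal(camera_pr(stat + 7, members, rho = 0.01)$statistic,
               base$statistic, tolerance = 1e-12)
  expect_equal(camera_pr(stat * 3.2, members, rho = 0.01)$statistic,
               base$statistic, tolerance = 1e-12)
  # |t| strictly decreases as rho grows (delta != 0)
  ts <- vapply(c(0, 0.05, 0.2, 0.5), function(r)
    abs(camera_pr(stat, members, rho = r)$statistic), numeric(1))
  expect_true(all(diff(ts) < 0))
})

test_that("null camera p-values are uniform over random draws", {
  set.seed(36)
  G <- 200
  members <- sprintf("g%03d", sample(G, 20))
  ps <- vapply(1:500, function(i) {
    stat <- setNames(rnorm(G), sprintf("g%03d", 1:G))
    camera_pr(stat, members, rho = 0)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("score_signatures recovers the planted structure of the world", {
  w <- small_world(3)
  sets <- extract_signature_sets(w$compendium, K = 20)
  scores <- score_signatures(w$profiles, sets, rho = 0.01,
                             meta = w$compendium$meta)
  expect_equal(dim(scores$up), c(length(sets), length(w$profiles)))

  meta <- w$compendium$meta
  planted_sigs <- meta$signature_id[meta$perturbed_gene %in% w$truth$planted]
  noise_sigs <- setdiff(meta$signature_id, planted_sigs)
  # planted knockdown signatures: up-sets up-shifted, down-sets down-shifted
  expect_gt(mean(scores$up[planted_sigs, ]), 0)
  expect_lt(mean(scores$down[planted_sigs, ]), 0)
  expect_gt(mean(scores$up[planted_sigs, ]), mean(scores$up[noise_sigs, ]) + 2)
})

test_that("per-gene aggregation matches a group-by oracle for both modes", {
  up <- matrix(c(1.2, 3.4, -0.5, 2, 0, 1), 3, 2,
               dimnames = list(c("s1", "s2", "s3"), c("pA", "pB")))
  dn <- -up
  meta <- data.frame(signature_id = c("s1", "s2", "s3"),
                     perturbed_gene = c("KD1", "KD1", "KD2"),
                     cell_line = "x", perturbation_type = "trt_sh.cgs")
  sc <- structure(list(up = up, down = dn, meta = meta),
                  class = "signature_scores")
  agg <- aggregate_by_gene(sc)                        # literal rule: max/max
  expect_equal(agg$up["KD1", "pA"], 3.4)
  expect_equal(agg$down["KD1", "pA"], max(dn[1:2, "pA"]))
  expect_equal(agg$up["KD2", ], up["s3", ])           # single context: identity
  agg2 <- aggregate_by_gene(sc, down_aggregate = "min")
  expect_equal(agg2$down["KD1", "pA"], min(dn[1:2, "pA"]))

  set.seed(37)
  n <- 40
  meta_r <- data.frame(signature_id = sprintf("s%02d", 1:n),
                       perturbed_gene = sample(sprintf("KD%02d", 1:12), n, TRUE),
                       cell_line = "x", perturbation_type = "trt_sh.cgs")
  upr <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(meta_r$signature_id, c("p1", "p2", "p3")))
  scr <- structure(list(up = upr, down = -upr, meta = meta_r),
                   class = "signature_scores")
  aggr <- aggregate_by_gene(scr)
  for (g in unique(meta_r$perturbed_gene)) {
    rows <- meta_r$signature_id[meta_r$perturbed_gene == g]
    expect_equal(aggr$up[g, ], apply(upr[rows, , drop = FALSE], 2, max))
  }
})

test_that("final similarity scores are rank differences with the stated range", {
  # N = 2 hand case: A has the higher up-score and lower down-score
  up <- matrix(c(2, 1), 2, 1, dimnames = list(c("A", "B"), "p1"))
  dn <- matrix(c(1, 2), 2, 1, dimnames = list(c("A", "B"), "p1"))
  sim <- similarity_predictors(structure(list(up = up, down = dn),
                                         class = "gene_scores"))
  expect_equal(sim$final["A", "p1"], 1)
  expect_equal(sim$final["B", "p1"], -1)

  set.seed(38)
  N <- 100
  upr <- matrix(rnorm(N * 4), N, 4,
                dimnames = list(sprintf("KD%03d", 1:N), sprintf("p%d", 1:4)))
  dnr <- matrix(rnorm(N * 4), N, 4, dimnames = dimnames(upr))
  simr <- similarity_predictors(structure(list(up = upr, down = dnr),
                                          class = "gene_scores"))
  oracle <- apply(upr, 2, rank) - apply(dnr, 2, rank)  # rank-subtraction oracle
  expect_equal(simr$final, oracle)
  expect_true(all(simr$final >= -(N - 1) & simr$final <= N - 1))
})

test_that("negating the profile statistic negates the final scores", {
  # single-context signatures so max-aggregation is the identity and the
  # antisymmetry is exact (no rank ties with continuous scores)
  w <- small_world(3)
  meta <- w$compendium$meta
  keep <- meta$signature_id[!duplicated(meta$perturbed_gene)][1:40]
  sets <- extract_signature_sets(w$compendium, K = 15)[keep]
  p1 <- w$profiles[[1]]
  neg <- fc_profile("neg", p1$gene, -p1$log2fc)
  s_pos <- score_signatures(list(p1), sets, rho = 0.01, meta = meta)
  s_neg <- score_signatures(list(neg), sets, rho = 0.01, meta = meta)
  expect_equal(unname(s_neg$up), unname(-s_pos$up), tolerance = 1e-12)
  sim_pos <- similarity_predictors(aggregate_by_gene(s_pos))
  sim_neg <- similarity_predictors(aggregate_by_gene(s_neg))
  expect_equal(unname(sim_neg$final), unname(-sim_pos$final))
})
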