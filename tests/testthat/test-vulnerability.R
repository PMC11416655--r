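test_that("noiseless LL.4 data are recovered to 1e-4 relative", {
  d <- 10^seq(-2, 1.5, length.out = 8)
  v <- ll4_curve(d, b = 1, c = 0, d = 100, e = 1)
  fit <- fit_dose_response(d, v)
  expect_true(fit$converged)
  expect_lt(abs(fit$b - 1) / 1, 1e-4)
  expect_lt(abs(fit$c - 0), 1e-2)          # absolute: true value is 0
  expect_lt(abs(fit$d - 100) / 100, 1e-4)
  expect_lt(abs(fit$e - 1) / 1, 1e-4)
})

test_that("degenerate and invalid dose-response inputs", {
  d <- 10^seq(-2, 1, length.out = 8)
  fit <- fit_dose_response(d, rep(100, 8))
  expect_true(fit$degenerate)
  expect_equal(fit$c, 100)
  expect_equal(fit$d, 100)
  expect_error(fit_dose_response(c(1, 2, 3), c(90, 50, 10)), "4 distinct doses")
  expect_error(fit_dose_response(c(-1, 1, 2, 4), c(1, 1, 1, 2)), "positive")
})

test_that("noisy inflection-dose recovery: median relative error < 0.2", {
  d <- rep(10^seq(-2, 1.5, length.out = 8), each = 3)
  errs <- vapply(1:50, function(s) {
    set.seed(s)
    v <- pmax(0, ll4_curve(d, 1.3, 5, 100, 0.5) + rnorm(length(d), 0, 5))
    fit <- fit_dose_response(d, v)
    abs(fit$e - 0.5) / 0.5
  }, numeric(1))
  expect_lt(median(errs), 0.2)
})

test_that("AUC normalization: analytic cases and fine-grid oracle", {
  pts <- data.frame(dose = 10^(0:3), viability = 100)
  expect_equal(compute_auc(pts), 1.0)

  # viability linear in log10 dose from 100 down to 0 -> triangle, AUC = 0.5
  lin <- data.frame(dose = 10^seq(0, 3, length.out = 7),
                    viability = seq(100, 0, length.out = 7))
  expect_equal(compute_auc(lin), 0.5)

  # fitted random LL.4 curve vs a 10,000-point Riemann-sum oracle
  set.seed(5)
  for (i in 1:5) {
    b <- runif(1, 0.5, 3); cc <- runif(1, 0, 20); dd <- runif(1, 80, 100)
    e <- 10^runif(1, -1, 1)
    fit <- structure(list(b = b, c = cc, d = dd, e = e, dose_range = c(0.01, 10),
                          degenerate = FALSE), class = "dose_response_fit")
    lx <- seq(log10(0.01), log10(10), length.out = 10000)
    oracle <- mean(pmin(pmax(ll4_curve(10^lx, b, cc, dd, e), 0), 100)) / 100
    expect_lt(abs(compute_auc(fit, n_grid = 2001) - oracle), 1e-3)
  }
})

test_that("AUC is monotone in pointwise viability", {
  fit_hi <- structure(list(b = 1, c = 20, d = 100, e = 1, dose_range = c(0.01, 10),
                           degenerate = FALSE), class = "dose_response_fit")
  fit_lo <- structure(list(b = 1, c = 0, d = 80, e = 1, dose_range = c(0.01, 10),
                           degenerate = FALSE), class = "dose_response_fit")
  expect_gt(compute_auc(fit_hi), compute_auc(fit_lo))
})

test_that("correlation predictors: exact vectors, formula oracle, invariances", {
  set.seed(11)
  lines <- sprintf("CL%02d", 1:5)
  auc <- matrix(runif(15), 5, 3, dimnames = list(lines, c("erastin", "RSL3", "FIN56")))
  ex <- matrix(rnorm(40), 8, 5, dimnames = list(sprintf("g%d", 1:8), lines))
  ex[1, ] <- auc[, "erastin"]            # perfect positive
  ex[2, ] <- -auc[, "erastin"]           # perfect negative
  dep <- matrix(rnorm(40), 8, 5, dimnames = dimnames(ex))
  preds <- correlation_predictors(ex, dep, auc)
  expect_equal(ncol(preds) - 1L, 6L)
  expect_equal(preds$expr_erastin[preds$gene == "g1"], 1.0)
  expect_equal(preds$expr_erastin[preds$gene == "g2"], -1.0)

  # covariance-formula oracle to 1e-12
  for (g in rownames(ex)) for (dr in colnames(auc)) {
    x <- ex[g, ]; y <- auc[, dr]
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(preds[preds$gene == g, paste0("expr_", dr)], oracle,
                 tolerance = 1e-12)
  }

  # Pearson is invariant to positive affine rescaling of expression
  preds2 <- correlation_predictors(3.7 * ex + 11, dep, auc)
  expect_equal(predictor_block(preds2, "expr"), predictor_block(preds, "expr"),
               tolerance = 1e-12)

  # pairwise-complete: a gene with < 3 complete pairs is NA
  ex[3, 1:3] <- NA
  preds3 <- correlation_predictors(ex, dep, auc)
  expect_true(is.na(preds3$expr_erastin[preds3$gene == "g3"]))

  bad <- ex; colnames(bad) <- sprintf("XX%02d", 1:5)
  expect_error(correlation_predictors(bad, dep, auc), "shared cell lines")
})

test_that("threshold lists use strict inequality and match a brute-force scan", {
  block <- rbind(inA = c(0.7, 0.66, 0.9), onB = c(0.7, 0.65, 0.9))
  colnames(block) <- c("d1", "d2", "d3")
  out <- threshold_gene_lists(block, 0.65)
  expect_true("inA" %in% out$high_all)
  expect_false("onB" %in% out$high_all)   # 0.65 is excluded (strict)

  set.seed(13)
  rb <- matrix(runif(600, -1, 1), 200, 3,
               dimnames = list(sprintf("g%03d", 1:200), c("a", "b", "c")))
  res <- threshold_gene_lists(rb, 0.65)
  for (dr in colnames(rb)) {
    expect_setequal(res$high[[dr]], rownames(rb)[rb[, dr] > 0.65])
    expect_setequal(res$low[[dr]], rownames(rb)[rb[, dr] < -0.65])
  }
  oracle_all <- rownames(rb)[apply(rb > 0.65, 1, all)]
  expect_setequal(res$high_all, oracle_all)
})

test_that("auc_table fits every (line, drug) pair of the synthetic world", {
  w <- small_world(3)
  auc <- auc_table(w$viability)
  expect_equal(dim(auc), dim(w$truth$auc_true))
  expect_true(all(auc >= 0 & auc <= 1))
  # fitted AUCs track the latent truth closely
  expect_gt(cor(as.vector(auc), as.vector(w$truth$auc_true)), 0.95)
})
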