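# Gene-trait association from individual-level data and summary
# statistics, plus the bookkeeping operations around it.

test_that("individual-level z-scores are calibrated under the null", {
  set.seed(50)
  n <- 1000
  rejections <- vapply(1:2000, function(i) {
    y <- rnorm(n)
    e_hat <- rnorm(n)
    abs(zscore_individual(y, e_hat)$z) > 1.96
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.01)
})

test_that("the OLS slope estimate is unbiased", {
  set.seed(51)
  gammas <- vapply(1:200, function(i) {
    e_hat <- rnorm(2000)
    y <- 0.3 * e_hat + rnorm(2000)
    zscore_individual(y, e_hat)$gamma_hat
  }, numeric(1))
  expect_lt(abs(mean(gammas) - 0.3), 0.02)
})

test_that("degenerate predictions are flagged instead of crashing", {
  y <- rnorm(100)
  res <- zscore_individual(y, rep(1, 100))
  expect_equal(res$flag, "constant_prediction")
  expect_true(is.na(res$z))
  res2 <- zscore_individual(y, y)
  expect_equal(res2$flag, "exact_fit")
  expect_equal(abs(res2$z), 40)
})

test_that("a single-SNP model gives Z = sign(beta) * z_j exactly", {
  w <- data.frame(id = "rs1", ref = "A", alt = "G", beta = -0.7)
  gwas <- data.frame(id = "rs1", a1 = "G", a2 = "A", z = 2.3, n = 5000)
  ld <- list(ids = "rs1", R = matrix(1, 1, 1), sd = 0.61)
  res <- zscore_sumstats(w, gwas, ld)
  expect_identical(res$z, -2.3)
  # all z_j = 0 gives Z = 0
  gwas0 <- data.frame(id = "rs1", a1 = "G", a2 = "A", z = 0, n = 5000)
  expect_equal(zscore_sumstats(w, gwas0, ld)$z, 0)
})

test_that("summary z-scores are invariant to allele flips", {
  set.seed(52)
  cfg <- sim_config(n_samples = 800L, n_snps = 10L, n_tissues = 2L,
                    n_ct_eqtls = 2L, n_ts_eqtls_per_tissue = 1L,
                    seed = 52L)
  g <- simulate_genotypes(cfg)
  sim <- simulate_expression(g, cfg)
  gw <- simulate_gwas(g, sim$expression, gamma = 0.2, seed = 53L)
  w <- data.frame(id = g$snps$id[1:4], ref = g$snps$ref[1:4],
                  alt = g$snps$alt[1:4], beta = c(0.5, -0.3, 0.2, 0.1))
  base <- zscore_sumstats(w, gw$sumstats, gw$ld_blocks[[1]])
  # flip SNP 2 in the GWAS: swap alleles and negate z
  flipped <- gw$sumstats
  flipped[2, c("a1", "a2")] <- flipped[2, c("a2", "a1")]
  flipped$z[2] <- -flipped$z[2]
  res <- zscore_sumstats(w, flipped, gw$ld_blocks[[1]])
  expect_equal(res$z, base$z, tolerance = 1e-10)
  # unresolvable alleles are dropped with a coverage warning
  mism <- gw$sumstats
  mism$a1[1] <- "T"; mism$a2[1] <- "C"
  expect_warning(res2 <- zscore_sumstats(w, mism, gw$ld_blocks[[1]]),
                 "weight SNPs")
  expect_equal(res2$n_snps_used, 3L)
})

test_that("summary-based and individual-level z-scores agree in-sample", {
  set.seed(54)
  agree <- vapply(1:25, function(r) {
    cfg <- sim_config(n_samples = 2000L, n_snps = 10L, n_tissues = 2L,
                      n_ct_eqtls = 2L, n_ts_eqtls_per_tissue = 1L,
                      noise_sd = 1, seed = 5400 + r)
    g <- simulate_genotypes(cfg)
    sim <- simulate_expression(g, cfg)
    gw <- simulate_gwas(g, sim$expression, gamma = 0.1, seed = 5400 + r)
    e <- sim$expression
    sel <- stepwise_select(e$values[, 1], g$dosages)$selected
    if (length(sel) == 0L) sel <- sim$truth$ct_idx
    fit <- wls_fit(e$values[, 1], g$dosages[, sel, drop = FALSE],
                   mask = rep(TRUE, 2000))
    e_hat <- as.numeric(g$dosages[, sel, drop = FALSE] %*% fit$beta)
    z_ind <- zscore_individual(as.numeric(scale(gw$trait)),
                               as.numeric(scale(e_hat)))$z
    w <- data.frame(id = g$snps$id[sel], ref = g$snps$ref[sel],
                    alt = g$snps$alt[sel], beta = unname(fit$beta))
    z_sum <- zscore_sumstats(w, gw$sumstats, gw$ld_blocks[[1]])$z
    c(z_ind, z_sum)
  }, numeric(2))
  expect_lt(max(abs(agree[1, ] - agree[2, ])), 0.05)
  expect_gt(cor(agree[1, ], agree[2, ]), 0.999)
})

test_that("the MHC mask removes exactly the GRCh38 6p21.3 interval", {
  genes <- data.frame(gene = c("a", "b", "c", "d", "e"),
                      chrom = c("6", "6", "6", "7", "chr6"),
                      start = c(30000000, 28000000, 25000000, 30000000,
                                33480577),
                      end = c(30000100, 28510119, 26000000, 30000100,
                              34000000))
  out <- mask_mhc(genes)
  # inside: removed; end exactly one below the lower bound: retained;
  # other chromosome: retained; start exactly at the upper bound: removed
  expect_setequal(out$gene, c("b", "c", "d"))
  snps <- data.frame(chrom = "6", pos = c(28510119, 28510120, 33480577,
                                          33480578))
  expect_equal(mask_mhc(snps)$pos, c(28510119, 33480578))
  expect_error(mask_mhc(genes, build = "GRCh37"), "unknown build")
})

test_that("p-value adjustment matches hand-checked vectors", {
  p <- c(0.01, 0.02, 0.03)
  expect_equal(adjust_pvalues(p, "bonferroni"), c(0.03, 0.06, 0.09))
  expect_equal(adjust_pvalues(p, "bh"), c(0.03, 0.03, 0.03))
  expect_equal(adjust_pvalues(0.04, "bonferroni"), 0.04)
  expect_equal(adjust_pvalues(0.04, "bh"), 0.04)
})

test_that("effective N follows the balanced-design formula", {
  expect_equal(effective_n(1000, 1000), 2000)
  expect_equal(effective_n(100, 900), 360)
  # monotone in n_case, bounded by 4 * n_control
  ns <- effective_n(c(1e3, 1e5, 1e7), 500)
  expect_true(all(diff(ns) > 0))
  expect_true(all(ns < 4 * 500))
  expect_error(effective_n(0, 10), "positive")
})

test_that("correlated-gene pruning keeps the lower-P gene", {
  set.seed(55)
  base <- rnorm(200)
  pred <- list(A = base + rnorm(200, sd = 0.5),
               B = base + rnorm(200, sd = 0.5),
               C = rnorm(200))
  # force the pairwise structure: A-B correlated, C independent
  stopifnot(cor(pred$A, pred$B)^2 > 0.5)
  assoc <- data.frame(gene = c("A", "B", "C"), p = c(1e-8, 1e-3, 0.02))
  out <- prune_correlated_genes(assoc, pred)
  expect_equal(out$kept, c(TRUE, FALSE, TRUE))
  # uncorrelated genes are all retained
  pred0 <- list(A = rnorm(100), B = rnorm(100), C = rnorm(100))
  out0 <- prune_correlated_genes(assoc, pred0)
  expect_true(all(out0$kept))
})

test_that("greedy pruning resolves correlation chains by ascending P", {
  # A-B and B-C correlated, A-C not; P(A) < P(B) < P(C) keeps {A, C}
  set.seed(56)
  n <- 500
  a <- rnorm(n)
  c_ <- 0.25 * scale(a)[, 1] + sqrt(1 - 0.0625) * rnorm(n)
  # with cor(a, c) = rho, b = a* + c* has r2 = (1 + rho)/2 to each endpoint
  b <- scale(a)[, 1] + scale(c_)[, 1] + 0.1 * rnorm(n)
  pred <- list(A = a, B = b, C = c_)
  stopifnot(cor(a, b)^2 > 0.5, cor(b, c_)^2 > 0.5, cor(a, c_)^2 < 0.1)
  assoc <- data.frame(gene = c("A", "B", "C"), p = c(1e-6, 1e-4, 1e-2))
  out <- prune_correlated_genes(assoc, pred)
  expect_equal(out$kept, c(TRUE, FALSE, TRUE))
  # every rejected gene conflicts with an accepted one (maximality)
  expect_gt(cor(pred$B, pred$A)^2, 0.5)
  # constant prediction is treated as uncorrelated, with r2 = 0
  pred$B <- rep(2, n)
  out2 <- prune_correlated_genes(assoc, pred)
  expect_true(all(out2$kept))
})

test_that("prediction metrics follow the F-test on (1, n-2) df", {
  y <- rnorm(102)
  res <- evaluate_prediction(y, y)
  expect_equal(res$r2, 1)
  expect_equal(res$signed_r2, 1)
  expect_equal(res$f_p, 0)
  resn <- evaluate_prediction(y, -y)
  expect_equal(resn$signed_r2, -1)
  # r = 0.2, n = 102: F = 0.04 * 100 / 0.96 = 4.1667
  set.seed(57)
  repeat {
    yp <- 0.2 * scale(y)[, 1] + rnorm(102)
    if (abs(cor(y, yp) - 0.2) < 0.001) break
  }
  res2 <- evaluate_prediction(y, yp)
  r2 <- cor(y, yp)^2
  expect_equal(res2$f_p,
               pf(r2 * 100 / (1 - r2), 1, 100, lower.tail = FALSE))
  expect_equal(pf(4.16666667, 1, 100, lower.tail = FALSE), 0.04386088,
               tolerance = 1e-6)
  resc <- evaluate_prediction(y, rep(0, 102))
  expect_equal(resc$flag, "constant_prediction")
  expect_equal(resc$r2, 0)
  expect_equal(resc$f_p, 1)
})
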