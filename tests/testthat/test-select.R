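# EBIC, stepwise selection, PC selection and weighted least squares.

test_that("EBIC evaluates the penalized Gaussian profile likelihood", {
  # rss/n = 1/(2*pi) makes -2*ll = n: value is n + k*log(n) + 2*l*k*log(m)
  expect_equal(ebic(100 / (2 * pi), 100, 3, 50, 0.5),
               100 + 3 * log(100) + 3 * log(50), tolerance = 1e-12)
  expect_equal(ebic(100 / (2 * pi), 100, 3, 50, 0.5), 125.551579574,
               tolerance = 1e-9)
  # empty model: pure likelihood term
  rss <- 7.3; n <- 40
  expect_equal(ebic(rss, n, 0, 10, 0.5),
               n * (log(2 * pi * rss / n) + 1))
  # strictly increasing in lambda for a nonempty model
  vals <- vapply(c(0, 0.25, 0.5, 1), function(l) ebic(5, 50, 2, 20, l),
                 numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_error(ebic(0, 50, 1, 10), "positive")
})

test_that("stepwise selection returns the empty set on pure noise", {
  # The first forward add fires when the best of M chi-square(1) score
  # statistics exceeds the penalty log(N) + 2*lambda*log(M); at N = 300,
  # M = 50, lambda = 0.5 that is 9.62, so the empty-model rate is about
  # (1 - P(chisq > 9.62))^50 = 0.91. Check the empirical rate against
  # that closed-form prediction within 3 binomial SDs (+/- 0.09).
  hits <- 0L
  for (rep in 1:100) {
    set.seed(1000 + rep)
    X <- matrix(rnorm(300 * 50), 300, 50)
    y <- rnorm(300)
    res <- stepwise_select(y, X, cfg = ebic_config(lambda = 0.5))
    if (length(res$selected) == 0L) hits <- hits + 1L
  }
  pen <- log(300) + 2 * 0.5 * log(50)
  predicted <- (1 - pchisq(pen, 1, lower.tail = FALSE))^50
  expect_lt(abs(hits / 100 - predicted), 0.09)
})

test_that("stepwise selection recovers a planted two-SNP signal", {
  # The planted SNPs have per-SNP t^2 in the thousands, so both must
  # always enter; the exact-set rate is bounded by the null false-positive
  # rate over the remaining 48 SNPs, about 0.91 at this penalty.
  exact <- 0L
  both <- 0L
  for (rep in 1:100) {
    set.seed(2000 + rep)
    X <- matrix(rnorm(400 * 50), 400, 50)
    y <- X[, 3] + X[, 17] + rnorm(400, sd = 0.2)
    res <- stepwise_select(y, X, cfg = ebic_config(lambda = 0.5))
    if (identical(res$selected, c(3L, 17L))) exact <- exact + 1L
    if (all(c(3L, 17L) %in% res$selected)) both <- both + 1L
  }
  expect_equal(both, 100L)
  expect_gte(exact, 85L)
})

test_that("fixed-set members are retained even when pure noise", {
  set.seed(30)
  X <- matrix(rnorm(200 * 20), 200, 20)
  y <- X[, 2] + rnorm(200, sd = 0.3)
  res <- stepwise_select(y, X, s0 = 5L)
  expect_true(5L %in% res$selected)
  expect_true(all(res$s0 %in% res$selected))
  # reported EBIC matches recomputing the criterion on the returned set
  fit <- stats::lm.fit(cbind(1, X[, res$selected, drop = FALSE]), y)
  expect_equal(res$ebic,
               ebic(sum(fit$residuals^2), 200, length(res$selected), 20, 0.5),
               tolerance = 1e-9)
})

test_that("the EBIC trace decreases strictly within each phase", {
  for (rep in 1:20) {
    set.seed(3000 + rep)
    X <- matrix(rnorm(250 * 30), 250, 30)
    k <- sample(0:4, 1)
    y <- rnorm(250, sd = 0.5)
    if (k > 0) y <- y + X[, seq_len(k), drop = FALSE] %*% rep(0.7, k)
    res <- stepwise_select(y, X)
    expect_true(all(res$selected >= res$s0))
    for (phase in c("forward", "backward")) {
      vals <- res$trace$ebic[res$trace$phase %in% c("init", phase)]
      expect_true(all(diff(vals) < 0))
    }
  }
})

test_that("stepwise plus enumeration matches the brute-force EBIC oracle", {
  for (rep in 1:20) {
    set.seed(4000 + rep)
    X <- matrix(rnorm(300 * 10), 300, 10)
    k <- sample(0:3, 1)
    y <- rnorm(300, sd = 0.4)
    if (k > 0) y <- y + X[, seq_len(k), drop = FALSE] %*% rep(0.5, k)
    res <- stepwise_select(y, X)
    oracle <- brute_force_ebic(y, X, 0.5)
    expect_equal(res$ebic, oracle$ebic, tolerance = 1e-9)
    expect_identical(res$selected, as.integer(oracle$selected))
  }
})

test_that("collinear candidates never enter the model", {
  set.seed(31)
  X <- matrix(rnorm(150 * 6), 150, 6)
  X[, 6] <- X[, 1]  # exact duplicate
  y <- X[, 1] + rnorm(150, sd = 0.2)
  res <- stepwise_select(y, X)
  expect_false(all(c(1L, 6L) %in% res$selected))
})

test_that("weighted selection accepts per-row weights", {
  set.seed(32)
  X <- matrix(rnorm(200 * 10), 200, 10)
  y <- X[, 4] + rnorm(200, sd = 0.3)
  w <- runif(200, 0.5, 1)
  res <- stepwise_select(y, X, weights = w)
  expect_true(4L %in% res$selected)
})

test_that("PC count follows the eigenvalue cutoff with a floor of one", {
  # strong single shared factor: exactly one eigenvalue above 2.0
  set.seed(33)
  n <- 400; k <- 10
  f <- rnorm(n)
  vals <- matrix(f, n, k) + matrix(rnorm(n * k, sd = 0.8), n, k)
  e <- expression_tensor(vals)
  pcs <- select_pcs(e)
  expect_equal(ncol(pcs), 1L)
  ev <- attr(pcs, "eigenvalues")
  expect_equal(sum(ev >= 2), 1L)
  # independent tissues: all eigenvalues near 1, floor keeps one PC
  vals0 <- matrix(rnorm(n * 6), n, 6)
  pcs0 <- select_pcs(expression_tensor(vals0))
  expect_equal(ncol(pcs0), 1L)
  # PC sign: nonnegative correlation with mean expression
  expect_gte(cor(pcs[, 1], rowMeans(scale(vals))), 0)
})

test_that("identical tissues reduce ct selection to single-tissue selection", {
  set.seed(34)
  cfg <- sim_config(n_samples = 400L, n_snps = 20L, n_tissues = 4L,
                    n_ct_eqtls = 2L, n_ts_eqtls_per_tissue = 0L,
                    ct_effect_size = 0.8, shared_factor_sd = 0.01,
                    noise_sd = 1, seed = 34L)
  g <- simulate_genotypes(cfg)
  y <- as.numeric(g$dosages[, 3] + g$dosages[, 9] + rnorm(400, sd = 0.5))
  e <- expression_tensor(matrix(y, 400, 4))  # exact copies
  ct <- select_ct_eqtls(e, g)
  single <- stepwise_select(y, g$dosages)
  expect_identical(unname(ct), single$selected)
})

test_that("ts selection conditions on the ct set and excludes it", {
  set.seed(35)
  cfg <- sim_config(n_samples = 500L, n_snps = 30L, n_tissues = 3L,
                    n_ct_eqtls = 2L, n_ts_eqtls_per_tissue = 2L,
                    seed = 35L)
  g <- simulate_genotypes(cfg)
  sim <- simulate_expression(g, cfg)
  e <- sim$expression
  ct <- select_ct_eqtls(e, g)
  ts1 <- select_ts_eqtls(e, g, ct, 1L)
  expect_length(intersect(ts1, ct), 0L)
  # ct_set = everything leaves nothing to select
  all_ct <- seq_len(ncol(g$dosages))
  # (too many fixed terms would exhaust the df guard; use a subset gene)
  small <- stepwise_select(e$values[, 1], g$dosages[, 1:5], s0 = 1:5)
  expect_identical(small$selected, 1:5)
})

test_that("WLS equals OLS when nothing is imputed", {
  set.seed(36)
  X <- matrix(rnorm(80 * 3), 80, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X %*% c(1, -0.5, 0.2) + rnorm(80)
  fit <- wls_fit(y, X, mask = rep(TRUE, 80))
  ols <- lm(y ~ X)
  expect_identical(unname(fit$beta), unname(coef(ols))[-1])
  expect_identical(fit$intercept, unname(coef(ols))[1])
  expect_equal(fit$n_imp, 0L)
})

test_that("imputed weight caps at one when observed samples dominate", {
  set.seed(37)
  n <- 150
  X <- matrix(rnorm(n * 2), n, 2)
  y <- X %*% c(0.5, 1) + rnorm(n)
  mask <- c(rep(TRUE, 100), rep(FALSE, 50))   # n_obs = 100 >= n_imp = 50
  fit <- wls_fit(y, X, mask = mask)
  ols <- lm(y ~ X)
  expect_equal(unname(fit$beta), unname(coef(ols))[-1], tolerance = 1e-12)
  expect_equal(unique(fit$weights), 1)
})

test_that("weight 1/2 equals the observed-row duplication oracle", {
  set.seed(38)
  n <- 150
  X <- matrix(rnorm(n * 2), n, 2)
  y <- as.numeric(X %*% c(0.5, 1) + rnorm(n))
  mask <- c(rep(TRUE, 50), rep(FALSE, 100))   # weight min(1, 50/100) = 1/2
  fit <- wls_fit(y, X, mask = mask)
  expect_equal(fit$weights[!mask][1], 0.5)
  # duplicating every observed row once and halving all weights is the
  # same normal system: fit OLS on observed x2 + imputed
  Xd <- rbind(X[mask, ], X[mask, ], X[!mask, ])
  yd <- c(y[mask], y[mask], y[!mask])
  dup <- lm(yd ~ Xd)
  expect_equal(unname(fit$beta), unname(coef(dup))[-1], tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(dup))[1], tolerance = 1e-10)
})

test_that("singular designs fall back to a logged ridge solution", {
  set.seed(39)
  X <- matrix(rnorm(50), 50, 1)
  X <- cbind(X, X)  # rank 1
  colnames(X) <- c("a", "b")
  y <- X[, 1] + rnorm(50)
  expect_warning(fit <- wls_fit(y, X, mask = rep(TRUE, 50)), "ridge")
  expect_true(fit$ridged)
  expect_true(all(is.finite(fit$beta)))
})

test_that("the trained model predicts expression from genotypes", {
  cfg <- sim_config(n_samples = 400L, n_snps = 15L, n_tissues = 3L,
                    n_ct_eqtls = 2L, n_ts_eqtls_per_tissue = 1L,
                    noise_sd = 0.5, missing_rate = 0.2, seed = 40L)
  g <- simulate_genotypes(cfg)
  sim <- simulate_expression(g, cfg)
  em <- mask_missing(sim$expression, cfg)
  imp <- impute_gene(em, impute_config(seed = 40))
  model <- train_gene_model(imp, g)
  pred <- predict_expression(model, g, 1L)
  expect_length(pred, 400L)
  expect_gt(cor(pred, sim$expression$values[, 1]), 0.5)
})
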