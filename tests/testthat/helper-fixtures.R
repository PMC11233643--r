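# Shared fixture builders. Everything is generated in code; no data files.

# Tiny deterministic genotype matrix with hand-set dosages.
toy_genotypes <- function(dosages, chrom = "1", pos = NULL,
                          ref = NULL, alt = NULL) {
  m <- ncol(dosages)
  if (is.null(pos)) pos <- 1000L * seq_len(m)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  genotype_matrix(dosages,
                  snps = data.frame(id = paste0("rs", seq_len(m)),
                                    chrom = chrom, pos = pos,
                                    ref = ref, alt = alt,
                                    stringsAsFactors = FALSE))
}

nrmse <- function(truth, est) {
  sqrt(mean((est - truth)^2)) / sd(truth)
}

# Equicorrelated Gaussian sample-by-tissue matrix (pairwise correlation
# rho), as an expression tensor.
equicorrelated_tensor <- function(n, k, rho, seed) {
  set.seed(seed)
  f <- rnorm(n)
  vals <- sqrt(rho) * matrix(f, n, k) +
    sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
  expression_tensor(vals, gene = list(id = "equicorr", chrom = "1",
                                      start = 1L, end = 1L))
}

# Brute-force EBIC minimum over all subsets of the candidate columns:
# the independent oracle for the stepwise search. Fits go through
# stats::lm.fit rather than the package's cross-product workspace.
brute_force_ebic <- function(y, X, lambda, s0 = integer(0)) {
  m <- ncol(X)
  free <- setdiff(seq_len(m), s0)
  best <- Inf
  best_set <- s0
  for (code in 0:(2^length(free) - 1L)) {
    subset <- free[bitwAnd(code, 2^(seq_along(free) - 1L)) > 0L]
    s <- sort(c(s0, subset))
    fit <- stats::lm.fit(cbind(1, X[, s, drop = FALSE]), y)
    rss <- sum(fit$residuals^2)
    val <- ebic(rss, length(y), length(s), m, lambda)
    if (val < best) {
      best <- val
      best_set <- s
    }
  }
  list(ebic = best, selected = best_set)
}

f1_score <- function(selected, truth) {
  tp <- length(intersect(selected, truth))
  if (tp == 0L) return(0)
  prec <- tp / length(selected)
  rec <- tp / length(truth)
  2 * prec * rec / (prec + rec)
}
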