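# Synthetic data generator: genotypes with AR(1) linkage disequilibrium via
# a Gaussian copula over haplotypes, multi-tissue expression with a shared
# cross-tissue factor plus cross-tissue and tissue-specific eQTL effects,
# MCAR missingness masks, and traits with matching GWAS summary statistics
# and LD reference blocks. The generator is the fixture source for every
# test; truth objects record the exact eQTL index sets and coefficients.

#' Simulation configuration
#'
#' Defaults describe the standard study condition used throughout the test
#' suite: 500 samples, 30 cis-SNPs with moderate AR(1) LD, 6 tissues, 3
#' cross-tissue eQTLs and 2 tissue-specific eQTLs per tissue of magnitude
#' 0.8, a unit-scale shared factor, unit residual noise and 30% missing
#' entries per tissue.
#'
#' @param n_samples,n_snps,n_tissues Dimensions.
#' @param ld_rho AR(1) correlation of the latent haplotype field, in `[0,1)`.
#' @param maf_range Range the per-SNP minor allele frequencies are drawn
#'   from, within `(0, 0.5]`.
#' @param n_ct_eqtls Number of cross-tissue causal SNPs.
#' @param n_ts_eqtls_per_tissue Tissue-specific causal SNPs per tissue
#'   (disjoint across tissues and from the cross-tissue set).
#' @param ct_effect_size,ts_effect_size Effect magnitudes (signs random).
#' @param noise_sd Residual SD of expression.
#' @param shared_factor_sd Loading of the per-sample shared factor in every
#'   tissue; drives cross-tissue expression correlation.
#' @param missing_rate Per-tissue probability an entry is unobserved.
#' @param seed Integer seed; all simulator randomness flows from it
#'   (Mersenne-Twister, R's default RNG).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 500L, n_snps = 30L, n_tissues = 6L,
                       ld_rho = 0.3, maf_range = c(0.05, 0.5),
                       n_ct_eqtls = 3L, n_ts_eqtls_per_tissue = 2L,
                       ct_effect_size = 0.8, ts_effect_size = 0.8,
                       noise_sd = 1, shared_factor_sd = 1,
                       missing_rate = 0.3, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
              n_tissues = as.integer(n_tissues), ld_rho = ld_rho,
              maf_range = maf_range, n_ct_eqtls = as.integer(n_ct_eqtls),
              n_ts_eqtls_per_tissue = as.integer(n_ts_eqtls_per_tissue),
              ct_effect_size = ct_effect_size, ts_effect_size = ts_effect_size,
              noise_sd = noise_sd, shared_factor_sd = shared_factor_sd,
              missing_rate = missing_rate, seed = as.integer(seed))
  stopifnot(cfg$n_samples >= 2L, cfg$n_snps >= 1L, cfg$n_tissues >= 1L,
            cfg$ld_rho >= 0, cfg$ld_rho < 1,
            cfg$maf_range[1] > 0, cfg$maf_range[2] <= 0.5,
            cfg$noise_sd > 0, cfg$missing_rate >= 0, cfg$missing_rate < 1)
  if (cfg$n_ct_eqtls + cfg$n_tissues * cfg$n_ts_eqtls_per_tissue > cfg$n_snps) {
    stop("requested eQTL counts exceed n_snps")
  }
  class(cfg) <- c("sim_config", "list")
  cfg
}

#' Simulate genotype dosages with AR(1) LD
#'
#' Each individual carries two haplotypes; a haplotype's alleles come from
#' thresholding a latent AR(1) Gaussian process at the per-SNP MAF quantile
#' (Gaussian copula), so adjacent SNPs are correlated with strength set by
#' `ld_rho` and per-SNP allele frequencies follow `maf_range`.
#'
#' @param cfg A [sim_config()].
#' @param n_samples Number of individuals (defaults to `cfg$n_samples`);
#'   override to draw a reference panel of a different size.
#' @param seed Seed (defaults to `cfg$seed`); override together with
#'   `maf` to draw an independent sample from the same population.
#' @param maf Optional vector of per-SNP population MAFs. Passing the
#'   `target_maf` attribute of an earlier draw yields an independent
#'   cohort (e.g. an LD reference panel) from the same generative law.
#' @return A [genotype_matrix()]; SNPs sit on chromosome "1" at 10 kb
#'   spacing with non-ambiguous ref/alt pairs. The population MAFs are
#'   stored in the `target_maf` attribute.
#' @export
simulate_genotypes <- function(cfg, n_samples = cfg$n_samples,
                               seed = cfg$seed, maf = NULL) {
  set.seed(seed)
  n <- as.integer(n_samples); m <- cfg$n_snps
  if (is.null(maf)) maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  stopifnot(length(maf) == m)
  thresh <- qnorm(maf)
  latent <- function() {
    z <- matrix(0, nrow = 2L * n, ncol = m)
    z[, 1] <- rnorm(2L * n)
    if (m > 1L) {
      sc <- sqrt(1 - cfg$ld_rho^2)
      for (j in 2:m) z[, j] <- cfg$ld_rho * z[, j - 1] + sc * rnorm(2L * n)
    }
    z
  }
  hap <- latent() < rep(thresh, each = 2L * n)
  dos <- hap[seq_len(n), , drop = FALSE] + hap[n + seq_len(n), , drop = FALSE]
  pairs <- rbind(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))
  alle <- pairs[sample.int(4L, m, replace = TRUE), , drop = FALSE]
  g <- genotype_matrix(dos * 1,
                       snps = data.frame(id = sprintf("snp_%04d", seq_len(m)),
                                         chrom = "1",
                                         pos = 10000L * seq_len(m),
                                         ref = alle[, 1], alt = alle[, 2],
                                         stringsAsFactors = FALSE),
                       samples = sprintf("sample_%04d", seq_len(n)))
  attr(g, "target_maf") <- maf
  g
}

#' Simulate multi-tissue expression with known eQTL architecture
#'
#' For tissue k: `E[, k] = X_ct b + X_ts(k) c_k + lambda * F + eps` where
#' the cross-tissue effects `b` are shared by all tissues, each
#' tissue-specific SNP acts in exactly one tissue, `F` is a per-sample
#' shared factor and `eps` is Gaussian noise.
#'
#' @param g A [genotype_matrix()] (typically from [simulate_genotypes()]).
#' @param cfg A [sim_config()].
#' @return List with `expression` (a fully observed [expression_tensor()])
#'   and `truth` (ct/ts index sets, effect vectors, factor loadings).
#' @export
simulate_expression <- function(g, cfg) {
  set.seed(seed_offset(cfg$seed, 1))
  n <- nrow(g$dosages); m <- ncol(g$dosages); k <- cfg$n_tissues
  if (cfg$n_ct_eqtls + k * cfg$n_ts_eqtls_per_tissue > m) {
    stop("requested eQTL counts exceed the number of SNPs in g")
  }
  ct_idx <- sort(sample.int(m, cfg$n_ct_eqtls))
  pool <- setdiff(seq_len(m), ct_idx)
  ts_idx <- vector("list", k)
  for (t in seq_len(k)) {
    ts_idx[[t]] <- sort(sample(pool, cfg$n_ts_eqtls_per_tissue))
    pool <- setdiff(pool, ts_idx[[t]])
  }
  b <- cfg$ct_effect_size * sample(c(-1, 1), cfg$n_ct_eqtls, replace = TRUE)
  c_eff <- lapply(seq_len(k), function(t) {
    cfg$ts_effect_size * sample(c(-1, 1), cfg$n_ts_eqtls_per_tissue,
                                replace = TRUE)
  })
  f <- rnorm(n)
  lambda <- rep(cfg$shared_factor_sd, k)
  vals <- matrix(0, n, k)
  ct_part <- if (length(ct_idx) > 0L) {
    g$dosages[, ct_idx, drop = FALSE] %*% b
  } else 0
  for (t in seq_len(k)) {
    ts_part <- if (length(ts_idx[[t]]) > 0L) {
      g$dosages[, ts_idx[[t]], drop = FALSE] %*% c_eff[[t]]
    } else 0
    vals[, t] <- ct_part + ts_part + lambda[t] * f +
      rnorm(n, sd = cfg$noise_sd)
  }
  tissues <- sprintf("tissue_%02d", seq_len(k))
  gene <- list(id = "sim_gene", chrom = "1", start = 1L,
               end = max(g$snps$pos))
  e <- expression_tensor(vals, gene = gene, samples = g$samples,
                         tissues = tissues)
  truth <- list(ct_idx = ct_idx, ct_ids = g$snps$id[ct_idx], ct_effects = b,
                ts_idx = ts_idx,
                ts_ids = lapply(ts_idx, function(i) g$snps$id[i]),
                ts_effects = c_eff, factor = f, lambda = lambda, config = cfg)
  list(expression = e, truth = truth)
}

#' Mask entries missing completely at random
#'
#' @param e A fully observed [expression_tensor()].
#' @param cfg A [sim_config()]; `missing_rate` and `seed` are used.
#' @return The tensor with masked entries set `NA` and `mask` updated.
#' @export
mask_missing <- function(e, cfg) {
  stopifnot(inherits(e, "expression_tensor"))
  if (!all(e$mask)) stop("mask_missing expects a fully observed tensor")
  set.seed(seed_offset(cfg$seed, 2))
  n <- nrow(e$values); k <- ncol(e$values)
  mask <- matrix(rbinom(n * k, 1L, 1 - cfg$missing_rate) == 1L, n, k)
  if (any(colSums(mask) < 2L)) {
    stop("missing_rate ", cfg$missing_rate,
         " leaves a tissue with fewer than 2 observed samples")
  }
  vals <- e$values
  vals[!mask] <- NA_real_
  expression_tensor(vals, mask = mask, gene = e$gene, samples = e$samples,
                    tissues = e$tissues)
}

#' Simulate a trait and matching GWAS summary statistics
#'
#' Builds `Y = gamma * E_tissue + direct genetic effects + noise`
#' (standardized), computes per-SNP marginal association z-scores of `Y` on
#' standardized dosages, and partitions the SNPs into contiguous LD blocks
#' whose correlation matrices and dosage SDs form the LD reference.
#'
#' @param g A [genotype_matrix()].
#' @param e_true A fully observed [expression_tensor()] (the trait acts
#'   through one of its tissues).
#' @param gamma Gene-level effect of the tissue's expression on the trait.
#' @param tissue Tissue index mediating the effect.
#' @param h2_direct Fraction of trait variance from direct (non-mediated)
#'   SNP effects spread over all SNPs; default 0.
#' @param seed Integer seed.
#' @param n_blocks Number of contiguous LD blocks (default 1).
#' @return List with `sumstats` (`id`, `a1` = alt, `a2` = ref, `z`, `n`),
#'   `ld_blocks` (list of `list(ids, R, sd)`) and `trait`.
#' @export
simulate_gwas <- function(g, e_true, gamma, tissue = 1L, h2_direct = 0,
                          seed = 1L, n_blocks = 1L) {
  stopifnot(is.finite(gamma), h2_direct >= 0, h2_direct < 1)
  set.seed(seed)
  dos <- g$dosages
  n <- nrow(dos); m <- ncol(dos)
  xs <- scale(dos)
  e <- as.numeric(scale(e_true$values[, tissue]))
  direct <- 0
  if (h2_direct > 0) {
    alpha <- rnorm(m, sd = sqrt(h2_direct / m))
    direct <- as.numeric(xs %*% alpha)
  }
  y <- gamma * e + direct + rnorm(n)
  y <- as.numeric(scale(y))
  r <- as.numeric(cor(y, dos))
  z <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  block_of <- rep(seq_len(n_blocks), each = ceiling(m / n_blocks))[seq_len(m)]
  blocks <- lapply(unique(block_of), function(bk) {
    idx <- which(block_of == bk)
    list(ids = g$snps$id[idx],
         R = cor(dos[, idx, drop = FALSE]),
         sd = apply(dos[, idx, drop = FALSE], 2, sd))
  })
  list(sumstats = data.frame(id = g$snps$id, a1 = g$snps$alt,
                             a2 = g$snps$ref, z = z, n = n,
                             stringsAsFactors = FALSE),
       ld_blocks = blocks, trait = y)
}
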