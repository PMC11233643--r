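# Gene-trait association. With individual-level data the trait is
# regressed on the predicted expression; with GWAS summary statistics the
# gene z-score is assembled from per-SNP z-scores, the trained weights and
# a block LD reference: Z ~ sum_j beta_j * (sd_j / sd_gene) * z_j, where
# sd_gene is the SD of the weighted SNP sum under the reference LD.

Z_CAP <- 40  # reported |z| cap for numerically exact fits

#' Gene-trait z-score from individual-level data
#'
#' Simple regression of the (standardized) trait on the (standardized)
#' predicted expression; `z = gamma_hat / se(gamma_hat)` with the standard
#' error from the residual variance on N - 2 degrees of freedom.
#'
#' @param y Trait vector.
#' @param e_hat Predicted expression vector, aligned with `y`.
#' @return List with `gamma_hat`, `se`, `z`, `p` and `flag` (`"ok"`,
#'   `"constant_prediction"` or `"exact_fit"`; the exact-fit z is capped
#'   at +/-40).
#' @export
zscore_individual <- function(y, e_hat) {
  n <- length(y)
  stopifnot(length(e_hat) == n, n >= 3L)
  sxx <- sum((e_hat - mean(e_hat))^2)
  if (sxx == 0) {
    return(list(gamma_hat = NA_real_, se = NA_real_, z = NA_real_,
                p = NA_real_, flag = "constant_prediction"))
  }
  gamma_hat <- sum((e_hat - mean(e_hat)) * (y - mean(y))) / sxx
  resid <- (y - mean(y)) - gamma_hat * (e_hat - mean(e_hat))
  rss <- sum(resid^2)
  if (rss <= .Machine$double.eps * sum(y^2)) {
    z <- sign(gamma_hat) * Z_CAP
    return(list(gamma_hat = gamma_hat, se = 0, z = z,
                p = 2 * pnorm(-abs(z)), flag = "exact_fit"))
  }
  se <- sqrt(rss / (n - 2) / sxx)
  z <- gamma_hat / se
  list(gamma_hat = gamma_hat, se = se, z = z, p = 2 * pnorm(-abs(z)),
       flag = "ok")
}

# Orient GWAS rows to the weights' ref/alt. Returns the z sign multiplier
# (+1 aligned, -1 flipped) or NA when alleles cannot be reconciled.
harmonize_alleles <- function(w_ref, w_alt, g_a1, g_a2) {
  same <- g_a1 == w_alt & g_a2 == w_ref
  flip <- g_a1 == w_ref & g_a2 == w_alt
  out <- rep(NA_real_, length(w_ref))
  out[same] <- 1
  out[flip] <- -1
  out
}

#' Gene-trait z-score from GWAS summary statistics
#'
#' Combines trained SNP weights with per-SNP GWAS z-scores through a
#' reference LD block. The predicted-expression SD is computed from the
#' reference: `sd_gene^2 = sum_jl beta_j beta_l sd_j sd_l R_jl`. Alleles
#' are harmonized to the weights' ref/alt; unresolvable or absent SNPs are
#' dropped and the retained fraction reported.
#'
#' @param weights `data.frame` with `id`, `ref`, `alt`, `beta` for the
#'   gene's eQTLs in one tissue.
#' @param gwas Summary statistics as from [read_sumstats()].
#' @param ld One LD block: `list(ids, R, sd)` covering the weight SNPs.
#' @return List with `z`, `p`, `n_snps_used`, `coverage` and `flag`.
#' @export
zscore_sumstats <- function(weights, gwas, ld) {
  m0 <- nrow(weights)
  if (m0 == 0L) {
    return(list(z = NA_real_, p = NA_real_, n_snps_used = 0L, coverage = 0,
                flag = "no_weights"))
  }
  gi <- match(weights$id, gwas$id)
  li <- match(weights$id, ld$ids)
  orient <- rep(NA_real_, m0)
  ok <- !is.na(gi)
  orient[ok] <- harmonize_alleles(toupper(weights$ref[ok]),
                                  toupper(weights$alt[ok]),
                                  gwas$a1[gi[ok]], gwas$a2[gi[ok]])
  keep <- !is.na(gi) & !is.na(li) & !is.na(orient)
  coverage <- mean(keep)
  if (!any(keep)) {
    return(list(z = NA_real_, p = NA_real_, n_snps_used = 0L, coverage = 0,
                flag = "no_overlap"))
  }
  if (coverage < 1) {
    warning(sprintf("only %.0f%% of weight SNPs found in sumstats/LD",
                    100 * coverage))
  }
  beta <- weights$beta[keep]
  zj <- gwas$z[gi[keep]] * orient[keep]
  sdj <- ld$sd[li[keep]]
  R <- ld$R[li[keep], li[keep], drop = FALSE]
  bs <- beta * sdj
  var_gene <- as.numeric(t(bs) %*% R %*% bs)
  if (var_gene <= 0) {
    # regularize only when the quadratic form is not numerically positive
    eps <- 1e-6 * mean(diag(R))
    var_gene <- as.numeric(t(bs) %*% (R + diag(eps, nrow(R))) %*% bs)
  }
  if (var_gene <= 0) {
    return(list(z = NA_real_, p = NA_real_, n_snps_used = sum(keep),
                coverage = coverage, flag = "degenerate_variance"))
  }
  z <- sum(bs * zj) / sqrt(var_gene)
  list(z = z, p = 2 * pnorm(-abs(z)), n_snps_used = sum(keep),
       coverage = coverage, flag = "ok")
}

#' Remove the MHC region
#'
#' Drops records overlapping the major histocompatibility complex
#' (6p21.3), chr6:28,510,120-33,480,577 on GRCh38, inclusive — the
#' conventional TWAS exclusion because of its extreme LD.
#'
#' @param records `data.frame` with `chrom` and either `pos` (point
#'   records) or `start`/`end` (intervals).
#' @param build Genome build; only `"GRCh38"` is supported.
#' @return The filtered `data.frame`.
#' @export
mask_mhc <- function(records, build = "GRCh38") {
  if (!identical(build, "GRCh38")) stop("unknown build: ", build)
  lo <- 28510120; hi <- 33480577
  chrom <- sub("^chr", "", as.character(records$chrom))
  if (all(c("start", "end") %in% names(records))) {
    hit <- chrom == "6" & records$start <= hi & records$end >= lo
  } else {
    hit <- chrom == "6" & records$pos >= lo & records$pos <= hi
  }
  records[!hit, , drop = FALSE]
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up, via
#' [stats::p.adjust()].
#'
#' @param p Vector of p-values.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Effective sample size of a binary GWAS
#'
#' `4 * n_case * n_control / (n_case + n_control)`, the balanced-design
#' equivalent N.
#'
#' @param n_case,n_control Positive counts.
#' @return Effective N.
#' @export
effective_n <- function(n_case, n_control) {
  if (any(n_case <= 0) || any(n_control <= 0)) {
    stop("case and control counts must be positive")
  }
  4 * n_case * n_control / (n_case + n_control)
}

#' Prune correlated genes within a tissue
#'
#' Genes are visited in ascending association P (ties broken by gene id);
#' a gene is kept iff the squared Pearson correlation of its predicted
#' expression with every already-kept gene is at or below the threshold.
#' For a correlated pair this keeps exactly the gene with the lower P.
#'
#' @param assoc `data.frame` with columns `gene` and `p`.
#' @param predicted_expr Named list of predicted-expression vectors (same
#'   samples), one per gene in `assoc`.
#' @param r2_threshold Squared-correlation threshold (default 0.5).
#' @return `assoc` with a logical `kept` column added.
#' @export
prune_correlated_genes <- function(assoc, predicted_expr,
                                   r2_threshold = 0.5) {
  stopifnot(all(assoc$gene %in% names(predicted_expr)))
  ord <- order(assoc$p, assoc$gene)
  kept <- logical(nrow(assoc))
  accepted <- character(0)
  for (i in ord) {
    g <- assoc$gene[i]
    x <- predicted_expr[[g]]
    conflict <- FALSE
    for (a in accepted) {
      y <- predicted_expr[[a]]
      r2 <- if (sd(x) == 0 || sd(y) == 0) 0 else cor(x, y)^2
      if (r2 > r2_threshold) { conflict <- TRUE; break }
    }
    if (!conflict) {
      kept[i] <- TRUE
      accepted <- c(accepted, g)
    }
  }
  assoc$kept <- kept
  assoc
}

#' Prediction performance of an expression model
#'
#' Squared Pearson correlation, its signed variant (sign of r times r^2),
#' and the F test of predictability on (1, n - 2) degrees of freedom:
#' `F = r^2 (n - 2) / (1 - r^2)`. Genes with `r2 > 0.01` meet the common
#' predictability standard; the stringent criterion additionally requires
#' the F-test p-values to survive BH FDR control (applied across genes via
#' [adjust_pvalues()]).
#'
#' @param y_true Observed expression (held-out samples).
#' @param y_pred Predicted expression.
#' @return List with `r2`, `signed_r2`, `f_p`, `n` and `flag`
#'   (`"ok"`, `"constant_prediction"` or `"exact_fit"`).
#' @export
evaluate_prediction <- function(y_true, y_pred) {
  n <- length(y_true)
  stopifnot(length(y_pred) == n, n >= 4L)
  if (sd(y_pred) == 0 || sd(y_true) == 0) {
    return(list(r2 = 0, signed_r2 = 0, f_p = 1, n = n,
                flag = "constant_prediction"))
  }
  r <- cor(y_true, y_pred)
  r2 <- r^2
  if (r2 >= 1) {
    return(list(r2 = 1, signed_r2 = sign(r), f_p = 0, n = n,
                flag = "exact_fit"))
  }
  f_stat <- r2 * (n - 2) / (1 - r2)
  list(r2 = r2, signed_r2 = sign(r) * r2,
       f_p = pf(f_stat, 1, n - 2, lower.tail = FALSE), n = n, flag = "ok")
}
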