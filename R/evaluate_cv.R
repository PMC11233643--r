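# Five-fold cross-validation of expression prediction. Imputation runs on
# the training folds only; the held-out fold stays unimputed and metrics
# are computed on its observed entries. Besides the full model two
# ablations are available: per-tissue EBIC selection on the imputed data
# without the ct/ts partition ("mtwas_tissue"), and per-tissue selection
# on observed samples only without imputation ("single_tissue").

#' Cross-validation plan
#'
#' Samples are assigned to folds round-robin after ordering by how many
#' tissues observe them (random within ties), which stratifies the folds
#' by per-tissue observedness so every fold tends to hold observed test
#' entries for every tissue.
#'
#' @param e An [expression_tensor()] (the raw, unimputed data).
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed.
#' @return A `cv_plan`: list with `fold` (integer per sample), `n_folds`,
#'   `seed`.
#' @export
make_cv_plan <- function(e, n_folds = 5L, seed = 1L) {
  n <- nrow(e$values)
  stopifnot(n_folds >= 2L, n >= n_folds)
  set.seed(seed)
  ord <- order(rowSums(e$mask), runif(n))
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(n_folds), n)
  structure(list(fold = fold, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "cv_plan")
}

# Per-tissue EBIC selection + WLS, shared by the two ablations.
fit_single_tissue <- function(y, mask, g, cfg, use_imputed) {
  if (use_imputed) {
    res <- stepwise_select(y, g$dosages, cfg = cfg)
    sel <- res$selected
    fit <- wls_fit(y, g$dosages[, sel, drop = FALSE], mask = mask)
  } else {
    yo <- y[mask]
    Xo <- g$dosages[mask, , drop = FALSE]
    res <- stepwise_select(yo, Xo, cfg = cfg)
    sel <- res$selected
    fit <- wls_fit(yo, Xo[, sel, drop = FALSE], mask = rep(TRUE, length(yo)))
  }
  fit$snp_idx <- sel
  fit$snp_id <- g$snps$id[sel]
  fit
}

predict_fit <- function(fit, g) {
  if (length(fit$snp_idx) == 0L) return(rep(fit$intercept, nrow(g$dosages)))
  as.numeric(g$dosages[, fit$snp_idx, drop = FALSE] %*% fit$beta) +
    fit$intercept
}

subset_tensor <- function(e, rows) {
  expression_tensor(e$values[rows, , drop = FALSE],
                    mask = e$mask[rows, , drop = FALSE],
                    gene = e$gene, samples = e$samples[rows],
                    tissues = e$tissues)
}

subset_genotypes <- function(g, rows) {
  genotype_matrix(g$dosages[rows, , drop = FALSE],
                  snps = g$snps[, c("id", "chrom", "pos", "ref", "alt")],
                  samples = g$samples[rows])
}

#' Cross-validated prediction metrics for one gene
#'
#' For each fold the training rows are imputed (full model and
#' "mtwas_tissue"), models are trained on them, and held-out observed
#' entries are predicted from genotypes. Per-fold prediction R^2 values
#' are averaged across folds; the predictability F test is evaluated on
#' the held-out predictions pooled over folds. Held-out entries are never
#' imputed.
#'
#' @param e Raw [expression_tensor()] with its missingness.
#' @param g Row-aligned [genotype_matrix()].
#' @param plan A [make_cv_plan()].
#' @param impute_cfg An [impute_config()].
#' @param ebic_cfg An [ebic_config()].
#' @param methods Subset of `c("mtwas", "mtwas_tissue", "single_tissue")`.
#' @return `data.frame`: gene, tissue, method, `r2` (fold average),
#'   `signed_r2`, `f_p`, `n_test` (pooled held-out entries),
#'   `predictable_common` (r2 > 0.01). BH FDR for the stringent criterion
#'   is applied across genes by the caller via [adjust_pvalues()].
#' @export
run_cv <- function(e, g, plan = make_cv_plan(e),
                   impute_cfg = impute_config(),
                   ebic_cfg = ebic_config(),
                   methods = c("mtwas", "mtwas_tissue", "single_tissue")) {
  methods <- match.arg(methods, several.ok = TRUE)
  k <- ncol(e$values)
  usable <- colSums(e$mask) >= plan$n_folds
  if (!all(usable)) {
    message("excluding tissue(s) with fewer observed samples than folds: ",
            paste(e$tissues[!usable], collapse = ", "))
  }
  acc <- list()  # acc[[method]][[tissue]] = list of per-fold results
  for (m in methods) {
    acc[[m]] <- lapply(seq_len(k), function(t) {
      list(r2 = numeric(0), obs = numeric(0), pred = numeric(0))
    })
  }
  for (f in seq_len(plan$n_folds)) {
    tr <- plan$fold != f
    te <- !tr
    e_tr <- subset_tensor(e, tr)
    g_tr <- subset_genotypes(g, tr)
    g_te <- subset_genotypes(g, te)
    mask_te <- e$mask[te, , drop = FALSE]
    vals_te <- e$values[te, , drop = FALSE]

    imp <- NULL
    if (any(c("mtwas", "mtwas_tissue") %in% methods)) {
      imp_cfg_f <- impute_cfg
      imp_cfg_f$seed <- seed_offset(impute_cfg$seed, f)
      imp <- impute_gene(e_tr, imp_cfg_f)
    }
    models <- list()
    if ("mtwas" %in% methods) {
      models$mtwas <- train_gene_model(imp, g_tr, ebic_cfg)
    }
    for (t in seq_len(k)) {
      if (!usable[t]) next
      preds <- list()
      if ("mtwas" %in% methods) {
        tname <- e$tissues[t]
        if (tname %in% models$mtwas$tissues) {
          preds$mtwas <- predict_expression(models$mtwas, g_te, tname)
        }
      }
      if ("mtwas_tissue" %in% methods && e$tissues[t] %in% imp$tissues) {
        ti <- match(e$tissues[t], imp$tissues)
        fit <- fit_single_tissue(imp$values[, ti], imp$mask[, ti], g_tr,
                                 ebic_cfg, use_imputed = TRUE)
        preds$mtwas_tissue <- predict_fit(fit, g_te)
      }
      if ("single_tissue" %in% methods) {
        fit <- fit_single_tissue(e_tr$values[, t], e_tr$mask[, t], g_tr,
                                 ebic_cfg, use_imputed = FALSE)
        preds$single_tissue <- predict_fit(fit, g_te)
      }
      obs_rows <- mask_te[, t]
      if (sum(obs_rows) < 4L) next
      for (m in names(preds)) {
        perf <- evaluate_prediction(vals_te[obs_rows, t],
                                    preds[[m]][obs_rows])
        acc[[m]][[t]]$r2 <- c(acc[[m]][[t]]$r2, perf$r2)
        acc[[m]][[t]]$obs <- c(acc[[m]][[t]]$obs, vals_te[obs_rows, t])
        acc[[m]][[t]]$pred <- c(acc[[m]][[t]]$pred, preds[[m]][obs_rows])
      }
    }
  }
  rows <- list()
  for (m in methods) {
    for (t in seq_len(k)) {
      a <- acc[[m]][[t]]
      if (length(a$r2) == 0L) next
      pooled <- evaluate_prediction(a$obs, a$pred)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = e$gene$id, tissue = e$tissues[t], method = m,
        r2 = mean(a$r2), signed_r2 = sign(cor(a$obs, a$pred)) * mean(a$r2),
        f_p = pooled$f_p, n_test = length(a$obs),
        predictable_common = mean(a$r2) > 0.01,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
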