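# eQTL selection under the extended Bayesian information criterion.
# Cross-tissue eQTLs are selected by regressing successive expression PCs
# on cis-SNP dosages, carrying previously selected SNPs forward as a fixed
# set; tissue-specific eQTLs are then selected per tissue conditional on
# the cross-tissue set. The stepwise search (forward additions, backward
# eliminations, exhaustive enumeration over the surviving non-fixed terms)
# uses precomputed cross-products so each candidate model costs one small
# Cholesky solve. Effects are estimated by weighted least squares with
# imputed samples down-weighted by min(1, N_obs / N_imp).

#' Selection configuration
#'
#' @param lambda EBIC tuning parameter (default 0.5, the standard choice
#'   retaining selection consistency when candidates outnumber samples).
#' @param eigenvalue_cutoff Keep expression PCs whose correlation-matrix
#'   eigenvalue is at least this (default 2.0: a PC carrying two
#'   variables' worth of variance).
#' @param min_pcs Lower bound on the number of PCs used (default 1).
#' @param max_enumeration Cap on the number of non-fixed terms enumerated
#'   exhaustively in the final stage (default 15, i.e. up to 2^15 fits);
#'   above it the backward result is returned and the skip logged.
#' @return An `ebic_config` list.
#' @export
ebic_config <- function(lambda = 0.5, eigenvalue_cutoff = 2.0, min_pcs = 1L,
                        max_enumeration = 15L) {
  stopifnot(lambda >= 0, eigenvalue_cutoff > 0, min_pcs >= 1L)
  structure(list(lambda = lambda, eigenvalue_cutoff = eigenvalue_cutoff,
                 min_pcs = as.integer(min_pcs),
                 max_enumeration = as.integer(max_enumeration)),
            class = c("ebic_config", "list"))
}

#' Extended Bayesian information criterion for a Gaussian linear model
#'
#' `-2 * ll + k * log(n) + 2 * lambda * k * log(m)` with the profile
#' Gaussian log-likelihood `ll = -(n/2) * (log(2 * pi * rss / n) + 1)`.
#' `k` counts the selected SNPs (the intercept is not penalized) and `m`
#' is the size of the candidate pool, whose `log m` term distinguishes
#' EBIC from BIC.
#'
#' @param rss Residual sum of squares (must be > 0).
#' @param n Sample size.
#' @param k_selected Number of selected variables.
#' @param m_candidates Number of candidate variables.
#' @param lambda Tuning parameter.
#' @return EBIC value (smaller is better).
#' @export
ebic <- function(rss, n, k_selected, m_candidates, lambda = 0.5) {
  stopifnot(n >= k_selected + 2, m_candidates >= 1)
  if (rss <= 0) stop("rss must be positive (perfect fit is degenerate)")
  n * (log(2 * pi * rss / n) + 1) + k_selected * log(n) +
    2 * lambda * k_selected * log(m_candidates)
}

# Cross-product workspace shared by every candidate evaluation. Weighted
# rows are folded in as sqrt(w)-scaled rows; the intercept is column 1.
stepwise_workspace <- function(y, X, weights = NULL) {
  n <- length(y)
  Xa <- cbind(1, X)
  if (!is.null(weights)) {
    sw <- sqrt(weights)
    Xa <- Xa * sw
    y <- y * sw
  }
  list(G = crossprod(Xa), Gy = as.numeric(crossprod(Xa, y)),
       yy = sum(y^2), n = n, m = ncol(X))
}

# RSS of the model with intercept plus SNP subset `s` (1-based column
# indices into X); NA when the normal equations are singular.
workspace_rss <- function(ws, s) {
  cols <- c(1L, s + 1L)
  L <- tryCatch(chol(ws$G[cols, cols, drop = FALSE]), error = function(e) NULL)
  if (is.null(L)) return(NA_real_)
  v <- backsolve(L, ws$Gy[cols], transpose = TRUE)
  max(ws$yy - sum(v^2), 0)
}

workspace_ebic <- function(ws, s, lambda) {
  rss <- workspace_rss(ws, s)
  if (is.na(rss)) return(Inf)
  rss <- max(rss, 1e-12 * max(ws$yy, 1))  # guard exact fits
  ebic(rss, ws$n, length(s), ws$m, lambda)
}

#' Stepwise EBIC model selection with a fixed set
#'
#' Forward additions (each step adds the candidate with the lowest EBIC
#' while EBIC decreases), backward eliminations over non-fixed terms, then
#' exhaustive enumeration of all subsets of the surviving non-fixed terms,
#' returning the EBIC-minimal model. Members of `s0` are never removed and
#' are always part of the returned set. Ties break to the lowest column
#' index. All fits are (weighted) least squares with an intercept.
#'
#' @param y Response vector.
#' @param X Candidate matrix (N x M), columns are SNP dosages.
#' @param s0 Integer vector of fixed column indices (may be empty).
#' @param cfg An [ebic_config()].
#' @param weights Optional nonnegative per-row weights.
#' @return A `selection_result`: list with `selected` (sorted indices,
#'   superset of `s0`), `s0`, `ebic`, `trace` (one row per move with the
#'   EBIC after it) and `enumeration_skipped`.
#' @export
stepwise_select <- function(y, X, s0 = integer(0), cfg = ebic_config(),
                            weights = NULL) {
  X <- as.matrix(X)
  s0 <- sort(unique(as.integer(s0)))
  stopifnot(length(y) == nrow(X),
            all(s0 >= 1L), all(s0 <= ncol(X)),
            length(y) > length(s0) + 2L)
  ws <- stepwise_workspace(y, X, weights)
  lambda <- cfg$lambda
  m <- ncol(X)

  trace <- list()
  note <- function(phase, action, idx, val) {
    trace[[length(trace) + 1L]] <<- data.frame(
      phase = phase, action = action, index = idx, ebic = val,
      stringsAsFactors = FALSE)
  }

  sel <- s0
  current <- workspace_ebic(ws, sel, lambda)
  note("init", "start", NA_integer_, current)

  # forward
  repeat {
    cand <- setdiff(seq_len(m), sel)
    if (length(cand) == 0L) break
    vals <- vapply(cand, function(j) workspace_ebic(ws, sort(c(sel, j)), lambda),
                   numeric(1))
    best <- which.min(vals)  # first minimum = lowest index on ties
    if (is.finite(vals[best]) && vals[best] < current) {
      sel <- sort(c(sel, cand[best]))
      current <- vals[best]
      note("forward", "add", cand[best], current)
    } else break
  }

  # backward over non-fixed terms
  repeat {
    cand <- setdiff(sel, s0)
    if (length(cand) == 0L) break
    vals <- vapply(cand, function(j) workspace_ebic(ws, setdiff(sel, j), lambda),
                   numeric(1))
    best <- which.min(vals)
    if (is.finite(vals[best]) && vals[best] < current) {
      sel <- setdiff(sel, cand[best])
      current <- vals[best]
      note("backward", "remove", cand[best], current)
    } else break
  }

  # exhaustive enumeration over the surviving non-fixed terms
  free <- setdiff(sel, s0)
  enumeration_skipped <- FALSE
  if (length(free) > cfg$max_enumeration) {
    enumeration_skipped <- TRUE
    message("enumeration skipped: ", length(free), " non-fixed terms exceed ",
            "max_enumeration = ", cfg$max_enumeration)
  } else if (length(free) > 0L) {
    best_set <- sel
    best_val <- current
    for (code in 0:(2^length(free) - 1L)) {
      subset <- free[bitwAnd(code, 2^(seq_along(free) - 1L)) > 0L]
      s <- sort(c(s0, subset))
      val <- workspace_ebic(ws, s, lambda)
      if (val < best_val) {
        best_val <- val
        best_set <- s
      }
    }
    if (best_val < current) note("enumeration", "jump", NA_integer_, best_val)
    sel <- best_set
    current <- best_val
  }

  structure(list(selected = sort(sel), s0 = s0, ebic = current,
                 trace = do.call(rbind, trace),
                 enumeration_skipped = enumeration_skipped),
            class = "selection_result")
}

#' Select expression principal components
#'
#' Standardizes the imputed tissue columns, eigendecomposes their
#' correlation matrix and keeps the PCs whose eigenvalues reach
#' `eigenvalue_cutoff` (at least `min_pcs`). PC signs are fixed so each
#' score vector correlates nonnegatively with mean expression across
#' tissues, making selection traces reproducible.
#'
#' @param e_imputed A completed [expression_tensor()].
#' @param cfg An [ebic_config()].
#' @return N x P matrix of PC scores (descending eigenvalue order) with
#'   attribute `eigenvalues` (all K of them).
#' @export
select_pcs <- function(e_imputed, cfg = ebic_config()) {
  vals <- e_imputed$values
  stopifnot(ncol(vals) >= 2L)
  sds <- apply(vals, 2, sd)
  if (any(sds == 0)) stop("constant tissue column; cannot standardize")
  zs <- scale(vals)
  eg <- eigen(cor(vals), symmetric = TRUE)
  n_pc <- max(sum(eg$values >= cfg$eigenvalue_cutoff), cfg$min_pcs)
  scores <- zs %*% eg$vectors[, seq_len(n_pc), drop = FALSE]
  rowmean <- rowMeans(zs)
  for (p in seq_len(n_pc)) {
    s <- sum(scores[, p] * rowmean)
    if (s < 0 || (s == 0 && sum(eg$vectors[, p]) < 0)) {
      scores[, p] <- -scores[, p]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  attr(scores, "eigenvalues") <- eg$values
  scores
}

#' Select cross-tissue eQTLs
#'
#' Regresses each retained expression PC on the cis-SNP dosages in order,
#' carrying the SNPs selected for earlier PCs as the fixed set of the next
#' PC's stepwise search (which both keeps them in the model and penalizes
#' additional selections). Fits are unweighted: all samples, observed and
#' imputed, enter at weight 1.
#'
#' @param e_imputed A completed [expression_tensor()].
#' @param g A [genotype_matrix()] row-aligned with `e_imputed`.
#' @param cfg An [ebic_config()].
#' @return Sorted integer vector of selected SNP column indices, named by
#'   SNP id.
#' @export
select_ct_eqtls <- function(e_imputed, g, cfg = ebic_config()) {
  pcs <- select_pcs(e_imputed, cfg)
  sel <- integer(0)
  for (p in seq_len(ncol(pcs))) {
    res <- stepwise_select(pcs[, p], g$dosages, s0 = sel, cfg = cfg)
    sel <- res$selected
  }
  names(sel) <- g$snps$id[sel]
  sel
}

#' Select tissue-specific eQTLs for one tissue
#'
#' Stepwise EBIC selection on the tissue's (imputed) expression with the
#' cross-tissue set fixed; returns only the additions beyond that set.
#' Observed and imputed samples all enter selection.
#'
#' @param e_imputed A completed [expression_tensor()].
#' @param g A [genotype_matrix()] row-aligned with `e_imputed`.
#' @param ct_set Integer indices of the cross-tissue eQTLs.
#' @param tissue Tissue column index.
#' @param cfg An [ebic_config()].
#' @return Sorted integer vector of tissue-specific SNP indices (disjoint
#'   from `ct_set`), named by SNP id.
#' @export
select_ts_eqtls <- function(e_imputed, g, ct_set, tissue,
                            cfg = ebic_config()) {
  res <- stepwise_select(e_imputed$values[, tissue], g$dosages,
                         s0 = as.integer(ct_set), cfg = cfg)
  ts <- setdiff(res$selected, as.integer(ct_set))
  names(ts) <- g$snps$id[ts]
  ts
}

#' Weighted least squares for eQTL effect sizes
#'
#' Observed samples get weight 1; imputed samples get
#' `min(1, n_obs / n_imp)`, which caps the influence of imputed rows when
#' they outnumber observed ones. With no imputed rows this is exactly OLS.
#'
#' @param y Expression vector (length N).
#' @param X Dosage matrix over the selected SNPs (N x p, may have 0
#'   columns).
#' @param mask Logical length-N vector, `TRUE` where the entry was
#'   observed.
#' @return List with `beta` (named by `colnames(X)`), `intercept`,
#'   `sigma` (weighted residual SD), `n_obs`, `n_imp`, `weights` and
#'   `ridged` (whether the ridge fallback fired).
#' @export
wls_fit <- function(y, X, mask) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n || ncol(X) == 0L, length(mask) == n)
  n_obs <- sum(mask)
  n_imp <- n - n_obs
  if (n_obs < ncol(X) + 2L) {
    stop("need at least ", ncol(X) + 2L, " observed samples, have ", n_obs)
  }
  w_imp <- if (n_imp > 0L) min(1, n_obs / n_imp) else 1
  w <- ifelse(mask, 1, w_imp)
  Xa <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.wfit(Xa, y, w)
  ridged <- FALSE
  if (fit$rank < ncol(Xa)) {
    ridged <- TRUE
    warning("singular weighted normal equations; applying ridge 1e-8")
    XtW <- t(Xa * w)
    A <- XtW %*% Xa + diag(1e-8, ncol(Xa))
    coefs <- as.numeric(solve(A, XtW %*% y))
    names(coefs) <- colnames(Xa)
    resid <- y - as.numeric(Xa %*% coefs)
  } else {
    coefs <- coef(fit)
    resid <- fit$residuals
  }
  df <- max(n - ncol(Xa), 1L)
  sigma <- sqrt(sum(w * resid^2) / df)
  list(beta = coefs[-1], intercept = unname(coefs[1]), sigma = sigma,
       n_obs = n_obs, n_imp = n_imp, weights = w, ridged = ridged)
}

#' Train the full per-gene eQTL model
#'
#' Runs cross-tissue selection, per-tissue tissue-specific selection, and
#' weighted least squares effect estimation; the result holds everything
#' needed to predict the gene's expression from genotypes in any tissue.
#'
#' @param e_imputed A completed [expression_tensor()] (from
#'   [impute_gene()]).
#' @param g A [genotype_matrix()] row-aligned with `e_imputed`.
#' @param cfg An [ebic_config()].
#' @return An `eqtl_model`: gene info, `ct_set`, per-tissue `ts_sets`,
#'   and per-tissue fits (`beta` over ct union ts SNPs, `intercept`,
#'   `sigma`, `n_obs`, `n_imp`).
#' @export
train_gene_model <- function(e_imputed, g, cfg = ebic_config()) {
  k <- ncol(e_imputed$values)
  ct <- select_ct_eqtls(e_imputed, g, cfg)
  ts_sets <- vector("list", k)
  fits <- vector("list", k)
  for (t in seq_len(k)) {
    ts_sets[[t]] <- select_ts_eqtls(e_imputed, g, ct, t, cfg)
    sel <- sort(union(ct, ts_sets[[t]]))
    fits[[t]] <- wls_fit(e_imputed$values[, t],
                         g$dosages[, sel, drop = FALSE],
                         mask = e_imputed$mask[, t])
    fits[[t]]$snp_idx <- sel
    fits[[t]]$snp_id <- g$snps$id[sel]
    fits[[t]]$class <- ifelse(sel %in% ct, "ct", "ts")
  }
  names(ts_sets) <- names(fits) <- e_imputed$tissues
  structure(list(gene = e_imputed$gene, tissues = e_imputed$tissues,
                 ct_set = ct, ts_sets = ts_sets, fits = fits,
                 snps = g$snps[, c("id", "chrom", "pos", "ref", "alt")]),
            class = "eqtl_model")
}

#' Predict genetically regulated expression
#'
#' @param model An `eqtl_model` from [train_gene_model()].
#' @param g A [genotype_matrix()] with the model's SNPs (matched by id).
#' @param tissue Tissue name or index.
#' @param intercept Include the intercept (default `TRUE`; gene-trait
#'   z-scores are invariant to it).
#' @return Numeric vector of predicted expression, one per sample of `g`.
#' @export
predict_expression <- function(model, g, tissue, intercept = TRUE) {
  fit <- model$fits[[tissue]]
  if (length(fit$snp_id) == 0L) {
    return(rep(if (intercept) fit$intercept else 0, nrow(g$dosages)))
  }
  idx <- match(fit$snp_id, g$snps$id)
  if (anyNA(idx)) {
    stop("genotype data lacks model SNP(s): ",
         paste(fit$snp_id[is.na(idx)], collapse = ", "))
  }
  pred <- as.numeric(g$dosages[, idx, drop = FALSE] %*% fit$beta)
  if (intercept) pred <- pred + fit$intercept
  pred
}

#' @export
print.eqtl_model <- function(x, ...) {
  cat(sprintf("<eqtl_model> gene %s: %d ct-eQTLs; ts-eQTLs per tissue: %s\n",
              x$gene$id, length(x$ct_set),
              paste(vapply(x$ts_sets, length, integer(1)), collapse = "/")))
  invisible(x)
}
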