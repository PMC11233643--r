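# Cross-tissue expression imputation. Each gene's sample-by-tissue matrix
# is completed by iterative per-column random-forest regression on the
# other columns (the missForest scheme): columns are visited in ascending
# missingness order after a mean-value initialization, and full sweeps
# repeat until the relative change over imputed entries first increases,
# at which point the previous sweep's values are kept. Genotypes are never
# consulted at this stage.

#' Imputation configuration
#'
#' @param n_trees Trees per forest (default 100).
#' @param max_iter Maximum number of full sweeps (default 10).
#' @param min_obs_per_tissue Tissues with fewer observed samples than this
#'   are dropped from the gene's matrix before imputation (default 10).
#' @param seed Integer seed; forests are deterministic given it.
#' @return An `impute_config` list.
#' @export
impute_config <- function(n_trees = 100L, max_iter = 10L,
                          min_obs_per_tissue = 10L, seed = 1L) {
  stopifnot(n_trees >= 1L, max_iter >= 1L)
  structure(list(n_trees = as.integer(n_trees),
                 max_iter = as.integer(max_iter),
                 min_obs_per_tissue = as.integer(min_obs_per_tissue),
                 seed = as.integer(seed)),
            class = c("impute_config", "list"))
}

#' Relative change of the imputed entries between sweeps
#'
#' `sum((curr - prev)^2) / sum(curr^2)` over the originally missing
#' positions only.
#'
#' @param prev,curr Matrix snapshots after consecutive sweeps.
#' @param missing_mask Logical matrix, `TRUE` at originally missing
#'   positions.
#' @return Nonnegative scalar.
#' @export
imputation_delta <- function(prev, curr, missing_mask) {
  stopifnot(identical(dim(prev), dim(curr)),
            identical(dim(prev), dim(missing_mask)))
  num <- sum((curr[missing_mask] - prev[missing_mask])^2)
  den <- sum(curr[missing_mask]^2)
  if (den == 0) return(0)
  num / den
}

#' Sweep stopping rule
#'
#' Stop (and roll back to the previous sweep) the first time the relative
#' change over imputed entries increases compared with the previous sweep,
#' or when `max_iter` sweeps have run.
#'
#' @param deltas Numeric vector of per-sweep [imputation_delta()] values so
#'   far (most recent last).
#' @param max_iter Sweep cap.
#' @return `TRUE` to stop.
#' @export
stopping_rule <- function(deltas, max_iter) {
  k <- length(deltas)
  if (k >= max_iter) return(TRUE)
  k >= 2L && deltas[k] > deltas[k - 1L]
}

#' Impute a gene's sample-by-tissue expression matrix
#'
#' @param e An [expression_tensor()]; `NA` at unobserved entries.
#' @param cfg An [impute_config()].
#' @return The completed tensor (observed entries bit-identical, `mask`
#'   unchanged so downstream weighting knows which rows were imputed).
#'   Tissues below `min_obs_per_tissue` observed samples are dropped with a
#'   message. Attributes `n_sweeps` and `rolled_back` record the iteration
#'   outcome.
#' @export
impute_gene <- function(e, cfg = impute_config()) {
  stopifnot(inherits(e, "expression_tensor"))
  n_obs <- colSums(e$mask)
  keep <- n_obs >= cfg$min_obs_per_tissue & n_obs > 0L
  if (!all(keep)) {
    message("dropping tissue(s) with < ", cfg$min_obs_per_tissue,
            " observed samples for gene ", e$gene$id, ": ",
            paste(e$tissues[!keep], collapse = ", "))
    e <- expression_tensor(e$values[, keep, drop = FALSE],
                           mask = e$mask[, keep, drop = FALSE],
                           gene = e$gene, samples = e$samples,
                           tissues = e$tissues[keep])
  }
  k <- ncol(e$values)
  if (all(e$mask)) {
    attr(e, "n_sweeps") <- 0L
    attr(e, "rolled_back") <- FALSE
    return(e)
  }
  if (k < 2L) stop("cannot impute with a single tissue (no donor columns)")

  miss <- !e$mask
  vals <- e$values
  # mean initialization, then sweep columns in ascending missingness order
  col_means <- colMeans(vals, na.rm = TRUE)
  for (j in seq_len(k)) vals[miss[, j], j] <- col_means[j]
  order_cols <- order(colSums(miss), seq_len(k))
  target_cols <- order_cols[colSums(miss)[order_cols] > 0L]

  deltas <- numeric(0)
  prev <- vals
  sweep <- 0L
  rolled_back <- FALSE
  repeat {
    sweep <- sweep + 1L
    curr <- vals
    for (j in target_cols) {
      obs_j <- e$mask[, j]
      train_x <- as.data.frame(curr[obs_j, -j, drop = FALSE])
      pred_x <- as.data.frame(curr[!obs_j, -j, drop = FALSE])
      names(train_x) <- names(pred_x) <- paste0("t", seq_len(k)[-j])
      fit <- ranger::ranger(x = train_x, y = curr[obs_j, j],
                            num.trees = cfg$n_trees,
                            mtry = ncol(train_x),
                            num.threads = 1L,
                            seed = seed_offset(cfg$seed, 1000 * sweep + j))
      curr[!obs_j, j] <- predict(fit, data = pred_x,
                                 num.threads = 1L)$predictions
    }
    deltas <- c(deltas, imputation_delta(vals, curr, miss))
    if (stopping_rule(deltas, cfg$max_iter)) {
      last <- length(deltas)
      if (last >= 2L && deltas[last] > deltas[last - 1L]) {
        curr <- vals  # roll back to the pre-increase iterate
        rolled_back <- TRUE
      }
      vals <- curr
      break
    }
    vals <- curr
  }
  vals[e$mask] <- e$values[e$mask]  # defensive; sweeps never touch observed
  out <- expression_tensor(vals, mask = e$mask, gene = e$gene,
                           samples = e$samples, tissues = e$tissues)
  attr(out, "n_sweeps") <- sweep
  attr(out, "rolled_back") <- rolled_back
  out
}

#' Mean-fill baseline imputation
#'
#' Replaces each missing entry by its tissue's observed mean. Used as the
#' comparison oracle when scoring the forest imputer.
#'
#' @param e An [expression_tensor()] with `NA` at unobserved entries.
#' @return The mean-completed tensor.
#' @export
impute_mean <- function(e) {
  vals <- e$values
  for (j in seq_len(ncol(vals))) {
    mj <- !e$mask[, j]
    if (any(mj)) vals[mj, j] <- mean(vals[e$mask[, j], j])
  }
  expression_tensor(vals, mask = e$mask, gene = e$gene, samples = e$samples,
                    tissues = e$tissues)
}
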