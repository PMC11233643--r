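# Core data containers. Plain lists with light S3 classes, in the style of
# most TWAS tooling: a dosage matrix plus a SNP metadata table, and a
# per-gene sample-by-tissue expression matrix with an observed-entry mask.

#' Construct a genotype matrix
#'
#' Bundles an `N x M` dosage matrix (alt-allele counts on the 0--2 scale,
#' `NA` allowed before QC) with its SNP metadata table.
#'
#' @param dosages Numeric matrix, samples in rows, SNPs in columns.
#' @param snps `data.frame` with columns `id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`; one row per dosage column, same order.
#' @param samples Character vector of sample identifiers (defaults to
#'   rownames of `dosages`).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `snps` (with a `maf` column computed from the dosages) and
#'   `samples`.
#' @export
genotype_matrix <- function(dosages, snps, samples = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(samples)) samples <- paste0("sample_", seq_len(nrow(dosages)))
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(need, names(snps))
  if (length(missing_cols) > 0L) {
    stop("snps table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(snps) != ncol(dosages)) {
    stop("snps table has ", nrow(snps), " rows but dosages has ",
         ncol(dosages), " columns")
  }
  if (anyDuplicated(snps$id)) {
    stop("duplicated SNP id(s): ",
         paste(unique(snps$id[duplicated(snps$id)]), collapse = ", "))
  }
  if (any(snps$pos < 1L)) stop("SNP positions must be >= 1 (1-based)")
  rownames(dosages) <- samples
  colnames(dosages) <- snps$id
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  snps$maf <- snp_maf(dosages)
  snps$ambiguous <- strand_ambiguous(snps$ref, snps$alt)
  rownames(snps) <- NULL
  structure(list(dosages = dosages, snps = snps, samples = samples),
            class = "genotype_matrix")
}

snp_maf <- function(dosages) {
  p <- colMeans(dosages, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

# A/T and C/G pairs cannot be oriented across strands.
strand_ambiguous <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- toupper(ref); alt <- toupper(alt)
  nchar(ref) == 1L & nchar(alt) == 1L & !is.na(comp[ref]) & comp[ref] == alt
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  if (ncol(x$dosages) > 0L) {
    cat(sprintf("  chrom %s, pos %s-%s, MAF %.3f-%.3f\n",
                paste(unique(x$snps$chrom), collapse = ","),
                format(min(x$snps$pos)), format(max(x$snps$pos)),
                min(x$snps$maf), max(x$snps$maf)))
  }
  invisible(x)
}

#' Construct a per-gene expression tensor
#'
#' Holds one gene's `N x K` sample-by-tissue expression matrix together with
#' the observed-entry mask that separates measured values from entries that
#' are absent (and later imputed).
#'
#' @param values Numeric `N x K` matrix (samples x tissues). Unobserved
#'   entries may be `NA`.
#' @param mask Logical `N x K` matrix, `TRUE` where the entry was observed.
#'   Defaults to `!is.na(values)`.
#' @param gene List with `id`, `chrom`, `start`, `end` describing the gene.
#' @param samples,tissues Identifier vectors; default to dimnames.
#' @return An object of class `expression_tensor`.
#' @export
expression_tensor <- function(values, mask = NULL,
                              gene = list(id = "gene", chrom = "1",
                                          start = 1L, end = 1L),
                              samples = rownames(values),
                              tissues = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(samples)) samples <- paste0("sample_", seq_len(nrow(values)))
  if (is.null(tissues)) tissues <- paste0("tissue_", seq_len(ncol(values)))
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  stopifnot(identical(dim(mask), dim(values)))
  if (any(mask & !is.finite(values))) {
    stop("observed entries (mask TRUE) must be finite")
  }
  dimnames(values) <- dimnames(mask) <- list(samples, tissues)
  structure(list(values = values, mask = mask, gene = gene,
                 samples = samples, tissues = tissues),
            class = "expression_tensor")
}

#' @export
print.expression_tensor <- function(x, ...) {
  cat(sprintf("<expression_tensor> gene %s: %d samples x %d tissues, %.1f%% observed\n",
              x$gene$id, nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  invisible(x)
}

#' Per-tissue observed / imputed sample counts
#'
#' @param e An [expression_tensor()].
#' @return `data.frame` with `tissue`, `n_obs`, `n_imp` (`n_obs + n_imp`
#'   always equals the number of samples).
#' @export
tissue_counts <- function(e) {
  n_obs <- colSums(e$mask)
  data.frame(tissue = e$tissues, n_obs = as.integer(n_obs),
             n_imp = as.integer(nrow(e$mask) - n_obs),
             row.names = NULL, stringsAsFactors = FALSE)
}
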