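# Readers and writers for the external formats: VCF (via vcfR), PLINK
# bed/bim/fam (minimal SNP-major codec, written here because no pre-built R
# reader is part of the package's dependency set), plain dosage TSV,
# expression TSV/GCT, covariate TSV, GWAS summary TSV and LD block matrices.
# Coordinates are 1-based inclusive (VCF convention) throughout.

#' Read genotype dosages
#'
#' @param path File path. For `format = "plink"` the path may be the shared
#'   prefix or any one of the `.bed/.bim/.fam` files.
#' @param format One of `"vcf"` (plain or bgzipped), `"plink"`
#'   (bed/bim/fam triplet) or `"tsv"` (rows = samples, columns = SNPs with a
#'   `chrom:pos:ref:alt`-style header; first column sample id).
#' @return A [genotype_matrix()] with dosages on the 0--2 alt-allele scale,
#'   samples and SNPs in file order. Missing genotypes are `NA` (clean them
#'   with [qc_genotypes()]).
#' @export
read_genotypes <- function(path, format = c("vcf", "plink", "tsv")) {
  format <- match.arg(format)
  switch(format,
         vcf = read_genotypes_vcf(path),
         plink = read_genotypes_plink(path),
         tsv = read_genotypes_tsv(path))
}

read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  # alt-allele count; tolerate phased separators and missing calls
  dos <- apply(gt, 2, function(col) {
    a <- strsplit(col, "[/|]")
    vapply(a, function(x) {
      if (length(x) == 0L || any(x == ".") || any(is.na(x))) return(NA_real_)
      sum(x != "0")
    }, numeric(1))
  })
  dos <- matrix(as.numeric(dos), nrow = nrow(gt),
                dimnames = list(rownames(gt), samples))
  ids <- fix$ID
  if (any(is.na(ids) | ids == ".")) {
    ids <- ifelse(is.na(ids) | ids == ".",
                  paste0(fix$CHROM, ":", fix$POS), ids)
  }
  genotype_matrix(t(dos),
                  snps = data.frame(id = ids, chrom = fix$CHROM,
                                    pos = as.integer(fix$POS),
                                    ref = fix$REF, alt = fix$ALT,
                                    stringsAsFactors = FALSE),
                  samples = samples)
}

plink_prefix <- function(path) sub("\\.(bed|bim|fam)$", "", path)

read_genotypes_plink <- function(path) {
  prefix <- plink_prefix(path)
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) if (!file.exists(f)) stop("no such file: ", f)
  bim_dt <- data.table::fread(bim, header = FALSE,
                              col.names = c("chrom", "id", "cm", "pos",
                                            "a1", "a2"))
  if (anyDuplicated(bim_dt$id)) {
    stop("duplicated SNP id(s) in ", bim, ": ",
         paste(unique(bim_dt$id[duplicated(bim_dt$id)]), collapse = ", "))
  }
  fam_dt <- data.table::fread(fam, header = FALSE)
  samples <- as.character(fam_dt[[2]])
  n <- length(samples); m <- nrow(bim_dt)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("malformed .bed file (bad magic number): ", bed)
  }
  if (raw[3] != as.raw(0x01)) stop("only SNP-major .bed files are supported")
  bytes_per_snp <- ceiling(n / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_snp * m) {
    stop("bed file size inconsistent with ", n, " samples x ", m, " SNPs")
  }
  # two bits per genotype: 00 hom A1 (dosage 2), 10 het (1), 11 hom A2 (0),
  # 01 missing; A1 is taken as the counted (alt) allele
  bits <- matrix(as.integer(rawToBits(body)), nrow = 8L)
  codes <- bits[seq(1L, 8L, 2L), , drop = FALSE] +
    2L * bits[seq(2L, 8L, 2L), , drop = FALSE]
  codes <- matrix(as.vector(codes), nrow = 4L * bytes_per_snp)[seq_len(n), ,
                                                               drop = FALSE]
  lookup <- c(`0` = 2, `1` = NA_real_, `2` = 1, `3` = 0)
  dos <- matrix(lookup[codes + 1L], nrow = n, ncol = m)
  genotype_matrix(dos,
                  snps = data.frame(id = bim_dt$id,
                                    chrom = as.character(bim_dt$chrom),
                                    pos = bim_dt$pos, ref = bim_dt$a2,
                                    alt = bim_dt$a1,
                                    stringsAsFactors = FALSE),
                  samples = samples)
}

read_genotypes_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = TRUE)
  samples <- as.character(dt[[1]])
  dos <- as.matrix(dt[, -1, drop = FALSE])
  cols <- colnames(dos)
  parts <- strsplit(cols, ":", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 4L)
  if (length(bad) > 0L) {
    stop("malformed TSV genotype header (need chrom:pos:ref:alt) in column ",
         bad[1] + 1L, ": '", cols[bad[1]], "'")
  }
  meta <- do.call(rbind, parts)
  genotype_matrix(dos,
                  snps = data.frame(id = cols, chrom = meta[, 1],
                                    pos = as.integer(meta[, 2]),
                                    ref = meta[, 3], alt = meta[, 4],
                                    stringsAsFactors = FALSE),
                  samples = samples)
}

#' Write genotype dosages
#'
#' Inverse of [read_genotypes()]; round-trips dosages and SNP metadata.
#' VCF output encodes dosages 0/1/2 as unphased GTs (`NA` as `./.`).
#'
#' @param g A [genotype_matrix()].
#' @param path Output path (PLINK: prefix or any triplet member).
#' @param format `"vcf"`, `"plink"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path, format = c("vcf", "plink", "tsv")) {
  format <- match.arg(format)
  switch(format,
         vcf = write_genotypes_vcf(g, path),
         plink = write_genotypes_plink(g, path),
         tsv = write_genotypes_tsv(g, path))
  invisible(path)
}

write_genotypes_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", g$samples), collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(g$dosages))) {
    d <- g$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[round(d) + 1L])
    writeLines(paste(c(g$snps$chrom[j], g$snps$pos[j], g$snps$id[j],
                       g$snps$ref[j], g$snps$alt[j], ".", "PASS", ".",
                       "GT", gt), collapse = "\t"), con)
  }
}

write_genotypes_plink <- function(g, path) {
  prefix <- plink_prefix(path)
  n <- nrow(g$dosages); m <- ncol(g$dosages)
  data.table::fwrite(data.frame(g$snps$chrom, g$snps$id, 0L, g$snps$pos,
                                g$snps$alt, g$snps$ref),
                     paste0(prefix, ".bim"), sep = "\t", col.names = FALSE)
  data.table::fwrite(data.frame(g$samples, g$samples, 0L, 0L, 0L, -9L),
                     paste0(prefix, ".fam"), sep = "\t", col.names = FALSE)
  code_for <- function(d) {
    if (is.na(d)) 1L else c(3L, 2L, 0L)[round(d) + 1L]
  }
  bytes_per_snp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(m)) {
    codes <- vapply(g$dosages[, j], code_for, integer(1))
    codes <- c(codes, rep(0L, 4L * bytes_per_snp - n))
    quads <- matrix(codes, nrow = 4L)
    bytes <- quads[1, ] + 4L * quads[2, ] + 16L * quads[3, ] + 64L * quads[4, ]
    writeBin(as.raw(bytes), con)
  }
}

write_genotypes_tsv <- function(g, path) {
  cols <- paste(g$snps$chrom, g$snps$pos, g$snps$ref, g$snps$alt, sep = ":")
  dt <- data.table::data.table(sample = g$samples)
  for (j in seq_along(cols)) data.table::set(dt, j = cols[j],
                                             value = g$dosages[, j])
  data.table::fwrite(dt, path, sep = "\t")
}

#' Genotype quality control
#'
#' Drops SNPs below a minor-allele-frequency threshold and (by default)
#' strand-ambiguous A/T and C/G variants, then mean-imputes any missing
#' dosages per SNP. Idempotent.
#'
#' @param g A [genotype_matrix()].
#' @param maf_threshold Minimum MAF to retain (default 0.05).
#' @param drop_ambiguous Drop strand-ambiguous SNPs (default `TRUE`).
#' @param whitelist Optional character vector (or path to a one-id-per-line
#'   file) restricting SNPs to a known set, e.g. a HapMap3 id list.
#' @return A filtered [genotype_matrix()] with no missing dosages.
#' @export
qc_genotypes <- function(g, maf_threshold = 0.05, drop_ambiguous = TRUE,
                         whitelist = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  keep <- g$snps$maf >= maf_threshold
  if (drop_ambiguous) keep <- keep & !g$snps$ambiguous
  if (!is.null(whitelist)) {
    if (length(whitelist) == 1L && file.exists(whitelist)) {
      whitelist <- readLines(whitelist)
    }
    keep <- keep & g$snps$id %in% whitelist
  }
  if (!any(keep)) {
    warning("all SNPs removed by QC; returning empty genotype_matrix")
  }
  dos <- g$dosages[, keep, drop = FALSE]
  if (anyNA(dos)) {
    for (j in seq_len(ncol(dos))) {
      miss <- is.na(dos[, j])
      if (any(miss)) dos[miss, j] <- mean(dos[!miss, j])
    }
  }
  genotype_matrix(dos, snps = g$snps[keep, c("id", "chrom", "pos", "ref", "alt"),
                                     drop = FALSE],
                  samples = g$samples)
}

#' Extract the cis window of a gene
#'
#' Keeps SNPs on the gene's chromosome with
#' `start - window_bp <= pos <= end + window_bp` (inclusive bounds).
#'
#' @param gene List with `chrom`, `start`, `end` (1-based inclusive).
#' @param g A [genotype_matrix()].
#' @param window_bp Flank size in base pairs; default 1 Mb, the common
#'   cis-window convention in TWAS model training.
#' @return A [genotype_matrix()] restricted to the cis window.
#' @export
cis_window <- function(gene, g, window_bp = 1e6) {
  stopifnot(inherits(g, "genotype_matrix"))
  on_chrom <- g$snps$chrom == as.character(gene$chrom)
  if (!any(on_chrom)) {
    warning("gene chromosome ", gene$chrom, " absent from genotype data")
  }
  keep <- on_chrom & g$snps$pos >= gene$start - window_bp &
    g$snps$pos <= gene$end + window_bp
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  snps = g$snps[keep, c("id", "chrom", "pos", "ref", "alt"),
                                drop = FALSE],
                  samples = g$samples)
}

#' Read per-tissue expression matrices
#'
#' Accepts plain TSV (rows = genes, columns = samples, first column the gene
#' id) or GCT 1.2 (two header lines, then `Name`/`Description` + samples).
#'
#' @param path File path.
#' @param format `"tsv"` or `"gct"`; `"auto"` sniffs GCT by its `#1.2` line.
#' @return Numeric matrix genes x samples with dimnames.
#' @export
read_expression <- function(path, format = c("auto", "tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") {
    format <- if (startsWith(readLines(path, n = 1L), "#1.2")) "gct" else "tsv"
  }
  if (format == "gct") {
    dt <- data.table::fread(path, skip = 2L, header = TRUE)
    genes <- as.character(dt[[1]])
    m <- as.matrix(dt[, -(1:2), drop = FALSE])
  } else {
    dt <- data.table::fread(path, header = TRUE)
    genes <- as.character(dt[[1]])
    m <- as.matrix(dt[, -1, drop = FALSE])
  }
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV
#'
#' @param m Numeric matrix genes x samples.
#' @param path Output path.
#' @param id_col Name of the leading gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, id_col = "gene_id") {
  dt <- data.table::data.table(V1 = rownames(m))
  data.table::setnames(dt, "V1", id_col)
  for (j in seq_len(ncol(m))) data.table::set(dt, j = colnames(m)[j],
                                              value = m[, j])
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a covariate table
#'
#' TSV with rows = samples (first column the sample id) and named numeric
#' covariate columns (sex, genotyping PCs, expression factors, ...).
#'
#' @param path File path.
#' @return `data.frame` with rownames = sample ids; all columns numeric.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = TRUE)
  out <- as.data.frame(dt[, -1, drop = FALSE])
  rownames(out) <- as.character(dt[[1]])
  if (anyNA(out)) stop("covariate table contains missing values")
  out
}

#' Read GWAS summary statistics
#'
#' TSV with columns `SNP`, `A1` (effect allele), `A2`, `Z`, `N` (sample
#' size, possibly an effective N for binary traits).
#'
#' @param path File path.
#' @return `data.frame` with columns `id`, `a1`, `a2`, `z`, `n`.
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = TRUE)
  need <- c("SNP", "A1", "A2", "Z", "N")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols) > 0L) {
    stop("summary-statistics file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(dt$Z))) stop("non-finite Z value(s) in ", path)
  data.frame(id = as.character(dt$SNP), a1 = toupper(dt$A1),
             a2 = toupper(dt$A2), z = as.numeric(dt$Z), n = as.numeric(dt$N),
             stringsAsFactors = FALSE)
}

#' Write / read block LD reference matrices
#'
#' A directory with an index TSV (`block`, `file`, `n_snps`) plus one TSV
#' per block: SNP ids and per-SNP dosage SDs in the first two columns, then
#' the correlation matrix.
#'
#' @param blocks List of blocks, each `list(ids, R, sd)`.
#' @param dir Directory path (created if needed).
#' @return `dir` (write) or the block list (read), invisibly for write.
#' @export
write_ld_blocks <- function(blocks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("block_%03d.tsv", seq_along(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    dt <- data.table::data.table(id = b$ids, sd = b$sd)
    R <- as.data.frame(b$R)
    names(R) <- b$ids
    data.table::fwrite(cbind(dt, R), file.path(dir, files[i]), sep = "\t")
  }
  data.table::fwrite(data.table::data.table(
    block = seq_along(blocks), file = files,
    n_snps = vapply(blocks, function(b) length(b$ids), integer(1))),
    file.path(dir, "blocks_index.tsv"), sep = "\t")
  invisible(dir)
}

#' @rdname write_ld_blocks
#' @export
read_ld_blocks <- function(dir) {
  idx <- data.table::fread(file.path(dir, "blocks_index.tsv"))
  lapply(seq_len(nrow(idx)), function(i) {
    dt <- data.table::fread(file.path(dir, idx$file[i]), header = TRUE)
    ids <- as.character(dt[[1]])
    R <- as.matrix(dt[, -(1:2), drop = FALSE])
    dimnames(R) <- list(ids, ids)
    list(ids = ids, R = R, sd = as.numeric(dt[[2]]))
  })
}
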