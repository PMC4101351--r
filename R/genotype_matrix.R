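# The central data container: a samples x SNPs minor-allele dosage matrix
# with a binary phenotype and per-SNP metadata.

#' Construct a genotype matrix with phenotype
#'
#' @param genotypes Integer matrix, samples in rows and SNPs in columns,
#'   coded as minor-allele dosage 0/1/2 with `NA` for missing genotypes.
#' @param phenotype Binary vector (1 = case, 0 = control), one per sample.
#' @param snp_meta Optional data frame with one row per SNP and columns
#'   `id`, `chr`, `pos`, `allele1`, `allele2` (1-based positions, PLINK
#'   convention). Defaults are synthesized from column names.
#' @param sample_ids Optional character vector of per-sample identifiers.
#' @return An object of class `"genotype_matrix"`: a list with elements
#'   `genotypes`, `phenotype`, `snp_meta`, `sample_ids`.
#' @export
genotype_matrix <- function(genotypes, phenotype, snp_meta = NULL,
                            sample_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  n <- nrow(genotypes)
  m <- ncol(genotypes)
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != n) {
    stop("`phenotype` length must equal the number of samples")
  }
  if (any(is.na(phenotype)) || !all(phenotype %in% 0:1)) {
    stop("`phenotype` must be 0 (control) or 1 (case) with no NA")
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(genotypes)
    if (is.null(sample_ids)) sample_ids <- sprintf("sample%04d", seq_len(n))
  }
  if (is.null(snp_meta)) {
    ids <- colnames(genotypes)
    if (is.null(ids)) ids <- sprintf("snp%04d", seq_len(m))
    snp_meta <- data.frame(
      id = ids, chr = rep("0", m), pos = seq_len(m),
      allele1 = rep("A", m), allele2 = rep("B", m),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(snp_meta) != m) {
    stop("`snp_meta` must have one row per SNP column")
  }
  colnames(genotypes) <- snp_meta$id
  rownames(genotypes) <- sample_ids
  structure(
    list(genotypes = genotypes, phenotype = phenotype,
         snp_meta = snp_meta, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples (%d cases / %d controls) x %d SNPs; %d missing genotypes\n",
    nrow(x$genotypes), sum(x$phenotype == 1), sum(x$phenotype == 0),
    ncol(x$genotypes), sum(is.na(x$genotypes))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' Minor allele frequency of each SNP
#'
#' Computed on non-missing genotypes after dosage orientation, so the value
#' is in `[0, 0.5]` by construction.
#'
#' @param g A [genotype_matrix()].
#' @return Numeric vector of per-SNP MAFs (NA for SNPs with no calls).
#' @export
snp_maf <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  f <- colMeans(g$genotypes, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

# Subset SNP columns, keeping metadata aligned.
subset_snps <- function(g, keep) {
  genotype_matrix(
    g$genotypes[, keep, drop = FALSE], g$phenotype,
    snp_meta = g$snp_meta[keep, , drop = FALSE],
    sample_ids = g$sample_ids
  )
}
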