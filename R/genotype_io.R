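# Readers/writers for PLINK binary and TSV genotype data, the QC filters
# applied before scanning, and the results serializers.

PLINK_MAGIC <- as.raw(c(0x6c, 0x1b))

#' Read a PLINK binary trio (.bed/.bim/.fam)
#'
#' Supports the v1.00 SNP-major layout: magic bytes `0x6C 0x1B`, mode byte
#' `0x01`, then per SNP `ceiling(N/4)` bytes of 2-bit genotypes
#' (00 = homozygous allele1, 01 = missing, 10 = heterozygous,
#' 11 = homozygous allele2). Genotypes are recoded to minor-allele dosage
#' using the observed allele frequencies; the .bim allele order is kept as
#' metadata but not trusted for minor/major orientation. Phenotype is taken
#' from .fam column 6 (2 = case, 1 = control); samples with any other value
#' are dropped with a message.
#'
#' @param bed_path,bim_path,fam_path Paths to the three files. If only
#'   `bed_path` is given and ends in `.bed`, the .bim/.fam paths are derived
#'   from the same prefix.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(bed_path, bim_path = NULL, fam_path = NULL) {
  if (is.null(bim_path)) bim_path <- sub("\\.bed$", ".bim", bed_path)
  if (is.null(fam_path)) fam_path <- sub("\\.bed$", ".fam", bed_path)
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  bim <- read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chr", "id", "cm", "pos", "allele1", "allele2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(fam_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(fam) < 6) stop("malformed .fam: expected 6 columns")
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != PLINK_MAGIC[1] || raw[2] != PLINK_MAGIC[2]) {
    stop("not a PLINK v1 .bed file (bad magic bytes): ", bed_path)
  }
  if (raw[3] == as.raw(0x00)) {
    stop("individual-major .bed (mode byte 0x00) is not supported; ",
         "re-save in SNP-major order")
  }
  if (raw[3] != as.raw(0x01)) stop("unknown .bed mode byte: ", as.integer(raw[3]))
  bytes_per_snp <- ceiling(n / 4)
  if (length(raw) - 3L != bytes_per_snp * m) {
    stop(sprintf(
      ".bed payload is %d bytes but .bim/.fam imply %d (%d SNPs x %d bytes)",
      length(raw) - 3L, bytes_per_snp * m, m, bytes_per_snp
    ))
  }
  # 2-bit codes, sample-fastest within each SNP block; rawToBits is LSB-first
  bits <- as.integer(rawToBits(raw[-(1:3)]))
  two_bit <- bits[c(TRUE, FALSE)] + 2L * bits[c(FALSE, TRUE)]
  codes <- matrix(two_bit, nrow = bytes_per_snp * 4L, ncol = m)[seq_len(n), ,
                                                                drop = FALSE]
  # code -> dosage of allele1: 0 (00) hom A1 = 2, 2 (10) het = 1, 3 (11) hom A2 = 0
  dosage <- matrix(c(2L, NA_integer_, 1L, 0L)[codes + 1L], nrow = n, ncol = m)
  # orient to minor-allele dosage from observed frequencies
  freq1 <- colMeans(dosage, na.rm = TRUE) / 2
  flip <- !is.na(freq1) & freq1 > 0.5
  dosage[, flip] <- 2L - dosage[, flip]

  phen_raw <- fam[[6]]
  phenotype <- ifelse(phen_raw == 2, 1L, ifelse(phen_raw == 1, 0L, NA_integer_))
  keep <- !is.na(phenotype)
  if (!all(keep)) {
    message(sum(!keep), " sample(s) dropped for missing/unknown phenotype")
  }
  genotype_matrix(
    dosage[keep, , drop = FALSE], phenotype[keep],
    snp_meta = bim[, c("id", "chr", "pos", "allele1", "allele2")],
    sample_ids = paste(fam[[1]], fam[[2]], sep = "_")[keep]
  )
}

#' Write a genotype matrix as a PLINK binary trio
#'
#' Minor-allele dosage is stored as the allele1 dosage (SNP-major v1 layout),
#' so a subsequent [read_plink()] round-trips the codes exactly as long as no
#' SNP has minor-allele frequency above 0.5 (true by construction).
#'
#' @param g A [genotype_matrix()].
#' @param prefix Output path prefix; writes `<prefix>.bed/.bim/.fam`.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$genotypes)
  m <- ncol(g$genotypes)
  bytes_per_snp <- ceiling(n / 4)
  # dosage -> 2-bit code (00 hom A1 = dosage 2, 10 het, 11 hom A2, 01 missing)
  code_of <- function(d) {
    out <- integer(length(d))
    out[is.na(d)] <- 1L
    out[!is.na(d) & d == 2L] <- 0L
    out[!is.na(d) & d == 1L] <- 2L
    out[!is.na(d) & d == 0L] <- 3L
    out
  }
  payload <- raw(bytes_per_snp * m)
  for (j in seq_len(m)) {
    codes <- c(code_of(g$genotypes[, j]), integer(bytes_per_snp * 4L - n))
    bits <- rbind(codes %% 2L, codes %/% 2L)
    payload[(j - 1L) * bytes_per_snp + seq_len(bytes_per_snp)] <-
      packBits(as.integer(bits) > 0L, "raw")
  }
  writeBin(c(PLINK_MAGIC, as.raw(0x01), payload), paste0(prefix, ".bed"))
  meta <- g$snp_meta
  write.table(
    data.frame(meta$chr, meta$id, 0, meta$pos, meta$allele1, meta$allele2),
    paste0(prefix, ".bim"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  write.table(
    data.frame(g$sample_ids, g$sample_ids, 0, 0, 0,
               ifelse(g$phenotype == 1, 2L, 1L)),
    paste0(prefix, ".fam"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(prefix)
}

#' Read a TSV genotype matrix
#'
#' Dialect: a header line `sample_id<TAB>phenotype<TAB><snp ids...>`, then
#' one row per sample with phenotype 0/1 and genotype codes 0/1/2 or NA.
#'
#' @param path Input file.
#' @return A [genotype_matrix()].
#' @export
read_tsv_genotypes <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", na.strings = character())
  if (ncol(tab) < 3) stop("genotype TSV needs sample_id, phenotype and >= 1 SNP column")
  snp_ids <- colnames(tab)[-(1:2)]
  geno <- as.matrix(tab[, -(1:2), drop = FALSE])
  ok <- geno %in% c("0", "1", "2", "NA")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    row <- (bad - 1L) %% nrow(geno) + 1L
    col <- (bad - 1L) %/% nrow(geno) + 1L
    stop(sprintf(
      "invalid genotype token '%s' at sample row %d, SNP column '%s' (expected 0/1/2/NA)",
      geno[bad], row, snp_ids[col]
    ))
  }
  geno[geno == "NA"] <- NA
  storage.mode(geno) <- "integer"
  phen <- tab[[2]]
  if (!all(phen %in% c("0", "1"))) {
    stop("phenotype column must be 0 (control) or 1 (case)")
  }
  genotype_matrix(
    geno, as.integer(phen),
    snp_meta = data.frame(id = snp_ids, chr = "0", pos = seq_along(snp_ids),
                          allele1 = "A", allele2 = "B", stringsAsFactors = FALSE),
    sample_ids = tab[[1]]
  )
}

#' Write a genotype matrix to the TSV dialect
#'
#' @param g A [genotype_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_tsv_genotypes <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  out <- data.frame(
    sample_id = g$sample_ids, phenotype = g$phenotype,
    g$genotypes, check.names = FALSE, stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hardy-Weinberg equilibrium test for one SNP
#'
#' Chi-square goodness-of-fit (1 df) of observed genotype counts against the
#' HWE expectations `p^2, 2pq, q^2` at the observed allele frequency.
#'
#' @param n_hom1,n_het,n_hom2 Genotype counts (homozygous allele1,
#'   heterozygous, homozygous allele2); total must be positive.
#' @return HWE p-value. A monomorphic SNP returns 1.
#' @export
hwe_test <- function(n_hom1, n_het, n_hom2) {
  counts <- c(n_hom1, n_het, n_hom2)
  if (any(counts < 0) || any(is.na(counts))) stop("counts must be nonnegative")
  n <- sum(counts)
  if (n <= 0) stop("no genotype calls")
  p <- (2 * n_hom1 + n_het) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((counts - expected)^2 / expected)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Quality-control filter for a genotype matrix
#'
#' SNPs are removed, in order, by (1) call rate below `call_rate_min`,
#' (2) Hardy-Weinberg p-value below `hwe_alpha` evaluated in controls only,
#' (3) minor allele frequency below `maf_min`. Each SNP is attributed to the
#' first filter that removes it. Defaults follow common GWAS practice:
#' call rate 95%, HWE alpha 5.7e-7, MAF 5%.
#'
#' @param g A [genotype_matrix()].
#' @param call_rate_min,hwe_alpha,maf_min Thresholds in `[0, 1]`.
#' @return A list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report` (class `"qc_report"`): SNP counts in/out and per-filter
#'   removal tallies.
#' @export
qc_filter <- function(g, call_rate_min = 0.95, hwe_alpha = 5.7e-7,
                      maf_min = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  for (thr in c(call_rate_min, hwe_alpha, maf_min)) {
    if (is.na(thr) || thr < 0 || thr > 1) stop("QC thresholds must lie in [0, 1]")
  }
  m <- ncol(g$genotypes)
  if (m == 0L) stop("empty genotype matrix")
  call_rate <- colMeans(!is.na(g$genotypes))
  controls <- g$genotypes[g$phenotype == 0, , drop = FALSE]
  hwe_p <- vapply(seq_len(m), function(j) {
    gj <- controls[, j]
    gj <- gj[!is.na(gj)]
    if (length(gj) == 0L) return(1)
    hwe_test(sum(gj == 0), sum(gj == 1), sum(gj == 2))
  }, numeric(1))
  maf <- snp_maf(g)
  maf[is.na(maf)] <- 0

  fail_call <- call_rate < call_rate_min
  fail_hwe <- !fail_call & hwe_p < hwe_alpha
  fail_maf <- !fail_call & !fail_hwe & maf < maf_min
  keep <- !(fail_call | fail_hwe | fail_maf)

  report <- structure(
    list(
      n_snps_in = m, n_snps_out = sum(keep),
      removed_by_call_rate = sum(fail_call),
      removed_by_hwe = sum(fail_hwe),
      removed_by_maf = sum(fail_maf),
      thresholds = c(call_rate_min = call_rate_min, hwe_alpha = hwe_alpha,
                     maf_min = maf_min)
    ),
    class = "qc_report"
  )
  list(genotypes = subset_snps(g, keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "QC: %d SNPs in, %d out (removed: %d call-rate, %d HWE, %d MAF)\n",
    x$n_snps_in, x$n_snps_out, x$removed_by_call_rate, x$removed_by_hwe,
    x$removed_by_maf
  ))
  invisible(x)
}

#' Write scan results to TSV
#'
#' Columns: rank, snp_ids (semicolon-joined), order, ig_bits, levels_x,
#' n_complete, p_raw, p_bonferroni. Rows are written in rank order.
#'
#' @param results A results data frame from [scan_exhaustive()] or
#'   [scan_stepwise()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- data.frame(
    rank = seq_len(nrow(results)),
    snp_ids = results$snp_ids,
    order = results$order,
    ig_bits = results$ig_bits,
    levels_x = results$levels_x,
    n_complete = results$n_complete,
    p_raw = results$p_raw,
    p_bonferroni = results$p_adjusted,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a results TSV written by [write_results()]
#'
#' @param path Input file.
#' @return A data frame with the serialized columns.
#' @export
read_results <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a pairwise edge list for network import
#'
#' Order-2 results only, one row per SNP pair: `snp_a`, `snp_b`,
#' `p_bonferroni`.
#'
#' @inheritParams write_results
#' @return `path`, invisibly.
#' @export
write_edges <- function(results, path) {
  pairs <- results[results$order == 2, , drop = FALSE]
  split_ids <- strsplit(pairs$snp_ids, ";", fixed = TRUE)
  out <- data.frame(
    snp_a = vapply(split_ids, `[`, "", 1L),
    snp_b = vapply(split_ids, `[`, "", 2L),
    p_bonferroni = pairs$p_adjusted,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
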