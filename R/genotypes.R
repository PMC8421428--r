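#' Construct a genotype container
#'
#' A dense n-by-m allele-dosage matrix plus a per-SNP metadata table. Dosages
#' count copies of `allele1` (the effect/counted allele) and lie in \[0, 2\];
#' hard calls are integers in {0, 1, 2}, continuous dosages (e.g. read from
#' VCF DS-free GT fields after mean imputation) are allowed.
#'
#' @param dosages Numeric or integer matrix, individuals in rows, SNPs in
#'   columns. Row names are individual ids (generated if absent).
#' @param snps Tibble with one row per SNP column: `snp_id`, `chromosome`,
#'   `position` (1-based, strictly increasing within a chromosome),
#'   `allele_freq` (frequency of `allele1`), `allele1`, `allele2`.
#'
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(dosages, snps) {
  snps <- as_tibble(snps)
  stopifnot(is.matrix(dosages), nrow(snps) == ncol(dosages))
  required <- c("snp_id", "chromosome", "position", "allele_freq", "allele1", "allele2")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0)
    abort(paste0("snps table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  snps$snp_id <- as.character(snps$snp_id)
  snps$chromosome <- as.character(snps$chromosome)
  snps$position <- as.integer(snps$position)
  snps$allele1 <- as.character(snps$allele1)
  snps$allele2 <- as.character(snps$allele2)
  rng <- range(dosages)
  if (rng[1] < 0 || rng[2] > 2) abort("dosages must lie in [0, 2]")
  for (chr in unique(snps$chromosome)) {
    pos <- snps$position[snps$chromosome == chr]
    if (any(diff(pos) <= 0))
      abort("positions must be strictly increasing within a chromosome")
  }
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("ind_", seq_len(nrow(dosages)))
  colnames(dosages) <- snps$snp_id
  structure(
    list(dosages = dosages, snps = snps),
    class = "genotype_data"
  )
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("<genotype_data> %d individuals x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$snps$chromosome), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$dosages)

#' Individual ids of a genotype container
#' @param x A `genotype_data` object.
#' @return Character vector of individual ids.
#' @export
individual_ids <- function(x) rownames(x$dosages)

# subset SNP columns, keeping metadata in sync
subset_snps <- function(geno, snp_ids) {
  keep <- match(snp_ids, geno$snps$snp_id)
  if (anyNA(keep)) abort("unknown snp_id in subset")
  genotype_data(geno$dosages[, keep, drop = FALSE], geno$snps[keep, ])
}

# subset individuals by index or id
subset_individuals <- function(geno, idx) {
  genotype_data(geno$dosages[idx, , drop = FALSE], geno$snps)
}
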