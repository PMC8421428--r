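#' Compute polygenic risk scores
#'
#' The PRS of individual i is the weighted allele-dosage sum
#' `sum_j beta_j * dosage_ij` over the selected SNPs. Effect alleles are
#' reconciled with the genotype orientation: when the summary-statistics
#' effect/other alleles are swapped relative to the counted allele, the
#' dosage is flipped (`2 - d`, equivalently the beta sign is flipped plus a
#' constant shift); SNPs whose alleles cannot be reconciled are dropped with
#' a warning.
#'
#' @param genotypes [genotype_data()] for the target individuals.
#' @param sumstats Summary-statistics tibble supplying `beta` and alleles.
#' @param snp_subset Character vector of snp_ids to score (e.g. the output of
#'   [threshold_snps()] then [prune_snps()]); must be nonempty.
#' @return A tibble `individual_id`, `score`, with attributes `n_snps_used`
#'   and `selection` (a list recording the SNP set size and any drops).
#' @examples
#' cfg <- architecture_config(n_individuals = 50, m_snps = 10, polygenicity = 1,
#'                            seed = 3)
#' g <- simulate_genotypes(cfg)
#' ph <- simulate_phenotypes(g, cfg)
#' ss <- run_gwas(g, ph, seq_len(25))
#' prs <- compute_prs(g, ss, ss$snp_id)
#' @export
compute_prs <- function(genotypes, sumstats, snp_subset) {
  if (length(snp_subset) == 0)
    abort("snp_subset is empty: no SNPs survived selection")
  idx_g <- match(snp_subset, genotypes$snps$snp_id)
  idx_s <- match(snp_subset, sumstats$snp_id)
  if (anyNA(idx_g)) abort("snp_subset contains SNPs absent from genotypes")
  if (anyNA(idx_s)) abort("snp_subset contains SNPs absent from sumstats")

  ga1 <- genotypes$snps$allele1[idx_g]
  ga2 <- genotypes$snps$allele2[idx_g]
  ea <- sumstats$effect_allele[idx_s]
  oa <- sumstats$other_allele[idx_s]
  direct <- ea == ga1 & oa == ga2
  flipped <- ea == ga2 & oa == ga1
  unresolved <- !(direct | flipped)
  if (mean(unresolved) > 0.5)
    abort(sprintf(
      "%d of %d SNPs have irreconcilable alleles (likely strand or build mismatch)",
      sum(unresolved), length(snp_subset)))
  if (any(unresolved))
    warn(sprintf("dropping %d SNP(s) with irreconcilable alleles", sum(unresolved)))
  keep <- !unresolved
  if (!any(keep)) abort("no SNPs left after allele reconciliation")

  x <- genotypes$dosages[, idx_g[keep], drop = FALSE]
  storage.mode(x) <- "double"
  flip <- flipped[keep]
  if (any(flip)) x[, flip] <- 2 - x[, flip]
  beta <- sumstats$beta[idx_s[keep]]
  score <- as.vector(x %*% beta)

  out <- tibble(individual_id = individual_ids(genotypes), score = score)
  attr(out, "n_snps_used") <- sum(keep)
  attr(out, "selection") <- list(
    requested = length(snp_subset),
    used = sum(keep),
    flipped = sum(flip),
    dropped_unresolved = sum(unresolved)
  )
  out
}
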