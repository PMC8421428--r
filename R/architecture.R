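#' Describe a simulated genetic architecture
#'
#' Bundles the parameters of a liability-threshold case-control simulation:
#' cohort size, number of variants, polygenicity (fraction of variants that
#' are causal), narrow-sense heritability on the liability scale, population
#' prevalence, the allele-frequency spectrum, optional block LD, and the
#' fraction of individuals reserved for the discovery GWAS.
#'
#' @param n_individuals Number of individuals to simulate.
#' @param m_snps Number of biallelic SNPs.
#' @param polygenicity Fraction of SNPs that are causal, in (0, 1]. The causal
#'   count is `round(polygenicity * m_snps)` and must be at least 1.
#' @param heritability Liability-scale h-squared, in \[0, 1).
#' @param prevalence Population prevalence K, in (0, 1); cases are individuals
#'   whose liability exceeds `qnorm(1 - prevalence)`.
#' @param maf_low,maf_high Bounds of the uniform minor-allele-frequency
#'   spectrum; `maf_low` must be at least 0.01 (the PRS MAF floor) and
#'   `maf_high` at most 0.5.
#' @param ld_block_rho Adjacent-SNP haplotype correlation in \[0, 1). Zero
#'   (the default) gives linkage equilibrium; positive values induce
#'   autoregressive LD within blocks so that pairwise r-squared decays with
#'   distance.
#' @param ld_block_size Number of SNPs per LD block (ignored when
#'   `ld_block_rho` is 0).
#' @param snp_spacing_bp Distance between adjacent SNPs in base pairs.
#' @param discovery_proportion Fraction of individuals used as the discovery
#'   GWAS sample, in (0, 1).
#' @param seed Integer seed; every random draw in the simulation flows from it.
#'
#' @return An object of class `architecture_config` (a named list).
#' @examples
#' architecture_config(n_individuals = 500, m_snps = 200, seed = 1)
#' @export
architecture_config <- function(n_individuals = 10000,
                                m_snps = 20000,
                                polygenicity = 0.01,
                                heritability = 0.5,
                                prevalence = 0.05,
                                maf_low = 0.05,
                                maf_high = 0.5,
                                ld_block_rho = 0,
                                ld_block_size = 20,
                                snp_spacing_bp = 1000,
                                discovery_proportion = 0.5,
                                seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    m_snps = as.integer(m_snps),
    polygenicity = polygenicity,
    heritability = heritability,
    prevalence = prevalence,
    maf_low = maf_low,
    maf_high = maf_high,
    ld_block_rho = ld_block_rho,
    ld_block_size = as.integer(ld_block_size),
    snp_spacing_bp = as.integer(snp_spacing_bp),
    discovery_proportion = discovery_proportion,
    seed = as.integer(seed)
  )
  class(cfg) <- "architecture_config"
  validate_architecture_config(cfg)
  cfg
}

validate_architecture_config <- function(cfg) {
  stop_field <- function(field, msg) {
    abort(sprintf("invalid `%s`: %s", field, msg), class = "mondrianprs_parameter_error")
  }
  if (cfg$n_individuals < 2) stop_field("n_individuals", "need at least 2 individuals")
  if (cfg$m_snps < 1) stop_field("m_snps", "need at least 1 SNP")
  if (cfg$polygenicity <= 0 || cfg$polygenicity > 1)
    stop_field("polygenicity", "must be in (0, 1]")
  if (round(cfg$polygenicity * cfg$m_snps) < 1)
    stop_field("polygenicity", "round(polygenicity * m_snps) must be >= 1")
  if (cfg$heritability < 0 || cfg$heritability >= 1)
    stop_field("heritability", "must be in [0, 1)")
  if (cfg$prevalence <= 0 || cfg$prevalence >= 1)
    stop_field("prevalence", "must be in (0, 1)")
  if (cfg$maf_low < 0.01)
    stop_field("maf_low", "must be >= 0.01 (PRS MAF floor)")
  if (cfg$maf_low > cfg$maf_high || cfg$maf_high > 0.5)
    stop_field("maf_high", "need maf_low <= maf_high <= 0.5")
  if (cfg$ld_block_rho < 0 || cfg$ld_block_rho >= 1)
    stop_field("ld_block_rho", "must be in [0, 1)")
  if (cfg$discovery_proportion <= 0 || cfg$discovery_proportion >= 1)
    stop_field("discovery_proportion", "must be in (0, 1)")
  invisible(cfg)
}

#' @export
print.architecture_config <- function(x, ...) {
  cat("<architecture_config>\n")
  cat(sprintf("  n = %d individuals, m = %d SNPs\n", x$n_individuals, x$m_snps))
  cat(sprintf("  polygenicity %.4g, h2 %.3g, prevalence %.3g\n",
              x$polygenicity, x$heritability, x$prevalence))
  cat(sprintf("  MAF ~ U(%.3g, %.3g), LD rho %.3g, discovery %.3g, seed %d\n",
              x$maf_low, x$maf_high, x$ld_block_rho, x$discovery_proportion, x$seed))
  invisible(x)
}
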