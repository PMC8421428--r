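#' Simulate genotype dosages under a given allele-frequency spectrum
#'
#' Draws per-SNP allele frequencies uniformly from
#' `[maf_low, maf_high]` and genotypes under Hardy-Weinberg proportions.
#' With `ld_block_rho > 0`, the two haplotypes of each individual follow a
#' latent Gaussian AR(1) process within blocks of `ld_block_size` SNPs, so
#' adjacent SNPs are correlated and pairwise r-squared decays with distance;
#' marginal allele frequencies are preserved. All SNPs are placed on
#' chromosome 1 at `snp_spacing_bp` intervals.
#'
#' Deterministic given `config$seed`.
#'
#' @param config An [architecture_config()].
#' @return A [genotype_data()] with integer dosages in {0, 1, 2}.
#' @examples
#' g <- simulate_genotypes(architecture_config(n_individuals = 100, m_snps = 50, seed = 7))
#' dim(g)
#' @export
simulate_genotypes <- function(config) {
  validate_architecture_config(config)
  n <- config$n_individuals
  m <- config$m_snps
  set.seed(config$seed)
  freq <- runif(m, config$maf_low, config$maf_high)

  dos <- matrix(0L, nrow = n, ncol = m)
  if (config$ld_block_rho == 0) {
    # linkage equilibrium: independent HWE draws, chunked to bound memory
    chunk <- 2000L
    for (s in seq(1L, m, by = chunk)) {
      e <- min(s + chunk - 1L, m)
      k <- e - s + 1L
      dos[, s:e] <- matrix(
        rbinom(n * k, 2L, rep(freq[s:e], each = n)),
        nrow = n, ncol = k
      )
    }
  } else {
    rho <- config$ld_block_rho
    bs <- max(1L, config$ld_block_size)
    starts <- seq(1L, m, by = bs)
    thr <- qnorm(freq) # allele = latent below threshold => marginal freq kept
    for (s in starts) {
      e <- min(s + bs - 1L, m)
      k <- e - s + 1L
      block <- matrix(0L, n, k)
      for (hap in 1:2) {
        z <- matrix(rnorm(n * k), n, k)
        if (k > 1) {
          for (j in 2:k) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
        }
        block <- block + (z < rep(thr[s:e], each = n))
      }
      dos[, s:e] <- block
    }
  }

  snps <- tibble(
    snp_id = sprintf("snp_%05d", seq_len(m)),
    chromosome = "1",
    position = seq_len(m) * config$snp_spacing_bp,
    allele_freq = freq,
    allele1 = "A",
    allele2 = "B"
  )
  rownames(dos) <- paste0("ind_", seq_len(n))
  genotype_data(dos, snps)
}

#' Simulate liability-threshold case-control phenotypes
#'
#' Implements the standard additive liability-threshold generative model on
#' standardized genotypes: `round(polygenicity * m)` causal SNPs are chosen
#' uniformly at random; their effects are drawn i.i.d. Normal(0, h2 / m_causal),
#' applied to column-standardized dosages, and rescaled so the sample variance
#' of the genetic value g is exactly h2 (the usual variance calibration in
#' GWAS simulators; without it, with few causal SNPs the realized heritability
#' and prevalence drift far from their nominal values). An independent
#' environmental deviate e ~ Normal(0, 1 - h2) completes the liability
#' l = g + e; an individual is a case exactly when l exceeds
#' `qnorm(1 - prevalence)`.
#'
#' Deterministic given `config$seed` (a seed offset keeps the draws
#' independent of those used for the genotypes).
#'
#' @param genotypes A [genotype_data()] with as many SNPs as `config$m_snps`.
#' @param config The [architecture_config()] used for `genotypes`.
#' @return A tibble with one row per individual: `individual_id`,
#'   `genetic_value`, `liability`, `status` (1 case / 0 control). The causal
#'   effect table (snp_id, effect) is attached as attribute `"causal"`.
#' @examples
#' cfg <- architecture_config(n_individuals = 200, m_snps = 50, polygenicity = 0.1, seed = 7)
#' ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
#' table(ph$status)
#' @export
simulate_phenotypes <- function(genotypes, config) {
  validate_architecture_config(config)
  m <- ncol(genotypes$dosages)
  if (m != config$m_snps)
    abort("genotypes and config disagree on the number of SNPs")
  m_c <- round(config$polygenicity * m)
  if (m_c < 1)
    abort("no causal SNPs: round(polygenicity * m_snps) is 0",
          class = "mondrianprs_parameter_error")
  n <- nrow(genotypes$dosages)
  h2 <- config$heritability

  set.seed(config$seed + 500L)
  causal_idx <- sort(sample.int(m, m_c))
  if (h2 > 0) {
    effects <- rnorm(m_c, 0, sqrt(h2 / m_c))
    xc <- genotypes$dosages[, causal_idx, drop = FALSE]
    storage.mode(xc) <- "double"
    mu <- colMeans(xc)
    sdv <- apply(xc, 2, sd)
    sdv[sdv == 0] <- 1 # monomorphic causal SNP contributes nothing
    g <- as.vector(scale(xc, center = mu, scale = sdv) %*% effects)
    # calibrate to the realized genetic variance so that h2 is exact by
    # construction (otherwise, with few causal SNPs, var(g) fluctuates and
    # liability variance / prevalence drift from their nominal values)
    v <- var(g)
    if (v > 0) {
      sc <- sqrt(h2 / v)
      g <- g * sc
      effects <- effects * sc
    }
  } else {
    effects <- rep(0, m_c)
    g <- rep(0, n)
  }
  e <- rnorm(n, 0, sqrt(1 - h2))
  liab <- g + e
  thr <- qnorm(1 - config$prevalence)

  out <- tibble(
    individual_id = individual_ids(genotypes),
    genetic_value = g,
    liability = liab,
    status = as.integer(liab > thr)
  )
  attr(out, "causal") <- tibble(
    snp_id = genotypes$snps$snp_id[causal_idx],
    effect = effects
  )
  out
}

#' Pick a discovery / target split
#'
#' Samples `round(discovery_proportion * n)` individuals (without replacement)
#' as the discovery GWAS set; the remainder is the target sample on which PRS
#' and MCCP operate. Deterministic given `config$seed`.
#'
#' @param n Number of individuals.
#' @param config An [architecture_config()].
#' @return A list with integer index vectors `discovery` and `target`.
#' @export
discovery_split <- function(n, config) {
  set.seed(config$seed + 1000L)
  n_disc <- round(config$discovery_proportion * n)
  disc <- sort(sample.int(n, n_disc))
  list(discovery = disc, target = setdiff(seq_len(n), disc))
}
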