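#' Per-SNP discovery GWAS by univariate logistic regression
#'
#' Fits, for every SNP, the logistic regression of case-control status on
#' allele dosage in the discovery individuals and returns the Wald summary
#' statistics. The per-SNP fits are computed by a vectorized two-parameter
#' Newton-Raphson (intercept + dosage) run simultaneously across SNP chunks;
#' results agree with `glm(status ~ dosage, family = binomial)` to numerical
#' precision. Monomorphic SNPs get `beta = 0`, `p_value = 1`. SNPs with
#' (quasi-)complete separation — common for strong effects at low prevalence,
#' where the Wald statistic degenerates — get the logistic score-test p-value
#' and a slope-ridge-penalized effect estimate instead.
#'
#' @param genotypes A [genotype_data()].
#' @param phenotypes Phenotype tibble with a `status` column aligned with the
#'   genotype rows (as returned by [simulate_phenotypes()]).
#' @param discovery_index Integer indices (or individual ids) of the discovery
#'   subsample; must contain both cases and controls and should be disjoint
#'   from any individuals later used for training, calibration or testing.
#' @param status_col Name of the binary status column.
#' @return A summary-statistics tibble: `snp_id`, `effect_allele`,
#'   `other_allele`, `beta` (per-allele log-odds), `se`, `p_value`,
#'   `allele_freq` (effect-allele frequency in the discovery sample).
#' @examples
#' cfg <- architecture_config(n_individuals = 300, m_snps = 40, polygenicity = 0.25,
#'                            heritability = 0.5, prevalence = 0.3, seed = 2)
#' g <- simulate_genotypes(cfg)
#' ph <- simulate_phenotypes(g, cfg)
#' ss <- run_gwas(g, ph, seq_len(150))
#' @export
run_gwas <- function(genotypes, phenotypes, discovery_index,
                     status_col = "status") {
  if (is.character(discovery_index))
    discovery_index <- match(discovery_index, individual_ids(genotypes))
  y <- phenotypes[[status_col]][discovery_index]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    abort(sprintf(
      "discovery set must contain both classes (got %d cases, %d controls)",
      n1, n0))

  m <- ncol(genotypes$dosages)
  beta <- numeric(m); se <- rep(NA_real_, m); pval <- rep(1, m)
  afreq <- numeric(m)

  chunk <- 2000L
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    x <- genotypes$dosages[discovery_index, s:e, drop = FALSE]
    storage.mode(x) <- "double"
    fit <- logistic_gwas_chunk(x, y)
    beta[s:e] <- fit$beta
    se[s:e] <- fit$se
    pval[s:e] <- fit$p
    afreq[s:e] <- colMeans(x) / 2
  }

  tibble(
    snp_id = genotypes$snps$snp_id,
    effect_allele = genotypes$snps$allele1,
    other_allele = genotypes$snps$allele2,
    beta = beta,
    se = se,
    p_value = pval,
    allele_freq = afreq
  )
}

# Vectorized per-column logistic regression y ~ 1 + x_j, Newton-Raphson on
# the 2x2 information matrix, all columns of a chunk at once.
logistic_gwas_chunk <- function(x, y, max_iter = 25L, tol = 1e-10) {
  n <- nrow(x); k <- ncol(x)
  mono <- apply(x, 2, function(col) max(col) == min(col))
  b0 <- rep(qlogis(mean(y)), k)
  b1 <- numeric(k)
  active <- !mono
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    eta <- x * rep(b1, each = n) + rep(b0, each = n)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    r <- y - mu
    u0 <- colSums(r); u1 <- colSums(x * r)
    i00 <- colSums(w); i01 <- colSums(x * w); i11 <- colSums(x * x * w)
    det <- i00 * i11 - i01 * i01
    det[det <= 0 | !is.finite(det)] <- NA
    d0 <- (i11 * u0 - i01 * u1) / det
    d1 <- (i00 * u1 - i01 * u0) / det
    d0[!active | is.na(d0)] <- 0
    d1[!active | is.na(d1)] <- 0
    # damp huge steps (quasi-separated SNPs) so the chunk stays finite
    big <- pmax(abs(d0), abs(d1))
    shrink <- ifelse(big > 5, 5 / big, 1)
    b0 <- b0 + d0 * shrink
    b1 <- b1 + d1 * shrink
    active <- active & (pmax(abs(d0), abs(d1)) > tol)
  }
  # final information for standard errors
  eta <- x * rep(b1, each = n) + rep(b0, each = n)
  mu <- plogis(eta)
  w <- mu * (1 - mu)
  i00 <- colSums(w); i01 <- colSums(x * w); i11 <- colSums(x * x * w)
  det <- i00 * i11 - i01 * i01
  se1 <- sqrt(ifelse(det > 0, i00 / det, NA))
  z <- b1 / se1
  p <- 2 * pnorm(-abs(z))
  beta <- b1; se_out <- se1

  # (quasi-)separated columns: the Wald statistic degenerates (Hauck-Donner),
  # so fall back to the null score test for p and a slope-ridge Newton fit
  # for a finite effect estimate
  bad <- !mono & (!is.finite(se_out) | se_out > 50 | abs(beta) > 8 | active)
  if (any(bad)) {
    ybar <- mean(y)
    for (j in which(bad)) {
      xj <- x[, j]
      u <- sum(xj * (y - ybar))
      v <- ybar * (1 - ybar) * sum((xj - mean(xj))^2)
      p[j] <- if (v > 0) 2 * pnorm(-abs(u / sqrt(v))) else 1
      rf <- ridge_logistic_1d(xj, y, lambda = 0.5)
      beta[j] <- rf$beta
      se_out[j] <- rf$se
    }
  }

  beta[mono] <- 0; se_out[mono] <- NA; p[mono | !is.finite(p)] <- 1
  list(beta = beta, se = se_out, p = p)
}

# single-SNP logistic fit with a ridge penalty on the slope only; keeps the
# effect estimate finite under separation
ridge_logistic_1d <- function(x, y, lambda = 0.5, max_iter = 50L) {
  b0 <- qlogis(mean(y)); b1 <- 0
  for (it in seq_len(max_iter)) {
    eta <- b0 + b1 * x
    mu <- plogis(eta); w <- mu * (1 - mu)
    u0 <- sum(y - mu); u1 <- sum(x * (y - mu)) - lambda * b1
    i00 <- sum(w); i01 <- sum(x * w); i11 <- sum(x * x * w) + lambda
    det <- i00 * i11 - i01^2
    if (det <= 0) break
    d0 <- (i11 * u0 - i01 * u1) / det
    d1 <- (i00 * u1 - i01 * u0) / det
    b0 <- b0 + d0; b1 <- b1 + d1
    if (max(abs(d0), abs(d1)) < 1e-10) break
  }
  eta <- b0 + b1 * x
  w <- plogis(eta) * (1 - plogis(eta))
  i00 <- sum(w); i01 <- sum(x * w); i11 <- sum(x * x * w) + lambda
  det <- i00 * i11 - i01^2
  list(beta = b1, se = if (det > 0) sqrt(i00 / det) else NA_real_)
}

#' Select SNPs by p-value thresholding
#'
#' Keeps SNPs with association p strictly below `p_threshold`, after applying
#' a minor-allele-frequency floor of `maf_floor` (frequencies folded to the
#' minor allele).
#'
#' @param sumstats Summary-statistics tibble from [run_gwas()] or
#'   [read_sumstats()].
#' @param p_threshold Strict upper bound on `p_value` (default 0.05).
#' @param maf_floor Minimum minor-allele frequency (default 0.01).
#' @return Character vector of surviving `snp_id`s (possibly empty), in input
#'   order.
#' @export
threshold_snps <- function(sumstats, p_threshold = 0.05, maf_floor = 0.01) {
  maf <- pmin(sumstats$allele_freq, 1 - sumstats$allele_freq)
  keep <- sumstats$p_value < p_threshold & maf >= maf_floor
  sumstats$snp_id[keep]
}
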