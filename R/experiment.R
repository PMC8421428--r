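#' Run the full simulation pipeline for one genetic architecture
#'
#' Chains the whole method end to end on synthetic data: simulate genotypes
#' and liability-threshold phenotypes, split off the discovery sample, run
#' the discovery GWAS, select SNPs by p-value thresholding then LD pruning,
#' score the target individuals, and cross-validate the Mondrian
#' cross-conformal predictor on the target sample (every target individual is
#' predicted exactly once by a model that never saw it).
#'
#' @param config An [architecture_config()].
#' @param p_threshold GWAS p-value cut for SNP inclusion (default 0.05).
#' @param r2_threshold LD pruning r-squared cut (default 0.1).
#' @param window_bp Pruning window in base pairs (default 100000).
#' @param step_bp Pruning window slide in base pairs (default 50).
#' @param n_folds Inner cross-conformal folds (default 5).
#' @param n_outer_folds Outer cross-validation folds (default 5).
#' @param alpha_grid Error-rate grid for the reliability curve.
#' @param bare_count Bare-count p-value convention?
#' @return A list of class `mccp_simulation`: `config`, `sumstats`,
#'   `snp_set` (selected snp_ids), `prs` (target scores), `curve` (a
#'   [reliability_curve()] whose `"predictions"` attribute holds the pooled
#'   per-individual p0/p1), and `target_data`.
#' @export
mccp_simulation_run <- function(config,
                                p_threshold = 0.05, r2_threshold = 0.1,
                                window_bp = 100000, step_bp = 50,
                                n_folds = 5, n_outer_folds = 5,
                                alpha_grid = seq(0.01, 0.5, by = 0.01),
                                bare_count = FALSE) {
  geno <- simulate_genotypes(config)
  pheno <- simulate_phenotypes(geno, config)
  split <- discovery_split(nrow(geno$dosages), config)

  sumstats <- run_gwas(geno, pheno, split$discovery)
  candidates <- threshold_snps(sumstats, p_threshold)
  if (length(candidates) == 0)
    abort("no SNPs passed the p-value threshold; cannot build a PRS")

  target_geno <- subset_individuals(geno, split$target)
  snp_set <- prune_snps(sumstats, target_geno, candidates,
                        r2_threshold = r2_threshold,
                        window_bp = window_bp, step_bp = step_bp)
  prs <- compute_prs(target_geno, sumstats, snp_set)

  target_data <- dplyr::bind_cols(
    pheno[split$target, c("individual_id", "status")],
    prs["score"]
  )

  curve <- reliability_curve(target_data, "status", "score",
                             n_outer_folds = n_outer_folds, n_folds = n_folds,
                             alpha_grid = alpha_grid, seed = config$seed,
                             bare_count = bare_count)

  structure(
    list(config = config, sumstats = sumstats, snp_set = snp_set,
         prs = prs, curve = curve, target_data = target_data),
    class = "mccp_simulation"
  )
}

#' @export
print.mccp_simulation <- function(x, ...) {
  cat("<mccp_simulation>\n")
  cat(sprintf("  architecture: h2 %.2g, polygenicity %.3g, prevalence %.2g\n",
              x$config$heritability, x$config$polygenicity, x$config$prevalence))
  cat(sprintf("  %d SNPs in PRS; %d target individuals (%d cases)\n",
              length(x$snp_set), nrow(x$target_data), sum(x$target_data$status)))
  invisible(x)
}

#' Benchmark architectures grid
#'
#' The heritability x polygenicity x prevalence triples of the simulation
#' benchmark: h2 in {0.3, 0.5, 0.8}, polygenicity in
#' {0.001, 0.01, 0.1, 0.2}, prevalence in {0.01, 0.05, 0.2}.
#'
#' @return A tibble with columns `heritability`, `polygenicity`, `prevalence`.
#' @export
architecture_grid <- function() {
  tidyr::expand_grid(
    heritability = c(0.3, 0.5, 0.8),
    polygenicity = c(0.001, 0.01, 0.1, 0.2),
    prevalence = c(0.01, 0.05, 0.2)
  )
}

#' Performance table across a grid of genetic architectures
#'
#' For each (heritability, polygenicity, prevalence) cell: simulate, run the
#' discovery GWAS on the configured proportion, build the PRS, cross-validate
#' the Mondrian cross-conformal predictor, and report predicted-subset AUC,
#' PPV and NPV (with 95% CIs) plus coverage at error rate `alpha`. Cells in
#' which no individual receives a singleton prediction report coverage 0 and
#' `NA` metrics with a reason code.
#'
#' @param grid Tibble with columns `heritability`, `polygenicity`,
#'   `prevalence` (default [architecture_grid()]).
#' @param base_config An [architecture_config()] supplying every other field
#'   (cohort size, SNP count, MAF spectrum, discovery proportion, seed); each
#'   cell gets a distinct seed derived from it.
#' @param alpha Error rate at which metrics are reported (default 0.05).
#' @param ... Passed to [mccp_simulation_run()] (thresholds, fold counts).
#' @return A tibble with one row per grid cell: the architecture columns,
#'   `auc`/`ppv`/`npv` with CI bounds, `coverage`, observed errors at
#'   `alpha`, and counts.
#' @export
run_table1_experiment <- function(grid = architecture_grid(),
                                  base_config = architecture_config(),
                                  alpha = 0.05, ...) {
  purrr::pmap_dfr(grid, function(heritability, polygenicity, prevalence) {
    cell_cfg <- architecture_config(
      n_individuals = base_config$n_individuals,
      m_snps = base_config$m_snps,
      polygenicity = polygenicity,
      heritability = heritability,
      prevalence = prevalence,
      maf_low = base_config$maf_low,
      maf_high = base_config$maf_high,
      ld_block_rho = base_config$ld_block_rho,
      ld_block_size = base_config$ld_block_size,
      snp_spacing_bp = base_config$snp_spacing_bp,
      discovery_proportion = base_config$discovery_proportion,
      seed = base_config$seed +
        7L * round(1000 * heritability) +
        13L * round(10000 * polygenicity) +
        29L * round(1000 * prevalence)
    )
    run <- mccp_simulation_run(cell_cfg, alpha_grid = alpha, ...)
    preds <- attr(run$curve, "predictions")
    reg <- prediction_region(preds, alpha)
    m <- stratified_metrics(reg, "status", "score")
    dplyr::bind_cols(
      tibble(heritability = heritability, polygenicity = polygenicity,
             prevalence = prevalence, alpha = alpha,
             n_snps_prs = length(run$snp_set),
             observed_error_case = observed_error_mccp(preds, preds$status, alpha, "case"),
             observed_error_control = observed_error_mccp(preds, preds$status, alpha, "control")),
      m
    )
  })
}
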