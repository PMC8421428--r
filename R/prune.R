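#' LD-prune SNPs within sliding windows
#'
#' Greedy sliding-window pruning of correlated SNPs, computed on the supplied
#' genotypes (in simulation the target sample stands in for an external LD
#' reference panel). Windows of `window_bp` base pairs slide along each
#' chromosome in steps of `step_bp` (window starts snapped to the step grid;
#' consecutive windows containing the same SNPs are processed once). Within a
#' window, while any surviving pair has squared Pearson correlation at or
#' above `r2_threshold`, the pair with the largest r-squared (ties broken by
#' index order) loses one member:
#'
#' * `mode = "min-p"` (default, clumping-like): the member with the larger
#'   association p is removed; p ties go to the larger position.
#' * `mode = "keep-first"` (PLINK `--indep-pairwise`-like, p-blind): the
#'   member appearing later in the window is removed.
#'
#' @param sumstats Summary statistics covering `snp_ids` (needed for
#'   `mode = "min-p"`).
#' @param genotypes [genotype_data()] supplying the dosages for r-squared.
#' @param snp_ids Candidate SNP ids (typically the [threshold_snps()]
#'   survivors); defaults to every SNP in `sumstats`.
#' @param r2_threshold Pairwise r-squared above which one SNP is removed;
#'   must lie in (0, 1). Default 0.1.
#' @param window_bp Window size in base pairs (default 100000).
#' @param step_bp Window slide in base pairs (default 50).
#' @param step_variants If non-`NULL`, slide by this many variants instead of
#'   by base pairs.
#' @param mode Removal rule, `"min-p"` or `"keep-first"`.
#' @return Character vector of surviving snp_ids, original order preserved.
#' @examples
#' cfg <- architecture_config(n_individuals = 200, m_snps = 60, seed = 5,
#'                            ld_block_rho = 0.9, ld_block_size = 10)
#' g <- simulate_genotypes(cfg)
#' ph <- simulate_phenotypes(g, cfg)
#' ss <- run_gwas(g, ph, seq_len(100))
#' kept <- prune_snps(ss, g, r2_threshold = 0.2)
#' @export
prune_snps <- function(sumstats, genotypes, snp_ids = sumstats$snp_id,
                       r2_threshold = 0.1, window_bp = 100000,
                       step_bp = 50, step_variants = NULL,
                       mode = c("min-p", "keep-first")) {
  mode <- match.arg(mode)
  if (r2_threshold <= 0 || r2_threshold >= 1)
    abort("r2_threshold must be in (0, 1)", class = "mondrianprs_parameter_error")
  if (length(snp_ids) == 0) return(character(0))

  meta <- genotypes$snps
  sel <- match(snp_ids, meta$snp_id)
  if (anyNA(sel)) abort("snp_ids absent from genotypes")
  pv <- sumstats$p_value[match(snp_ids, sumstats$snp_id)]
  if (mode == "min-p" && anyNA(pv))
    abort("sumstats lack p-values for some candidate SNPs")

  ord <- order(meta$chromosome[sel], meta$position[sel])
  # work in position order per chromosome; restore input order at the end
  alive_global <- rep(TRUE, length(snp_ids))

  for (chr in unique(meta$chromosome[sel])) {
    on_chr <- which(meta$chromosome[sel] == chr)
    on_chr <- on_chr[order(meta$position[sel][on_chr])]
    pos <- meta$position[sel][on_chr]
    p_here <- pv[on_chr]
    k <- length(on_chr)
    if (k < 2) next
    x <- genotypes$dosages[, sel[on_chr], drop = FALSE]
    storage.mode(x) <- "double"
    alive <- rep(TRUE, k)

    if (is.null(step_variants)) {
      starts <- seq(pos[1], pos[k], by = max(1, step_bp))
      lo <- findInterval(starts - 0.5, pos) + 1L
      hi <- findInterval(starts + window_bp - 0.5, pos)
      keep_win <- c(TRUE, diff(lo) != 0 | diff(hi) != 0)
      wins <- cbind(lo, hi)[keep_win & lo <= hi, , drop = FALSE]
    } else {
      sv <- max(1L, as.integer(step_variants))
      lo <- seq(1L, k, by = sv)
      hi <- vapply(lo, function(l) findInterval(pos[l] + window_bp - 0.5, pos), 1L)
      wins <- cbind(lo, hi)
    }

    for (w in seq_len(nrow(wins))) {
      idx <- wins[w, 1]:wins[w, 2]
      idx <- idx[alive[idx]]
      if (length(idx) < 2) next
      r2 <- cor(x[, idx, drop = FALSE])^2
      diag(r2) <- 0
      while (TRUE) {
        mx <- max(r2)
        if (is.na(mx) || mx < r2_threshold) break
        hit <- which(r2 == mx, arr.ind = TRUE)[1, ] # first pair in index order
        a <- min(hit); b <- max(hit)
        drop_local <- if (mode == "keep-first") {
          b
        } else {
          pa <- p_here[idx[a]]; pb <- p_here[idx[b]]
          if (pa > pb) a else if (pb > pa) b else b # p tie: larger position
        }
        r2[drop_local, ] <- 0; r2[, drop_local] <- 0
        alive[idx[drop_local]] <- FALSE
      }
    }
    alive_global[on_chr] <- alive
  }
  snp_ids[alive_global]
}
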