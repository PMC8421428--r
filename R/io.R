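# Readers and writers for the plain-text formats the pipeline speaks:
# dosage matrices (TSV), PLINK "raw" exports, VCF (GT -> alt-allele dosage),
# GWAS summary statistics, and phenotype/covariate tables.
# Coordinates are 1-based inclusive everywhere (VCF/PLINK convention).

.sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read GWAS summary statistics
#'
#' Delimited text (tab or comma, sniffed from the header line) with one row
#' per SNP. Column names are configurable through `col_map`; an odds-ratio
#' column may be supplied instead of `beta` and is log-transformed. Duplicate
#' SNP ids are rejected.
#'
#' @param path File path.
#' @param col_map Named list mapping the canonical names `snp_id`,
#'   `effect_allele`, `other_allele`, `beta` (or `or`), `se`, `p_value`,
#'   `allele_freq` to the file's column names. Defaults: SNP, A1, A2, BETA,
#'   SE, P, FRQ.
#' @return A summary-statistics tibble as produced by [run_gwas()].
#' @export
read_sumstats <- function(path, col_map = list()) {
  map <- modifyList(
    list(snp_id = "SNP", effect_allele = "A1", other_allele = "A2",
         beta = "BETA", or = "OR", se = "SE", p_value = "P",
         allele_freq = "FRQ"),
    col_map
  )
  raw <- readr::read_delim(path, delim = .sniff_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  get <- function(nm) if (map[[nm]] %in% names(raw)) raw[[map[[nm]]]] else NULL
  beta <- get("beta")
  if (is.null(beta)) {
    or <- get("or")
    if (is.null(or)) abort("sumstats need a BETA or OR column")
    beta <- log(or)
  }
  out <- tibble(
    snp_id = as.character(get("snp_id") %||% abort("missing SNP id column")),
    effect_allele = as.character(get("effect_allele") %||% "A"),
    other_allele = as.character(get("other_allele") %||% "B"),
    beta = as.numeric(beta),
    se = as.numeric(get("se") %||% NA_real_),
    p_value = as.numeric(get("p_value") %||% NA_real_),
    allele_freq = as.numeric(get("allele_freq") %||% NA_real_)
  )
  dup <- duplicated(out$snp_id)
  if (any(dup))
    abort(sprintf("duplicate snp_id(s) in sumstats: %s",
                  paste(head(unique(out$snp_id[dup]), 5), collapse = ", ")))
  bad_p <- !is.na(out$p_value) & (out$p_value <= 0 | out$p_value > 1)
  if (any(bad_p)) abort("p_value outside (0, 1] in sumstats")
  out
}

#' Write GWAS summary statistics
#' @param sumstats Tibble from [run_gwas()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(sumstats, path) {
  out <- sumstats
  names(out) <- c("SNP", "A1", "A2", "BETA", "SE", "P", "FRQ")[seq_along(out)]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write genotypes as a dosage matrix or PLINK raw file
#'
#' `"dosage-tsv"`: first column `individual_id`, then one column per SNP
#' (header = snp_id) holding counted-allele dosages. A companion
#' `<path>.snps.tsv` stores the SNP metadata so a round-trip preserves
#' coordinates and alleles. `"plink-raw"`: the PLINK `--recode A` dialect
#' (FID IID PAT MAT SEX PHENOTYPE, then `<snp_id>_<allele1>` columns).
#'
#' @param genotypes A [genotype_data()].
#' @param path Output path.
#' @param format `"dosage-tsv"` or `"plink-raw"`.
#' @param phenotype Optional 1/0 status vector for the PLINK PHENOTYPE column
#'   (written as 2 = case, 1 = control).
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path,
                            format = c("dosage-tsv", "plink-raw"),
                            phenotype = NULL) {
  format <- match.arg(format)
  dos <- genotypes$dosages
  if (format == "dosage-tsv") {
    df <- as_tibble(as.data.frame(dos))
    names(df) <- genotypes$snps$snp_id
    df <- dplyr::bind_cols(tibble(individual_id = rownames(dos)), df)
    readr::write_tsv(df, path, progress = FALSE)
    readr::write_tsv(genotypes$snps, paste0(path, ".snps.tsv"), progress = FALSE)
  } else {
    df <- as_tibble(as.data.frame(dos))
    names(df) <- paste0(genotypes$snps$snp_id, "_", genotypes$snps$allele1)
    lead <- tibble(
      FID = rownames(dos), IID = rownames(dos),
      PAT = 0L, MAT = 0L, SEX = 0L,
      PHENOTYPE = if (is.null(phenotype)) -9L else as.integer(phenotype) + 1L
    )
    readr::write_delim(dplyr::bind_cols(lead, df), path, delim = " ",
                       progress = FALSE)
  }
  invisible(path)
}

#' Read genotypes from dosage TSV, PLINK raw, or VCF
#'
#' All formats yield a [genotype_data()] with dosages in \[0, 2\]. VCF GT
#' fields are converted to alt-allele counts (`0/1` -> 1, `1/1` -> 2, `./.`
#' missing). Missing genotypes are mean-imputed per SNP (count reported via a
#' message); SNPs with more than `max_missing` missingness are dropped with a
#' warning. For `"dosage-tsv"`, SNP metadata is taken from the companion
#' `<path>.snps.tsv` when present, otherwise synthesized (chromosome 1,
#' 1-kb-spaced positions, alleles A/B, empirical frequencies).
#'
#' @param path File path.
#' @param format `"dosage-tsv"`, `"plink-raw"` or `"vcf"`.
#' @param max_missing Per-SNP missingness above which the SNP is dropped
#'   (default 0.1).
#' @return A [genotype_data()].
#' @export
read_genotypes <- function(path, format = c("dosage-tsv", "plink-raw", "vcf"),
                           max_missing = 0.1) {
  format <- match.arg(format)
  if (format == "vcf") return(read_genotypes_vcf(path, max_missing))

  if (format == "dosage-tsv") {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    ids <- as.character(raw[[1]])
    dos <- as.matrix(raw[, -1, drop = FALSE])
    snp_ids <- colnames(dos)
    meta_path <- paste0(path, ".snps.tsv")
    if (file.exists(meta_path)) {
      snps <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
      snps <- snps[match(snp_ids, snps$snp_id), ]
    } else {
      snps <- tibble(
        snp_id = snp_ids, chromosome = "1",
        position = seq_along(snp_ids) * 1000L,
        allele_freq = colMeans(dos, na.rm = TRUE) / 2,
        allele1 = "A", allele2 = "B"
      )
    }
  } else { # plink-raw
    raw <- readr::read_delim(path, delim = " ", show_col_types = FALSE,
                             progress = FALSE, na = c("NA", ""))
    ids <- as.character(raw$IID)
    dos <- as.matrix(raw[, -(1:6), drop = FALSE])
    parts <- regmatches(colnames(dos), regexpr("_[^_]+$", colnames(dos)))
    snp_ids <- sub("_[^_]+$", "", colnames(dos))
    counted <- sub("^_", "", parts)
    snps <- tibble(
      snp_id = snp_ids, chromosome = "1",
      position = seq_along(snp_ids) * 1000L,
      allele_freq = colMeans(dos, na.rm = TRUE) / 2,
      allele1 = counted, allele2 = "B"
    )
    snps$allele2[snps$allele2 == snps$allele1] <- "A"
  }

  finalize_genotypes(dos, ids, snps, max_missing, basename(path))
}

read_genotypes_vcf <- function(path, max_missing) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT") # SNPs x samples
  # count alt alleles; either separator, missing as NA
  count_alt <- function(g) {
    out <- vapply(strsplit(g, "[/|]"),
                  function(a) sum(a == "1"), numeric(1))
    out[is.na(g) | grepl("\\.", g)] <- NA_real_
    out
  }
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  for (j in seq_len(nrow(gt))) dos[, j] <- count_alt(gt[j, ])
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  snps <- tibble(
    snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste0(fix$CHROM, ":", fix$POS), fix$ID),
    chromosome = fix$CHROM,
    position = as.integer(fix$POS),
    allele_freq = NA_real_,
    allele1 = fix$ALT, # dosage counts ALT
    allele2 = fix$REF
  )
  finalize_genotypes(dos, rownames(dos), snps, max_missing, basename(path))
}

finalize_genotypes <- function(dos, ids, snps, max_missing, label) {
  storage.mode(dos) <- "double"
  miss_frac <- colMeans(is.na(dos))
  drop <- miss_frac > max_missing
  if (any(drop)) {
    warn(sprintf("%s: dropping %d SNP(s) with > %.0f%% missing genotypes",
                 label, sum(drop), 100 * max_missing))
    dos <- dos[, !drop, drop = FALSE]
    snps <- snps[!drop, ]
  }
  n_missing <- sum(is.na(dos))
  if (n_missing > 0) {
    inform(sprintf("%s: mean-imputing %d missing genotype(s)", label, n_missing))
    for (j in which(colSums(is.na(dos)) > 0)) {
      dos[is.na(dos[, j]), j] <- mean(dos[, j], na.rm = TRUE)
    }
  }
  if (anyNA(snps$allele_freq)) snps$allele_freq <- colMeans(dos) / 2
  rownames(dos) <- ids
  genotype_data(dos, snps)
}

#' Read a phenotype / covariate table
#'
#' Delimited text with a header; must contain an individual-id column and the
#' status column (values coerced to 1 case / 0 control; case/control and
#' PLINK 2/1 codings accepted).
#'
#' @param path File path.
#' @param id_col,status_col Column names (defaults `individual_id`, `status`).
#' @return A tibble with `individual_id`, `status` first, remaining columns
#'   (covariates) unchanged.
#' @export
read_phenotypes <- function(path, id_col = "individual_id",
                            status_col = "status") {
  raw <- readr::read_delim(path, delim = .sniff_delim(path),
                           show_col_types = FALSE, progress = FALSE)
  if (!id_col %in% names(raw)) abort(sprintf("missing id column '%s'", id_col))
  if (!status_col %in% names(raw))
    abort(sprintf("missing status column '%s'", status_col))
  st <- raw[[status_col]]
  status <- dplyr::case_when(
    st %in% c(1, "1", "case") ~ 1L,
    st %in% c(0, "0", "control") ~ 0L,
    st %in% c(2, "2") ~ 1L, # PLINK 2/1 coding
    TRUE ~ NA_integer_
  )
  if (anyNA(status)) abort("unrecognized status values in phenotype table")
  out <- tibble(individual_id = as.character(raw[[id_col]]), status = status)
  covars <- setdiff(names(raw), c(id_col, status_col))
  dplyr::bind_cols(out, raw[, covars, drop = FALSE])
}

# small stable polynomial hash over a serialized object; stamps outputs so
# mismatched inputs are detectable before compute
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the whole pipeline and write its artifacts
#'
#' Executes simulate -> GWAS -> PRS -> cross-conformal calibration ->
#' prediction -> evaluation on a synthetic cohort and writes every artifact
#' to `out_dir`: `sumstats.tsv`, `prs.tsv`, `predictions.tsv` (per-individual
#' p0/p1, confidence, credibility, outcome at each requested alpha),
#' `reliability.tsv`, `evaluation.tsv`, and `manifest.json` recording the
#' seed, every threshold, and a config hash. Runs with equal configs are
#' byte-identical.
#'
#' @param config An [architecture_config()].
#' @param out_dir Output directory (created if needed).
#' @param alphas Error rates at which per-individual outcomes are emitted.
#' @param ... Passed to [mccp_simulation_run()].
#' @return The [mccp_simulation_run()] result, invisibly.
#' @export
end_to_end <- function(config, out_dir, alphas = 0.05, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- mccp_simulation_run(config, ...)
  preds <- attr(run$curve, "predictions")

  write_sumstats(run$sumstats, file.path(out_dir, "sumstats.tsv"))
  readr::write_tsv(run$prs, file.path(out_dir, "prs.tsv"), progress = FALSE)

  pred_tabs <- purrr::map_dfr(alphas, function(a) prediction_region(preds, a))
  readr::write_tsv(pred_tabs, file.path(out_dir, "predictions.tsv"),
                   progress = FALSE)
  readr::write_tsv(as_tibble(run$curve), file.path(out_dir, "reliability.tsv"),
                   progress = FALSE)
  readr::write_tsv(evaluation_report(preds, alpha_grid = alphas),
                   file.path(out_dir, "evaluation.tsv"), progress = FALSE)

  manifest <- list(
    package = "mondrianprs",
    version = as.character(utils::packageVersion("mondrianprs")),
    config = unclass(config),
    config_hash = config_hash(unclass(config)),
    alphas = alphas,
    n_snps_prs = length(run$snp_set),
    created = "run manifest"
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(run)
}
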