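# Independent brute-force oracles used across the suite. These deliberately
# use naive loops / direct transcriptions of the definitions, never the
# package's own vectorized code paths.

# O(N^2) conformal p-value: count calibration scores >= test score
bf_conformal_p <- function(cal_ncms, test_ncm, c = 1) {
  cnt <- 0
  for (s in cal_ncms) if (s >= test_ncm) cnt <- cnt + 1
  (cnt + c) / (length(cal_ncms) + 1)
}

# all-pairs Mann-Whitney concordance AUC (ties count 1/2)
bf_auc <- function(y, score) {
  cases <- score[y == 1]; controls <- score[y == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cases) * length(controls))
}

# exhaustive greedy pruning on one window: repeatedly find the pair with the
# highest r2 at or above the threshold, drop its larger-p member (p ties:
# larger position)
bf_prune <- function(dosages, p_values, positions, r2_threshold) {
  alive <- rep(TRUE, ncol(dosages))
  repeat {
    idx <- which(alive)
    if (length(idx) < 2) break
    best <- NULL; best_r2 <- -Inf
    for (ii in seq_along(idx)) {
      for (jj in seq_along(idx)) {
        if (jj <= ii) next
        r2 <- cor(dosages[, idx[ii]], dosages[, idx[jj]])^2
        if (is.finite(r2) && r2 > best_r2) {
          best_r2 <- r2; best <- c(idx[ii], idx[jj])
        }
      }
    }
    if (best_r2 < r2_threshold) break
    pa <- p_values[best[1]]; pb <- p_values[best[2]]
    drop <- if (pa > pb) best[1]
    else if (pb > pa) best[2]
    else best[which.max(positions[best])]
    alive[drop] <- FALSE
  }
  which(alive)
}

# literal transcription of the naive-classifier observed-error rule
bf_observed_error_lr <- function(prob, y, alpha) {
  n_err <- 0
  for (i in seq_along(y)) {
    if (y[i] == 0 && prob[i] > (1 - alpha)) n_err <- n_err + 1
    else if (y[i] == 1 && prob[i] < alpha) n_err <- n_err + 1
  }
  n_err / length(y)
}

# genotype container built directly from a dosage matrix (for hand-crafted
# oracle instances)
make_geno <- function(dosages, positions = seq_len(ncol(dosages)) * 1000,
                      chromosome = "1") {
  m <- ncol(dosages)
  genotype_data(
    dosages,
    tibble::tibble(
      snp_id = sprintf("s%03d", seq_len(m)),
      chromosome = chromosome,
      position = positions,
      allele_freq = colMeans(dosages) / 2,
      allele1 = "A", allele2 = "B"
    )
  )
}
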