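test_that("invalid architecture parameters are rejected with the field named", {
  expect_error(architecture_config(polygenicity = 0), "polygenicity")
  expect_error(architecture_config(m_snps = 100, polygenicity = 0.001),
               "polygenicity")
  expect_error(architecture_config(heritability = 1), "heritability")
  expect_error(architecture_config(prevalence = 0), "prevalence")
  expect_error(architecture_config(maf_low = 0.001), "maf_low")
  expect_error(architecture_config(maf_low = 0.4, maf_high = 0.2), "maf_high")
  expect_error(architecture_config(ld_block_rho = 1), "ld_block_rho")
  expect_error(architecture_config(discovery_proportion = 1), "discovery")
})

test_that("genotype simulation is deterministic and respects forced MAF", {
  cfg <- architecture_config(n_individuals = 400, m_snps = 60, polygenicity = 0.1,
                             maf_low = 0.5, maf_high = 0.5, seed = 11)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosages, g2$dosages)
  expect_true(all(g1$snps$allele_freq == 0.5))
  # at frequency 0.5 the mean dosage is 1 up to binomial noise
  expect_equal(mean(g1$dosages), 1,
               tolerance = 3 * sqrt(0.5 / (400 * 60)) / 1)
  expect_true(all(g1$dosages %in% 0:2))
})

test_that("linkage-equilibrium genotypes have near-null pairwise r2", {
  cfg <- architecture_config(n_individuals = 300, m_snps = 40,
                             polygenicity = 0.1, seed = 3)
  g <- simulate_genotypes(cfg)
  r2 <- cor(g$dosages)^2
  off <- r2[upper.tri(r2)]
  # oracle: E[r2] between independent variables at sample size n is 1/(n-1)
  expect_gt(mean(off), 0.5 / 299)
  expect_lt(mean(off), 2 / 299)
})

test_that("block LD induces distance-decaying correlation", {
  cfg <- architecture_config(n_individuals = 800, m_snps = 60,
                             polygenicity = 0.1, seed = 9,
                             ld_block_rho = 0.9, ld_block_size = 20)
  g <- simulate_genotypes(cfg)
  r2 <- cor(g$dosages)^2
  adjacent <- mean(r2[cbind(1:19, 2:20)])
  distant <- mean(r2[cbind(1:10, 11:20)])
  expect_gt(adjacent, 0.3)
  expect_gt(adjacent, 3 * distant)
  # marginal frequencies are preserved despite the latent correlation
  expect_equal(unname(colMeans(g$dosages)) / 2, g$snps$allele_freq,
               tolerance = 0.08)
})

test_that("null heritability gives zero genetic values and prevalence ~ K", {
  cfg <- architecture_config(n_individuals = 10000, m_snps = 50,
                             polygenicity = 0.1, heritability = 0,
                             prevalence = 0.05, seed = 21)
  ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  expect_true(all(ph$genetic_value == 0))
  # binomial oracle: 3 SDs around K
  expect_lt(abs(mean(ph$status) - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("liability model recovers h2, unit variance and the threshold rule", {
  cfg <- architecture_config(n_individuals = 10000, m_snps = 500,
                             polygenicity = 0.2, heritability = 0.5,
                             prevalence = 0.05, seed = 8)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  expect_equal(var(ph$genetic_value), 0.5, tolerance = 1e-10) # exact by calibration
  expect_equal(var(ph$liability), 1, tolerance = 0.05)
  fit <- lm(ph$liability ~ ph$genetic_value)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
  expect_equal(summary(fit)$r.squared, 0.5, tolerance = 0.03)
  expect_identical(ph$status, as.integer(ph$liability > qnorm(0.95)))
  expect_lt(abs(mean(ph$status) - 0.05), 3 * sqrt(0.05 * 0.95 / 10000))
})

test_that("phenotype simulation is deterministic and errors without causals", {
  cfg <- architecture_config(n_individuals = 100, m_snps = 40,
                             polygenicity = 0.1, seed = 4)
  g <- simulate_genotypes(cfg)
  expect_identical(simulate_phenotypes(g, cfg), simulate_phenotypes(g, cfg))
})

test_that("discovery split is a deterministic partition", {
  cfg <- architecture_config(n_individuals = 100, m_snps = 10,
                             polygenicity = 0.2, seed = 2,
                             discovery_proportion = 0.3)
  s1 <- discovery_split(100, cfg)
  s2 <- discovery_split(100, cfg)
  expect_identical(s1, s2)
  expect_length(s1$discovery, 30)
  expect_setequal(c(s1$discovery, s1$target), 1:100)
})
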