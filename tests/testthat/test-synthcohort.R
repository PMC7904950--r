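# Synthetic-cohort generator: determinism, Hardy-Weinberg frequencies,
# LD induction, the variance decomposition, and causal-regime structure.

test_that("genotype simulation is bit-reproducible and respects allele frequencies", {
  specs <- variant_specs(5, seed = 7)
  g1 <- simulate_genotypes(50, specs, seed = 11)
  g2 <- simulate_genotypes(50, specs, seed = 11)
  expect_identical(g1$dosages, g2$dosages)
  expect_true(all(g1$dosages %in% c(0, 1, 2)))

  # empirical allele frequency vs the Binomial(2, maf) expectation
  spec03 <- data.frame(variant_id = "v1", chrom = "1", pos = 100L,
                       effect_allele = "A", other_allele = "G", maf = 0.3)
  g <- simulate_genotypes(20000, spec03, seed = 3)
  expect_lt(abs(mean(g$dosages[, 1]) / 2 - 0.3), 0.01)
})

test_that("palindromic variants are generated like any other", {
  spec_pal <- data.frame(variant_id = "pal1", chrom = "1", pos = 5L,
                         effect_allele = "A", other_allele = "T", maf = 0.5)
  g <- simulate_genotypes(200, spec_pal, seed = 1)
  expect_equal(dim(g$dosages), c(200L, 1L))
})

test_that("LD blocks induce the requested pairwise dosage correlation", {
  specs <- variant_specs(3, seed = 2)
  g <- simulate_genotypes(
    20000, specs, seed = 5,
    ld_blocks = list(list(variants = c("rs1", "rs2"), r2 = 0.5)))
  r2 <- cor(g$dosages[, "rs1"], g$dosages[, "rs2"])^2
  expect_lt(abs(r2 - 0.5), 0.05)
  # variant outside the block stays uncorrelated
  expect_lt(cor(g$dosages[, "rs1"], g$dosages[, "rs3"])^2, 0.01)
})

test_that("generator inputs are validated", {
  bad_maf <- data.frame(variant_id = "v", chrom = "1", pos = 1L,
                        effect_allele = "A", other_allele = "G", maf = 0.7)
  expect_error(simulate_genotypes(10, bad_maf, seed = 1), "maf")
  dup <- variant_specs(2, seed = 1)
  dup$variant_id <- c("a", "a")
  expect_error(simulate_genotypes(10, dup, seed = 1), "duplicate")
  expect_error(sim_config(amplification_k = 0.5), "amplification_k")
  expect_error(sim_config(noise_sd_bmi = 0), "noise")
  reg <- default_regimes(1)
  reg$regime[1] <- "unknown_regime"
  expect_error(sim_config(regimes = reg), "unknown regime")
  reg2 <- default_regimes(1)
  reg2$alpha[1] <- NA
  expect_error(sim_config(regimes = reg2), "missing effect sizes")
})

test_that("the score slope calibrated for a target R2 achieves it empirically", {
  cfg0 <- sim_config(n_samples = 10000, amplification_k = 1, seed = 21)
  cfg <- sim_config(n_samples = 10000, amplification_k = 1, seed = 21,
                    beta_gps = gps_slope_for_r2(0.25, cfg0))
  specs <- variant_specs(116, seed = 21)
  geno <- simulate_genotypes(10000, specs, seed = 22)
  co <- simulate_traits(geno, cfg)
  r2 <- summary(lm(co$phenotypes$bmi ~ co$score_true))$r.squared
  expect_lt(abs(r2 - 0.25), 0.02)
})

test_that("the bmi-to-protein regime generates the stated protein-on-BMI slope", {
  # protein = alpha * z(BMI) + noise (delta = 0 isolates the direct edge);
  # the standardized-protein slope is alpha / sqrt(alpha^2 + 1)
  alpha <- 0.10
  reg <- data.frame(protein_id = "p1", regime = "bmi_to_protein",
                    alpha = alpha, theta = 0, delta = 0)
  est <- vapply(1:200, function(s) {
    cc <- make_cohort(n = 5000, seed = s, k = 1, n_score = 10, regimes = reg)
    sc <- association_scan(preprocess_proteins(cc$cohort$proteins),
                           cc$cohort$phenotypes$bmi,
                           cc$cohort$phenotypes[, c("age", "sex")])
    sc$beta
  }, numeric(1))
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - alpha / sqrt(alpha^2 + 1)), 3 * mc_se)
})

test_that("confounded-null proteins show biased OLS despite a null causal effect", {
  cc <- make_cohort(n = 5000, seed = 31)
  truth <- cc$cohort$truth
  pid <- truth$protein_id[truth$regime == "confounded_null"][1]
  expect_equal(truth$alpha[truth$protein_id == pid], 0)
  expect_equal(truth$theta[truth$protein_id == pid], 0)
  sc <- association_scan(
    preprocess_proteins(cc$cohort$proteins)[, pid, drop = FALSE],
    cc$cohort$phenotypes$bmi, cc$cohort$phenotypes[, c("age", "sex")])
  expect_gt(abs(sc$beta) / sc$se, 5)
})

test_that("a global-null configuration yields uniform scan p-values", {
  reg <- default_regimes(5, alpha = 0, theta = 0, delta = 0)
  cc <- make_cohort(n = 600, seed = 41, k = 1, n_score = 10, regimes = reg,
                    beta_gps = 0, confound_bmi = 0, confound_protein = 0)
  sc <- association_scan(preprocess_proteins(cc$cohort$proteins),
                         cc$cohort$phenotypes$bmi,
                         cc$cohort$phenotypes[, c("age", "sex")])
  expect_gt(min(sc$p), 0.05 / 1000) # no spurious strong hit
  expect_true(all(sc$p <= 1) && all(sc$p > 0))
})

test_that("confounder catalogs plant exactly the requested associations", {
  specs <- variant_specs(6, seed = 2)
  geno <- simulate_genotypes(20, specs, seed = 2)
  cat0 <- make_confounder_catalog(geno, c("smoking", "education"), seed = 3)
  expect_equal(sum(cat0$p < 1e-8), 0L)
  cat3 <- make_confounder_catalog(geno, "smoking", seed = 3,
                                  planted = c("rs1", "rs3", "rs5"))
  expect_setequal(cat3$variant_id[cat3$p < 1e-8], c("rs1", "rs3", "rs5"))
  # round-trip through disk preserves content
  path <- tempfile(fileext = ".tsv")
  write.table(cat3, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back$p, cat3$p, tolerance = 1e-12)
  expect_equal(back$variant_id, cat3$variant_id)
})
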