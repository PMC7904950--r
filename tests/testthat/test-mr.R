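# Mendelian randomization: instrument selection, harmonization, the four
# estimators against independent oracles, and the bidirectional report.

test_that("instrument selection applies significance, strength, confounder and LD rules", {
  stats_df <- data.frame(
    variant_id = c("rs1", "rs2", "rs3", "rs4"),
    chrom = "1", pos = c(1e6, 1.5e6, 50e6, 80e6),
    effect_allele = "A", other_allele = "G",
    beta = c(0.10, 0.08, 0.09, 0.001),
    se = c(0.010, 0.010, 0.010, 0.010),
    p = c(1e-12, 1e-9, 1e-10, 0.9))
  specs <- variant_specs(4, seed = 1)
  specs$pos <- c(1e6, 1.5e6, 50e6, 80e6)
  ld <- simulate_genotypes(5000, specs, seed = 2,
                           ld_blocks = list(list(variants = c("rs1", "rs2"),
                                                 r2 = 0.5)))
  sel <- select_instruments(stats_df, ld_reference = ld)
  # rs4 is weak; rs2 is clumped away by the stronger rs1 (r2 = 0.5 >> 0.001)
  expect_setequal(sel$instruments$variant_id, c("rs1", "rs3"))
  expect_true("ld_clumped" %in% sel$removed$reason[sel$removed$variant_id == "rs2"])
  expect_true(all(sel$instruments$f_stat > 10))

  # a sub-threshold confounder association removes the SNP with that reason
  conf <- data.frame(variant_id = "rs3", trait = "education", p = 5e-9)
  sel2 <- select_instruments(stats_df, ld_reference = ld, confounders = conf)
  expect_false("rs3" %in% sel2$instruments$variant_id)
  expect_equal(sel2$removed$reason[sel2$removed$variant_id == "rs3"], "confounder")

  # an empty result is a typed outcome, not an error
  none <- select_instruments(stats_df[4, ], ld_reference = ld)
  expect_equal(none$status, "no_instruments")
  expect_equal(nrow(none$instruments), 0L)
})

test_that("summary-statistic harmonization aligns alleles and drops ambiguity", {
  ex <- data.frame(variant_id = c("rs1", "rs2", "rs3", "rs4"),
                   effect_allele = c("A", "A", "A", "A"),
                   other_allele = c("G", "T", "G", "G"),
                   beta = c(0.1, 0.1, 0.1, 0.1), se = 0.01, p = 1e-10)
  ou <- data.frame(variant_id = c("rs1", "rs2", "rs3", "rs4"),
                   effect_allele = c("G", "A", "A", "C"),
                   other_allele = c("A", "T", "G", "T"),
                   beta = c(0.05, 0.05, 0.05, 0.05), se = 0.02)
  h <- harmonize_summary_stats(ex, ou)
  # rs1 swapped -> negated; rs2 palindromic -> dropped; rs3 identical ->
  # unchanged; rs4 alleles irreconcilable -> dropped
  expect_equal(h$instruments$variant_id, c("rs1", "rs3"))
  expect_equal(h$instruments$beta_outcome, c(-0.05, 0.05))
  expect_setequal(h$dropped$reason, c("palindromic", "allele_mismatch"))
})

test_that("Wald ratio arithmetic and edge cases", {
  w <- wald_ratio(0.5, 0.01, 0.25, 0.05)
  expect_equal(w$beta, 0.5)
  expect_equal(wald_ratio(2, 0.01, 0.1, 0.1)$se, 0.05)
  z <- wald_ratio(0.5, 0.01, 0, 0.05)
  expect_equal(z$beta, 0)
  expect_equal(z$p, 1)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.05), "null instrument")
})

test_that("IVW reduces to the Wald ratio for one SNP and matches the WLS oracle", {
  one <- simulate_mr_summary(1, 0.3, seed = 1)
  expect_equal(ivw(one)$beta,
               wald_ratio(one$beta_exposure, one$se_exposure,
                          one$beta_outcome, one$se_outcome)$beta)
  expect_equal(ivw(one)$se, one$se_outcome / abs(one$beta_exposure))

  # identical per-SNP ratios: beta = the shared ratio and Q = 0
  d <- data.frame(beta_exposure = c(0.1, 0.2, 0.4),
                  se_exposure = 0.01,
                  beta_outcome = 0.7 * c(0.1, 0.2, 0.4),
                  se_outcome = c(0.02, 0.05, 0.03))
  fit <- ivw(d)
  expect_equal(fit$beta, 0.7, tolerance = 1e-12)
  expect_equal(fit$q_stat, 0, tolerance = 1e-12)

  d8 <- simulate_mr_summary(8, 0.4, seed = 2)
  o <- wls_origin_oracle(d8$beta_exposure, d8$beta_outcome, 1 / d8$se_outcome^2)
  fit8 <- ivw(d8)
  expect_equal(fit8$beta, o$beta, tolerance = 1e-10)
  expect_equal(fit8$se, o$se, tolerance = 1e-10)

  # order invariance and joint sign-flip invariance
  perm <- d8[sample(8), ]
  expect_equal(ivw(perm)$beta, fit8$beta, tolerance = 1e-12)
  expect_equal(ivw(perm)$q_stat, fit8$q_stat, tolerance = 1e-10)
  flip <- d8
  flip$beta_exposure[1:3] <- -flip$beta_exposure[1:3]
  flip$beta_outcome[1:3] <- -flip$beta_outcome[1:3]
  expect_equal(ivw(flip)$beta, fit8$beta, tolerance = 1e-12)

  expect_equal(ivw(NULL)$status, "no_instruments")
})

test_that("MR-Egger recovers exact fits and matches the weighted oracle", {
  bx <- c(0.05, 0.1, 0.15, 0.2)
  d <- data.frame(beta_exposure = bx, se_exposure = 0.01,
                  beta_outcome = 0.03 + 0.6 * bx,
                  se_outcome = c(0.02, 0.03, 0.04, 0.05))
  fit <- mr_egger(d)
  expect_equal(fit$beta, 0.6, tolerance = 1e-10)
  expect_equal(fit$egger_intercept, 0.03, tolerance = 1e-10)
  expect_equal(fit$q_stat, 0, tolerance = 1e-10)

  # zero intercept in an exact fit: the slope coincides with IVW
  d0 <- d
  d0$beta_outcome <- 0.6 * bx
  expect_equal(mr_egger(d0)$beta, ivw(d0)$beta, tolerance = 1e-10)

  d10 <- simulate_mr_summary(10, 0.4, seed = 3, pleiotropy = 0.02)
  o <- wls_intercept_oracle(d10$beta_exposure, d10$beta_outcome,
                            1 / d10$se_outcome^2)
  fit10 <- mr_egger(d10)
  expect_equal(fit10$beta, o$slope, tolerance = 1e-10)
  expect_equal(fit10$egger_intercept, o$intercept, tolerance = 1e-10)
  expect_equal(fit10$se, o$se_slope, tolerance = 1e-10)
  expect_equal(fit10$intercept_se, o$se_intercept, tolerance = 1e-10)

  expect_equal(mr_egger(d[1:2, ])$status, "insufficient_instruments")
})

test_that("2SLS identities: perfect instrument, ratio closed form, reduced-form Wald", {
  set.seed(10)
  n <- 400
  z <- rnorm(n)
  x <- 0.8 * z + rnorm(n)
  y <- 0.5 * x + rnorm(n)

  # z = x: 2SLS collapses to OLS
  ols <- ols_oracle(y, cbind(1, x))
  expect_equal(two_stage_least_squares(y, x, x)$beta, ols$beta,
               tolerance = 1e-10)

  # single instrument, no covariates: beta = cov(z, y) / cov(z, x)
  ts <- two_stage_least_squares(y, x, z)
  expect_equal(ts$beta, cov(z, y) / cov(z, x), tolerance = 1e-10)

  # ... equivalently the Wald ratio of the two reduced-form slopes
  bzy <- ols_oracle(y, cbind(1, z))$beta
  bzx <- ols_oracle(x, cbind(1, z))$beta
  expect_equal(ts$beta, bzy / bzx, tolerance = 1e-10)

  expect_gt(ts$f_first_stage, 10)
  set.seed(11)
  expect_warning(two_stage_least_squares(y, x, rnorm(n)),
                 "weak instrument")
})

test_that("per-SNP summary statistics match the single-variant regression oracle", {
  cc <- make_cohort(n = 400, seed = 12)
  ph <- cc$cohort$phenotypes
  st <- snp_summary_stats(cc$geno, ph$bmi, as.matrix(ph[, c("age", "sex")]),
                          variant_ids = c("rs1", "rs5"))
  for (v in c("rs1", "rs5")) {
    o <- ols_oracle(ph$bmi, cbind(1, cc$geno$dosages[, v], ph$age, ph$sex))
    expect_equal(st$beta[st$variant_id == v], o$beta, tolerance = 1e-10)
    expect_equal(st$se[st$variant_id == v], o$se, tolerance = 1e-10)
  }
})

test_that("the bidirectional report flags the generative direction per regime", {
  cc <- make_cohort(n = 4000, seed = 13)
  gps <- compute_gps(cc$geno, cc$cohort$weights)
  prot <- preprocess_proteins(cc$cohort$proteins)
  rep_df <- run_bidirectional(cc$geno, cc$cohort$phenotypes, prot, gps,
                              cc$cohort$truth, alpha = 1e-3)
  dirs <- setNames(rep_df$direction,
                   cc$cohort$truth$regime[match(rep_df$protein_id,
                                                cc$cohort$truth$protein_id)])
  expect_equal(unname(dirs["bmi_to_protein"]), "forward")
  expect_equal(unname(dirs["protein_to_bmi"]), "reverse")
  expect_equal(unname(dirs["bidirectional"]), "both")
  expect_equal(unname(dirs["confounded_null"]), "none")
  expect_true(all(rep_df$fwd_2smr_status == "not_available"))

  # a protein without cis instruments gets the literal no-instruments marker
  truth2 <- cc$cohort$truth
  truth2$cis_variants[1] <- ""
  rep2 <- run_bidirectional(cc$geno, cc$cohort$phenotypes, prot, gps, truth2,
                            alpha = 1e-3)
  expect_equal(rep2$rev_1smr_status[1], "no_instruments")
})
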