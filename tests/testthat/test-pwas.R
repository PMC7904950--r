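# Association scans: preprocessing, OLS correctness against a
# normal-equations oracle, null uniformity, replication logic and the
# subsampling power procedure.

test_that("protein preprocessing is log2 + exact z-scoring with informative errors", {
  m <- cbind(p1 = c(2, 4, 8), p2 = c(1, 4, 16))
  rownames(m) <- c("s1", "s2", "s3")
  z <- preprocess_proteins(m)
  expect_equal(unname(z[, "p1"]), c(-1, 0, 1))
  expect_equal(unname(z[, "p2"]), c(-1, 0, 1))

  const <- cbind(p1 = c(4, 4, 4))
  expect_error(preprocess_proteins(const), "zero variance")

  neg <- cbind(pA = c(2, -1, 8))
  rownames(neg) <- c("s1", "s2", "s3")
  expect_error(preprocess_proteins(neg), "pA")
  expect_error(preprocess_proteins(neg), "s2")
  # output is centred at zero, so feeding it back violates the positivity contract
  expect_error(preprocess_proteins(z), "non-positive")
})

test_that("scan estimates match the normal-equations oracle to 1e-10", {
  set.seed(42)
  n <- 50
  x <- rnorm(n)
  covs <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("c1", "c2", "c3")))
  Y <- sapply(1:5, function(j) 0.3 * x + covs %*% rnorm(3) + rnorm(n))
  colnames(Y) <- paste0("p", 1:5)
  sc <- association_scan(Y, x, covs, standardize_exposure = FALSE)
  X <- cbind(1, x, covs)
  for (j in 1:5) {
    o <- ols_oracle(Y[, j], X)
    expect_equal(sc$beta[j], o$beta, tolerance = 1e-10)
    expect_equal(sc$se[j], o$se, tolerance = 1e-10)
    expect_equal(sc$p[j], o$p, tolerance = 1e-10)
  }
})

test_that("an exact linear protein gives the exact slope and a vanishing p", {
  set.seed(1)
  x <- rnorm(10)
  Y <- cbind(p = 2 * x)
  sc <- association_scan(Y, x, standardize_exposure = FALSE)
  expect_equal(sc$beta, 2, tolerance = 1e-12)
  expect_lt(sc$p, 1e-100)
})

test_that("negating the exposure flips betas and leaves p-values unchanged", {
  set.seed(2)
  Y <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("p", 1:4)))
  x <- rnorm(50)
  a <- association_scan(Y, x)
  b <- association_scan(Y, -x)
  expect_equal(a$beta, -b$beta, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  set.seed(3)
  x <- rnorm(30)
  covs <- cbind(dup = x)
  Y <- matrix(rnorm(30), ncol = 1, dimnames = list(NULL, "p"))
  expect_error(association_scan(Y, x, covs, standardize_exposure = FALSE),
               "collinear")
})

test_that("p-values are uniform under a permuted-exposure global null", {
  set.seed(4)
  n <- 300
  Y <- matrix(rnorm(n * 500), n, 500, dimnames = list(NULL, paste0("p", 1:500)))
  x <- sample(rnorm(n)) # permuted against everything
  sc <- association_scan(Y, x)
  ks <- suppressWarnings(ks.test(sc$p, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("Bonferroni thresholds and their guards", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("replication status combines significance and directional concordance", {
  disc <- data.frame(protein_id = c("a", "b", "c"),
                     beta = c(0.1, 0.1, 0.2), p = c(1e-6, 1e-6, 1e-6))
  rep1 <- data.frame(protein_id = c("a", "b"),
                     beta = c(0.08, -0.02), p = c(1e-6, 1e-6))
  suppressMessages({
    st <- assess_replication(disc, rep1, alpha = 0.05, m = 184)
  })
  expect_equal(st$status, c("replicated", "discordant", "missing"))

  # significant but with the wrong sign is never a replication
  expect_equal(st$status[st$protein_id == "b"], "discordant")

  # identical tables replicate fully at any alpha above the max p
  disc2 <- data.frame(protein_id = letters[1:4],
                      beta = c(0.2, -0.3, 0.1, -0.4), p = rep(1e-8, 4))
  st2 <- assess_replication(disc2, disc2, alpha = 0.05)
  expect_true(all(st2$status == "replicated"))
  expect_equal(attr(st2, "beta_correlation"), 1, tolerance = 1e-12)
})

test_that("p95: degenerate pairs, null calibration, and a strong association", {
  set.seed(5)
  n <- 996
  x <- rnorm(n)

  # exact linear relation: every subsample gives the same (vanishing) p
  exact <- subsample_power(2 * x, x, n_sub = 200, reps = 20, seed = 1)
  expect_lt(exact$p95, 1e-100)

  # null protein in a parent cohort large enough that subsamples are nearly
  # independent: p95 is the 5th percentile of uniform p-values
  xl <- rnorm(8000)
  null <- subsample_power(rnorm(8000), xl, n_sub = 356, reps = 1000, seed = 2)
  expect_gt(null$p95, 0.02)
  expect_lt(null$p95, 0.09)
  expect_false(null$powered)

  # strong association: powered at the replication threshold
  strong <- subsample_power(0.5 * x + rnorm(n), x, n_sub = 356, reps = 200,
                            seed = 3)
  expect_lt(strong$p95, 0.05 / 184)
  expect_true(strong$powered)

  expect_error(subsample_power(rnorm(10), rnorm(10), n_sub = 20, reps = 5),
               "exceeds")
})

test_that("the sensitivity model leaves unconfounded associations essentially unchanged", {
  cc <- make_cohort(n = 2000, seed = 51)
  prot <- preprocess_proteins(cc$cohort$proteins)
  ph <- cc$cohort$phenotypes
  basic <- association_scan(prot, ph$bmi, ph[, c("age", "sex")], model = "basic")
  full <- association_scan(prot, ph$bmi,
                           ph[, c("age", "sex", "smoking", "alcohol",
                                  "physical_activity", "diabetes")],
                           model = "full")
  expect_true(all(abs(basic$beta - full$beta) < 2 * basic$se))
})
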