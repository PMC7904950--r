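# Independent oracles (normal equations, not the package's QR path) and
# small-cohort builders shared across test files.

# OLS of y on X via explicit normal equations; returns beta/se/t/p for
# column `which`, t reference with n - p df.
ols_oracle <- function(y, X, which = 2) {
  xtx_inv <- solve(crossprod(X))
  beta <- drop(xtx_inv %*% crossprod(X, y))
  res <- y - drop(X %*% beta)
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  se <- sqrt(sigma2 * diag(xtx_inv))
  tval <- beta / se
  list(beta = unname(beta[which]), se = unname(se[which]),
       p = unname(2 * pt(-abs(tval[which]), nrow(X) - ncol(X))))
}

# Weighted least squares of by on bx through the origin, weights w:
# the textbook IVW identity.
wls_origin_oracle <- function(bx, by, w) {
  beta <- sum(w * bx * by) / sum(w * bx^2)
  list(beta = beta, se = 1 / sqrt(sum(w * bx^2)))
}

# Weighted regression with intercept via explicit normal equations,
# fixed-effect (sigma = 1) covariance: the MR-Egger oracle.
wls_intercept_oracle <- function(bx, by, w) {
  X <- cbind(1, bx)
  W <- diag(w)
  xtx_inv <- solve(t(X) %*% W %*% X)
  beta <- drop(xtx_inv %*% t(X) %*% W %*% by)
  se <- sqrt(diag(xtx_inv))
  list(intercept = unname(beta[1]), slope = unname(beta[2]),
       se_intercept = unname(se[1]), se_slope = unname(se[2]))
}

# Small synthetic cohort: genotypes + traits + computed score, one protein
# per regime unless overridden.
make_cohort <- function(n = 2000, seed = 1, k = 4, n_score = 50,
                        regimes = default_regimes(1), ...) {
  cfg <- sim_config(n_samples = n, n_score_variants = n_score,
                    amplification_k = k, regimes = regimes, seed = seed, ...)
  n_var <- n_score + nrow(regimes) * cfg$n_cis_variants_per_protein
  specs <- variant_specs(n_var, seed = seed)
  geno <- simulate_genotypes(n, specs, seed = seed + 100000)
  cohort <- simulate_traits(geno, cfg)
  list(cfg = cfg, specs = specs, geno = geno, cohort = cohort)
}

# Tail/full effect ratio of BMI on the computed score for one simulated
# cohort (the tail-effect signature quantity).
bmi_tail_ratio <- function(seed, k, n = 10000, p = 5) {
  cc <- make_cohort(n = n, seed = seed, k = k)
  gps <- compute_gps(cc$geno, cc$cohort$weights)
  tail_regression(cc$cohort$phenotypes$bmi, gps$standardized_score,
                  as.matrix(cc$cohort$phenotypes[, c("age", "sex")]),
                  p = p)$ratio
}
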