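# Protein-wide association scans
#
# One ordinary-least-squares regression per protein against an exposure (BMI
# or a polygenic score) with covariate adjustment, Bonferroni control,
# replication assessment against a second cohort, and subsampling-based
# replication power (the p95 procedure).

#' Log2-transform and z-score a protein matrix
#'
#' Each protein column is log2-transformed and then standardized to mean 0,
#' sample SD 1 -- the canonical preprocessing for relative-abundance
#' (aptamer-based) proteomics before linear modelling.
#'
#' @param raw Samples x proteins matrix of positive relative abundances.
#' @return Matrix of the same shape, each column mean 0 / SD 1.
#' @export
preprocess_proteins <- function(raw) {
  .assert(is.matrix(raw) && is.numeric(raw), "raw must be a numeric matrix")
  if (any(raw <= 0 | !is.finite(raw))) {
    bad <- which(raw <= 0 | !is.finite(raw), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "preprocess_proteins: non-positive value for protein '%s', sample '%s'",
      if (!is.null(colnames(raw))) colnames(raw)[bad[2]] else bad[2],
      if (!is.null(rownames(raw))) rownames(raw)[bad[1]] else bad[1]),
      call. = FALSE)
  }
  .standardize_cols(log2(raw), what = "protein")
}

# Multi-response OLS via one QR decomposition of the design. Returns the
# coefficient, SE, t and two-sided p (t reference, n - p df) of the design
# column `which` for every response column of Y.
.ols_scan <- function(Y, X, which = 2L) {
  n <- nrow(X)
  p <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  coefs <- qr.coef(qrx, Y)
  res <- Y - X %*% coefs
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtx_inv <- .xtx_inverse(qrx)
  se <- sqrt(sigma2 * xtx_inv[which, which])
  beta <- coefs[which, ]
  tval <- beta / se
  list(beta = beta, se = se, t = tval,
       p = 2 * stats::pt(-abs(tval), df), df = df, n = n)
}

#' Protein-wide association scan
#'
#' Regresses every (already standardized) protein on
#' `[intercept, exposure, covariates]` by ordinary least squares and reports
#' the exposure coefficient, its standard error and a two-sided p-value from
#' the t distribution with `n - p` degrees of freedom. By default the
#' exposure and covariates are z-scored before fitting so coefficients are in
#' SD-per-SD units; set `standardize_exposure = FALSE` to keep the exposure
#' on its native scale (e.g. BMI in kg/m2).
#'
#' @param proteins Samples x proteins matrix (see [preprocess_proteins()]).
#' @param exposure Numeric vector, one value per sample.
#' @param covariates Optional numeric matrix/data.frame of covariates.
#' @param exposure_name Label recorded in the output.
#' @param standardize_exposure Z-score exposure and covariates before fitting.
#' @param model Label recorded in the output (`"basic"`, `"full"`, ...).
#' @return Data.frame with columns `protein_id`, `exposure`, `beta`, `se`,
#'   `p`, `n`, `model`.
#' @export
association_scan <- function(proteins, exposure, covariates = NULL,
                             exposure_name = "bmi",
                             standardize_exposure = TRUE,
                             model = "basic") {
  .assert(is.matrix(proteins) && is.numeric(proteins),
          "proteins must be a numeric matrix")
  n <- nrow(proteins)
  .assert(length(exposure) == n,
          "exposure has %d values but %d samples expected", length(exposure), n)
  cov <- .as_covariate_matrix(covariates, n)
  if (standardize_exposure) {
    exposure <- standardize(exposure, exposure_name)
    if (ncol(cov) > 0) cov <- .standardize_cols(cov, what = "covariate")
  }
  X <- cbind("(Intercept)" = 1, exposure = exposure, cov)
  fit <- .ols_scan(proteins, X, which = 2L)
  ids <- colnames(proteins)
  if (is.null(ids)) ids <- paste0("protein", seq_len(ncol(proteins)))
  data.frame(
    protein_id = ids,
    exposure = exposure_name,
    beta = unname(fit$beta),
    se = unname(fit$se),
    p = unname(fit$p),
    n = n,
    model = model,
    stringsAsFactors = FALSE
  )
}

#' Bonferroni family-wise threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Number of tests, >= 1.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 921) # 5.43e-5
#' @export
bonferroni_threshold <- function(alpha, m) {
  .assert(is.numeric(alpha) && alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  .assert(is.numeric(m) && m >= 1, "m must be >= 1")
  alpha / m
}

#' Assess replication of association results in a second cohort
#'
#' A discovery association is `replicated` when its replication p-value is
#' below `alpha / m` (with `m` the number of associations brought to
#' replication) and the two effect estimates agree in sign;
#' `concordant_only` when the sign matches but significance is missed;
#' `discordant` otherwise; `missing` when the protein was not tested in the
#' replication table. The Pearson correlation of effect sizes across cohorts
#' is attached as attribute `beta_correlation`.
#'
#' @param discovery,replication Association tables from [association_scan()].
#' @param alpha Family-wise error rate before correction (default 0.05).
#' @param m Number of tests for the Bonferroni correction; defaults to the
#'   number of discovery rows.
#' @return Data.frame with `protein_id`, `beta_discovery`, `beta_replication`,
#'   `p_replication`, `status`; attributes `threshold`, `beta_correlation`.
#' @export
assess_replication <- function(discovery, replication, alpha = 0.05, m = NULL) {
  .assert(all(c("protein_id", "beta", "p") %in% names(discovery)) &&
            all(c("protein_id", "beta", "p") %in% names(replication)),
          "discovery/replication must be association tables")
  if (is.null(m)) m <- nrow(discovery)
  thr <- bonferroni_threshold(alpha, m)
  idx <- match(discovery$protein_id, replication$protein_id)
  out <- data.frame(
    protein_id = discovery$protein_id,
    beta_discovery = discovery$beta,
    beta_replication = replication$beta[idx],
    p_replication = replication$p[idx],
    stringsAsFactors = FALSE
  )
  concord <- sign(out$beta_discovery) == sign(out$beta_replication)
  status <- ifelse(is.na(idx), "missing",
            ifelse(!concord, "discordant",
            ifelse(out$p_replication < thr, "replicated", "concordant_only")))
  out$status <- status
  if (any(status == "missing")) {
    message(sprintf("assess_replication: %d protein(s) missing from replication: %s",
                    sum(status == "missing"),
                    paste(out$protein_id[status == "missing"], collapse = ", ")))
  }
  ok <- !is.na(idx)
  attr(out, "threshold") <- thr
  attr(out, "beta_correlation") <-
    if (sum(ok) >= 3) stats::cor(out$beta_discovery[ok], out$beta_replication[ok])
    else NA_real_
  out
}

#' Subsampling-based replication power (the p95 procedure)
#'
#' Draws `reps` subsamples of size `n_sub` without replacement, refits the
#' association of the protein on the exposure (plus covariates) in each, and
#' returns the `ceiling(0.05 * reps)`-th smallest p-value -- for the default
#' 1000 repetitions, the 50th smallest. This is the p-value achievable with
#' 95% probability at the replication sample size; the association is
#' `powered` when that p95 falls below the replication threshold.
#'
#' @param protein Numeric vector (standardized protein), one value per sample.
#' @param exposure Numeric exposure vector.
#' @param covariates Optional covariate matrix.
#' @param n_sub Subsample size (default 356, a typical replication cohort).
#' @param reps Number of subsamples (default 1000).
#' @param seed Integer seed.
#' @param alpha_replication Replication threshold compared against p95
#'   (default 0.05/184).
#' @return A one-row data.frame: `p95`, `n_sub`, `reps`, `powered`.
#' @export
subsample_power <- function(protein, exposure, covariates = NULL,
                            n_sub = 356, reps = 1000, seed = 1,
                            alpha_replication = 0.05 / 184) {
  n <- length(protein)
  .assert(length(exposure) == n, "protein and exposure lengths differ")
  .assert(n_sub <= n, "n_sub (%d) exceeds the sample size (%d)", n_sub, n)
  .assert(reps >= 1, "reps must be >= 1")
  cov <- .as_covariate_matrix(covariates, n)
  X <- cbind(1, exposure, cov)
  set.seed(seed)
  ps <- vapply(seq_len(reps), function(r) {
    idx <- sample.int(n, n_sub)
    fit <- .ols_scan(matrix(protein[idx], ncol = 1), X[idx, , drop = FALSE])
    fit$p[1]
  }, numeric(1))
  k <- ceiling(0.05 * reps)
  p95 <- sort(ps)[k]
  data.frame(p95 = p95, n_sub = n_sub, reps = reps,
             powered = p95 < alpha_replication)
}
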