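# Bidirectional Mendelian randomization
#
# Instrument selection (significance, instrument strength, confounder
# exclusion, greedy LD clumping), summary-statistic harmonization, and the
# estimators: single-instrument Wald ratio, fixed-effect inverse-variance
# weighting with Cochran's Q, MR-Egger with the directional-pleiotropy
# intercept test, and one-sample two-stage least squares.

.mr_estimate <- function(method, beta = NA_real_, se = NA_real_, p = NA_real_,
                         n_snps = NA_integer_, q_stat = NA_real_,
                         q_p = NA_real_, egger_intercept = NA_real_,
                         intercept_se = NA_real_, intercept_p = NA_real_,
                         status = "ok") {
  structure(
    data.frame(method = method, beta = beta, se = se, p = p,
               n_snps = as.integer(n_snps), q_stat = q_stat, q_p = q_p,
               egger_intercept = egger_intercept, intercept_se = intercept_se,
               intercept_p = intercept_p, status = status,
               stringsAsFactors = FALSE),
    class = c("mr_estimate", "data.frame")
  )
}

#' Select genetic instruments from exposure summary statistics
#'
#' Filters to genome-wide significance (`p < p_max`) and instrument strength
#' (`F = (beta/se)^2 > f_min`), removes variants with any confounder
#' association below `confounder_p`, then applies greedy LD clumping: SNPs
#' are visited in ascending p-value order and accepted only if their squared
#' dosage correlation with every already-accepted SNP within
#' `clump_window_bp` on the same chromosome is at most `clump_r2`. Every
#' removal is recorded with its reason. An empty result is a typed
#' "no instruments" outcome, not an error.
#'
#' @param exposure_stats Data.frame with `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `p`.
#' @param p_max,f_min Significance and strength thresholds (defaults 1e-8, 10).
#' @param clump_r2 Maximum pairwise r2 between accepted SNPs (default 0.001).
#' @param clump_window_bp Clumping window (default 10 Mb).
#' @param ld_reference Optional `genotype_matrix` supplying dosages for the
#'   r2 computation; without it clumping is skipped (a warning is raised when
#'   more than one candidate survives).
#' @param confounders Optional catalog data.frame (`variant_id`, `trait`, `p`).
#' @param confounder_p Exclusion threshold for confounder associations.
#' @return List of class `mr_instruments`: `instruments` (accepted rows with
#'   `f_stat`), `removed` (variant_id, reason), `status` ("ok" or
#'   "no_instruments").
#' @export
select_instruments <- function(exposure_stats, p_max = 1e-8, f_min = 10,
                               clump_r2 = 0.001, clump_window_bp = 1e7,
                               ld_reference = NULL, confounders = NULL,
                               confounder_p = 1e-8) {
  need <- c("variant_id", "beta", "se", "p")
  .assert(all(need %in% names(exposure_stats)),
          "exposure_stats must have columns: %s", paste(need, collapse = ", "))
  st <- exposure_stats
  st$f_stat <- (st$beta / st$se)^2
  removed <- data.frame(variant_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  drop <- function(ids, reason) {
    if (length(ids)) {
      removed <<- rbind(removed, data.frame(variant_id = ids, reason = reason,
                                            stringsAsFactors = FALSE))
    }
  }
  weak <- st$p >= p_max | st$f_stat <= f_min
  drop(st$variant_id[weak], "weak_or_nonsignificant")
  st <- st[!weak, , drop = FALSE]
  if (!is.null(confounders) && nrow(confounders)) {
    conf_ids <- unique(confounders$variant_id[confounders$p < confounder_p])
    hit <- st$variant_id %in% conf_ids
    drop(st$variant_id[hit], "confounder")
    st <- st[!hit, , drop = FALSE]
  }
  if (nrow(st) > 1) {
    st <- st[order(st$p), , drop = FALSE]
    if (is.null(ld_reference)) {
      warning("select_instruments: no ld_reference supplied; clumping skipped")
    } else {
      .assert(inherits(ld_reference, "genotype_matrix"),
              "ld_reference must be a genotype_matrix")
      has_pos <- all(c("chrom", "pos") %in% names(st))
      accepted <- integer(0)
      clumped <- character(0)
      for (i in seq_len(nrow(st))) {
        id <- st$variant_id[i]
        ok <- TRUE
        for (j in accepted) {
          same_window <- !has_pos ||
            (st$chrom[i] == st$chrom[j] &&
               abs(st$pos[i] - st$pos[j]) <= clump_window_bp)
          if (same_window) {
            di <- ld_reference$dosages[, id]
            dj <- ld_reference$dosages[, st$variant_id[j]]
            if (stats::cor(di, dj)^2 > clump_r2) { ok <- FALSE; break }
          }
        }
        if (ok) accepted <- c(accepted, i) else clumped <- c(clumped, id)
      }
      drop(clumped, "ld_clumped")
      st <- st[accepted, , drop = FALSE]
    }
  }
  rownames(st) <- NULL
  structure(
    list(instruments = st, removed = removed,
         status = if (nrow(st)) "ok" else "no_instruments"),
    class = "mr_instruments"
  )
}

#' Harmonize exposure and outcome summary statistics
#'
#' Keeps SNPs present in both tables, aligned on the exposure's effect
#' allele: when the outcome's effect allele equals the exposure's other
#' allele the outcome beta is negated (alleles swapped); palindromic (A/T,
#' C/G) SNPs and unresolvable allele pairs are dropped with a reason.
#'
#' @param exposure_stats,outcome_stats Data.frames keyed by `variant_id` with
#'   `effect_allele`, `other_allele`, `beta`, `se` (and `p` for the exposure).
#' @return List: `instruments` (data.frame with `beta_exposure`,
#'   `se_exposure`, `p_exposure`, `beta_outcome`, `se_outcome`, `f_stat`),
#'   `dropped` (variant_id, reason).
#' @export
harmonize_summary_stats <- function(exposure_stats, outcome_stats) {
  idx <- match(exposure_stats$variant_id, outcome_stats$variant_id)
  dropped <- data.frame(variant_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  keep <- !is.na(idx)
  if (any(!keep)) {
    dropped <- rbind(dropped, data.frame(
      variant_id = exposure_stats$variant_id[!keep],
      reason = "absent_from_outcome", stringsAsFactors = FALSE))
  }
  ex <- exposure_stats[keep, , drop = FALSE]
  ou <- outcome_stats[idx[keep], , drop = FALSE]

  pal <- .is_palindromic(ex$effect_allele, ex$other_allele)
  same <- ou$effect_allele == ex$effect_allele & ou$other_allele == ex$other_allele
  swapped <- ou$effect_allele == ex$other_allele & ou$other_allele == ex$effect_allele
  bad <- !pal & !same & !swapped
  if (any(pal)) {
    dropped <- rbind(dropped, data.frame(variant_id = ex$variant_id[pal],
                                         reason = "palindromic",
                                         stringsAsFactors = FALSE))
  }
  if (any(bad)) {
    dropped <- rbind(dropped, data.frame(variant_id = ex$variant_id[bad],
                                         reason = "allele_mismatch",
                                         stringsAsFactors = FALSE))
  }
  ok <- !pal & !bad
  ex <- ex[ok, , drop = FALSE]
  ou <- ou[ok, , drop = FALSE]
  sw <- swapped[ok]
  out <- data.frame(
    variant_id = ex$variant_id,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    p_exposure = if ("p" %in% names(ex)) ex$p else
      2 * stats::pnorm(-abs(ex$beta / ex$se)),
    beta_outcome = ifelse(sw, -ou$beta, ou$beta),
    se_outcome = ou$se,
    stringsAsFactors = FALSE
  )
  out$f_stat <- (out$beta_exposure / out$se_exposure)^2
  rownames(out) <- NULL
  list(instruments = out, dropped = dropped)
}

#' Wald ratio (single-instrument causal estimate)
#'
#' `beta = by / bx` with the first-order delta-method standard error
#' `se = sy / |bx|` (the exposure-side uncertainty is ignored, matching the
#' conventional ratio method; `second_order = TRUE` adds the
#' `by^2 * sx^2 / bx^4` term). Two-sided normal p-value.
#'
#' @param bx,sx Exposure beta and SE (bx must be nonzero).
#' @param by,sy Outcome beta and SE.
#' @param second_order Include the exposure-uncertainty term in the SE.
#' @return A one-row `mr_estimate` data.frame.
#' @export
wald_ratio <- function(bx, sx, by, sy, second_order = FALSE) {
  .assert(bx != 0, "wald_ratio: null instrument (bx = 0)")
  beta <- by / bx
  se <- if (second_order) sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4) else sy / abs(bx)
  .mr_estimate("wald", beta = beta, se = se,
               p = 2 * stats::pnorm(-abs(beta / se)), n_snps = 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Fixed-effect IVW: `beta = sum(bx*by/sy^2) / sum(bx^2/sy^2)`,
#' `se = 1/sqrt(sum(bx^2/sy^2))` -- the weighted regression of outcome betas
#' on exposure betas through the origin with weights `1/sy^2`. Cochran's
#' `Q = sum((by - beta*bx)^2 / sy^2)` with `k - 1` degrees of freedom
#' measures heterogeneity of the per-SNP ratios. With a single SNP the
#' estimate reduces to the Wald ratio and Q is undefined. With
#' `random_effects = TRUE` the SE is inflated by `sqrt(Q/(k-1))` when that
#' exceeds 1 (multiplicative random effects).
#'
#' @param instruments Harmonized data.frame (see
#'   [harmonize_summary_stats()] or [simulate_mr_summary()]).
#' @param random_effects Inflate the SE under excess heterogeneity.
#' @return A one-row `mr_estimate` data.frame; `status = "no_instruments"`
#'   when the set is empty.
#' @export
ivw <- function(instruments, random_effects = FALSE) {
  k <- if (is.null(instruments)) 0L else nrow(instruments)
  if (k == 0L) return(.mr_estimate("ivw", n_snps = 0L, status = "no_instruments"))
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sy <- instruments$se_outcome
  if (k == 1L) {
    est <- wald_ratio(bx, instruments$se_exposure, by, sy)
    est$method <- "ivw"
    return(est)
  }
  w <- 1 / sy^2
  denom <- sum(w * bx^2)
  beta <- sum(w * bx * by) / denom
  se <- 1 / sqrt(denom)
  q <- sum(w * (by - beta * bx)^2)
  if (random_effects) se <- se * max(1, sqrt(q / (k - 1)))
  .mr_estimate("ivw", beta = beta, se = se,
               p = 2 * stats::pnorm(-abs(beta / se)), n_snps = k,
               q_stat = q, q_p = stats::pchisq(q, k - 1, lower.tail = FALSE))
}

#' MR-Egger regression with the directional-pleiotropy intercept test
#'
#' SNPs are re-oriented so every exposure beta is non-negative, then outcome
#' betas are regressed on exposure betas with a free intercept, weights
#' `1/sy^2` (weighted normal equations, fixed-effect standard errors). The
#' slope is the causal estimate; the intercept estimates directional
#' pleiotropy, with its SE and two-sided normal p-value. Residual
#' heterogeneity Q' is reported on `k - 2` degrees of freedom.
#'
#' @param instruments Harmonized data.frame with >= 3 SNPs.
#' @return A one-row `mr_estimate` data.frame; `status =
#'   "insufficient_instruments"` with fewer than 3 SNPs.
#' @export
mr_egger <- function(instruments) {
  k <- if (is.null(instruments)) 0L else nrow(instruments)
  if (k < 3L) {
    return(.mr_estimate("egger", n_snps = k, status = "insufficient_instruments"))
  }
  s <- ifelse(instruments$beta_exposure < 0, -1, 1)
  bx <- instruments$beta_exposure * s
  by <- instruments$beta_outcome * s
  sy <- instruments$se_outcome
  w <- 1 / sy^2
  # weighted normal equations for by ~ a + b * bx
  sw <- sum(w); swx <- sum(w * bx); swx2 <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swx2 - swx^2
  .assert(det > 0, "mr_egger: degenerate design (no spread in exposure betas)")
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swx2 * swy - swx * swxy) / det
  se_slope <- sqrt(sw / det)
  se_int <- sqrt(swx2 / det)
  resid <- by - intercept - slope * bx
  q <- sum(w * resid^2)
  .mr_estimate("egger",
               beta = slope, se = se_slope,
               p = 2 * stats::pnorm(-abs(slope / se_slope)), n_snps = k,
               q_stat = q,
               q_p = stats::pchisq(q, k - 2, lower.tail = FALSE),
               egger_intercept = intercept, intercept_se = se_int,
               intercept_p = 2 * stats::pnorm(-abs(intercept / se_int)))
}

#' One-sample Mendelian randomization by two-stage least squares
#'
#' Stage 1 regresses the exposure on the instrument(s) and covariates and
#' forms fitted exposures; stage 2 regresses the outcome on the fitted
#' exposure and covariates. The coefficient on the fitted exposure is the
#' causal estimate. Standard errors use the classical 2SLS variance: the
#' residuals are recomputed with the *actual* exposure, and the covariance is
#' `sigma^2 (Zhat' Zhat)^-1` with a t reference on `n - p` degrees of
#' freedom. The first-stage F statistic for the instrument block is recorded
#' (a warning is raised below 10).
#'
#' @param y Outcome vector.
#' @param x Exposure vector.
#' @param z Instrument vector or matrix (one column per instrument).
#' @param covariates Optional covariate matrix.
#' @return A one-row `mr_estimate` data.frame (method `"tsls"`) with an
#'   additional `f_first_stage` column.
#' @export
two_stage_least_squares <- function(y, x, z, covariates = NULL) {
  n <- length(y)
  .assert(length(x) == n, "y and x lengths differ")
  if (is.vector(z)) z <- matrix(z, ncol = 1, dimnames = list(NULL, "z"))
  if (is.data.frame(z)) z <- as.matrix(z)
  .assert(nrow(z) == n, "instrument rows must match sample count")
  if (is.null(colnames(z))) colnames(z) <- paste0("z", seq_len(ncol(z)))
  cov <- .as_covariate_matrix(covariates, n)

  X1 <- cbind(1, z, cov)
  q1 <- qr(X1)
  .assert(q1$rank == ncol(X1), "two_stage_least_squares: rank-deficient first stage")
  xhat <- qr.fitted(q1, x)
  # first-stage F for the instrument block
  X0 <- cbind(rep(1, n), cov)
  rss1 <- sum(qr.resid(q1, x)^2)
  rss0 <- sum(qr.resid(qr(X0), x)^2)
  qk <- ncol(z)
  f_first <- ((rss0 - rss1) / qk) / (rss1 / (n - ncol(X1)))
  .assert(is.finite(f_first) && rss0 > rss1 + 1e-300,
          "two_stage_least_squares: irrelevant instrument (zero first-stage slope)")
  if (f_first < 10) {
    warning(sprintf("weak instrument: first-stage F = %.2f < 10", f_first))
  }

  X2 <- cbind("(Intercept)" = 1, exposure = xhat, cov)
  q2 <- qr(X2)
  .assert(q2$rank == ncol(X2), "two_stage_least_squares: rank-deficient second stage")
  coefs <- qr.coef(q2, y)
  # classical 2SLS variance: residuals from the actual exposure
  Xa <- cbind(1, x, cov)
  resid <- y - drop(Xa %*% coefs)
  p2 <- ncol(X2)
  sigma2 <- sum(resid^2) / (n - p2)
  xtx_inv <- .xtx_inverse(q2)
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  beta <- unname(coefs[2])
  est <- .mr_estimate("tsls", beta = beta, se = se,
                      p = 2 * stats::pt(-abs(beta / se), n - p2),
                      n_snps = qk)
  est$f_first_stage <- f_first
  est
}

# "no data" / "no instruments" cell for the bidirectional report
.mr_cell <- function(prefix, est = NULL, status = "not_available") {
  if (is.null(est)) {
    out <- data.frame(beta = NA_real_, se = NA_real_, p = NA_real_,
                      status = status, stringsAsFactors = FALSE)
  } else {
    out <- data.frame(beta = est$beta, se = est$se, p = est$p,
                      status = est$status, stringsAsFactors = FALSE)
  }
  names(out) <- paste0(prefix, "_", names(out))
  out
}

#' Bidirectional MR report over a cohort
#'
#' For every protein, four cells are evaluated where inputs permit:
#' one-sample MR in the BMI-to-protein direction (2SLS with the polygenic
#' score instrumenting BMI), one-sample MR in the protein-to-BMI direction
#' (2SLS with up to `max_reverse_instruments` strongest cis instruments for
#' the protein), and, when summary-statistic bundles are supplied,
#' two-sample IVW in each direction. Cells without usable instruments carry
#' the literal status `"no_instruments"`; absent summary data gives
#' `"not_available"`. Significance flags use `alpha` (default Bonferroni
#' 0.05 over the number of proteins, per direction).
#'
#' @param geno A `genotype_matrix` (for cis instruments).
#' @param phenotypes Phenotype data.frame with `bmi` plus covariates.
#' @param proteins Standardized protein matrix (samples x proteins).
#' @param gps A `gps_vector` (instrument for BMI).
#' @param truth Truth table with `protein_id` and comma-separated
#'   `cis_variants` naming each protein's candidate instruments.
#' @param covariate_names Phenotype columns used as covariates.
#' @param forward_2smr,reverse_2smr Optional named lists (per protein) of
#'   harmonized summary-statistic data.frames for the two-sample cells.
#' @param alpha Per-test significance threshold; default `0.05 / n_proteins`.
#' @param max_reverse_instruments Cis instruments allowed in the reverse
#'   one-sample fit (default 2, mirroring the one-or-two instrument rule).
#' @return Data.frame, one row per protein, with the four cells'
#'   beta/se/p/status, `fwd_sig`, `rev_sig`, and `direction` in
#'   `{forward, reverse, both, none}`.
#' @export
run_bidirectional <- function(geno, phenotypes, proteins, gps, truth,
                              covariate_names = c("age", "sex"),
                              forward_2smr = NULL, reverse_2smr = NULL,
                              alpha = NULL, max_reverse_instruments = 2) {
  .assert(inherits(gps, "gps_vector"), "gps must be a gps_vector")
  ids <- colnames(proteins)
  .assert(all(truth$protein_id %in% ids) || all(ids %in% truth$protein_id),
          "truth and protein matrix do not share protein ids")
  ids <- intersect(ids, truth$protein_id)
  if (is.null(alpha)) alpha <- bonferroni_threshold(0.05, length(ids))
  cov <- as.matrix(phenotypes[, covariate_names, drop = FALSE])
  z_bmi <- standardize(phenotypes$bmi, "bmi")
  s <- gps$standardized_score

  rows <- lapply(ids, function(pid) {
    y <- proteins[, pid]
    fwd <- two_stage_least_squares(y, z_bmi, s, cov)
    cells <- .mr_cell("fwd_1smr", fwd)

    cis <- strsplit(truth$cis_variants[truth$protein_id == pid], ",")[[1]]
    cis <- intersect(cis, colnames(geno$dosages))
    if (length(cis) == 0) {
      cells <- cbind(cells, .mr_cell("rev_1smr", status = "no_instruments"))
    } else {
      zc <- geno$dosages[, cis, drop = FALSE]
      # strongest instruments first: rank by first-stage association p
      pv <- apply(zc, 2, function(g) {
        f <- .ols_scan(matrix(y, ncol = 1), cbind(1, g, cov))
        f$p[1]
      })
      zc <- zc[, order(pv)[seq_len(min(max_reverse_instruments, ncol(zc)))],
               drop = FALSE]
      rev <- tryCatch(
        suppressWarnings(two_stage_least_squares(z_bmi, y, zc, cov)),
        error = function(e) NULL)
      cells <- cbind(cells, if (is.null(rev))
        .mr_cell("rev_1smr", status = "no_instruments")
        else .mr_cell("rev_1smr", rev))
    }

    f2 <- if (!is.null(forward_2smr) && !is.null(forward_2smr[[pid]]))
      .mr_cell("fwd_2smr", ivw(forward_2smr[[pid]])) else
        .mr_cell("fwd_2smr", status = "not_available")
    r2 <- if (!is.null(reverse_2smr) && !is.null(reverse_2smr[[pid]]))
      .mr_cell("rev_2smr", ivw(reverse_2smr[[pid]])) else
        .mr_cell("rev_2smr", status = "not_available")
    cbind(data.frame(protein_id = pid, stringsAsFactors = FALSE),
          cells, f2, r2)
  })
  out <- do.call(rbind, rows)
  sig <- function(p, status) !is.na(p) & status == "ok" & p < alpha
  out$fwd_sig <- sig(out$fwd_1smr_p, out$fwd_1smr_status) |
    sig(out$fwd_2smr_p, out$fwd_2smr_status)
  out$rev_sig <- sig(out$rev_1smr_p, out$rev_1smr_status) |
    sig(out$rev_2smr_p, out$rev_2smr_status)
  out$direction <- ifelse(out$fwd_sig & out$rev_sig, "both",
                   ifelse(out$fwd_sig, "forward",
                   ifelse(out$rev_sig, "reverse", "none")))
  attr(out, "alpha") <- alpha
  out
}

#' Per-SNP association summary statistics from individual-level data
#'
#' Regresses a trait on each variant's dosage (plus covariates) and returns
#' the GWAS-style summary table used as input to the two-sample estimators.
#'
#' @param geno A `genotype_matrix`.
#' @param trait Numeric vector, one value per sample.
#' @param covariates Optional covariate matrix.
#' @param variant_ids Subset of variants (default all).
#' @return Data.frame with `variant_id`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `beta`, `se`, `p`, `n`.
#' @export
snp_summary_stats <- function(geno, trait, covariates = NULL,
                              variant_ids = NULL) {
  .assert(inherits(geno, "genotype_matrix"), "geno must be a genotype_matrix")
  n <- length(trait)
  .assert(n == length(geno$sample_ids), "trait length must match sample count")
  cov <- .as_covariate_matrix(covariates, n)
  if (is.null(variant_ids)) variant_ids <- geno$variants$variant_id
  meta <- geno$variants[match(variant_ids, geno$variants$variant_id), ]
  Y <- matrix(trait, ncol = 1)
  res <- lapply(variant_ids, function(v) {
    f <- .ols_scan(Y, cbind(1, geno$dosages[, v], cov))
    c(f$beta[1], f$se[1], f$p[1])
  })
  res <- do.call(rbind, res)
  data.frame(
    variant_id = variant_ids, chrom = meta$chrom, pos = meta$pos,
    effect_allele = meta$effect_allele, other_allele = meta$other_allele,
    beta = res[, 1], se = res[, 2], p = res[, 3], n = n,
    stringsAsFactors = FALSE
  )
}
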