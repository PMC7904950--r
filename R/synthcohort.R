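# Synthetic-cohort generator
#
# Generates cohorts with a known causal structure so that every downstream
# stage (scoring, association scans, tail analysis, Mendelian randomization)
# can be validated against ground truth. Genotypes follow Hardy-Weinberg
# proportions per variant; BMI is driven by a polygenic score through an
# optionally tail-amplified (hinge) link; proteins are generated under four
# causal regimes with cis-pQTL instruments.

#' Build a table of variant descriptors
#'
#' Creates `n` biallelic variant records with minor allele frequencies drawn
#' uniformly from `maf_range`. By default palindromic (A/T, C/G) allele pairs
#' are avoided so that every variant is usable for scoring; set
#' `prop_palindromic > 0` to plant strand-ambiguous variants for testing the
#' harmonization path.
#'
#' @param n Number of variants.
#' @param maf_range Length-2 numeric, allele-frequency bounds in (0, 0.5].
#' @param chrom Chromosome label(s), recycled.
#' @param start_pos,spacing Base-pair position of the first variant and the
#'   spacing between consecutive variants.
#' @param prop_palindromic Fraction of variants given an A/T or C/G pair.
#' @param seed Integer seed; the function is deterministic given it.
#' @param prefix Variant-id prefix.
#' @return A data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `maf`.
#' @export
variant_specs <- function(n, maf_range = c(0.05, 0.5), chrom = "1",
                          start_pos = 1e6, spacing = 1e6,
                          prop_palindromic = 0, seed = 1, prefix = "rs") {
  .assert(n >= 1, "variant_specs: n must be >= 1")
  .assert(length(maf_range) == 2 && maf_range[1] > 0 && maf_range[2] <= 0.5 &&
            maf_range[1] <= maf_range[2],
          "variant_specs: maf_range must lie in (0, 0.5]")
  set.seed(seed)
  maf <- stats::runif(n, maf_range[1], maf_range[2])
  nonpal <- list(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pal <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  is_pal <- stats::runif(n) < prop_palindromic
  pick <- function(lst) lst[[sample.int(length(lst), 1)]]
  alleles <- t(vapply(is_pal, function(p) if (p) pick(pal) else pick(nonpal),
                      character(2)))
  data.frame(
    variant_id = paste0(prefix, seq_len(n)),
    chrom = rep_len(as.character(chrom), n),
    pos = as.integer(start_pos + (seq_len(n) - 1) * spacing),
    effect_allele = alleles[, 1],
    other_allele = alleles[, 2],
    maf = maf,
    stringsAsFactors = FALSE
  )
}

.validate_variant_specs <- function(specs) {
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele", "maf")
  .assert(all(need %in% names(specs)),
          "variant specs must have columns: %s", paste(need, collapse = ", "))
  .assert(!anyDuplicated(specs$variant_id),
          "duplicate variant_id in variant specs: %s",
          paste(unique(specs$variant_id[duplicated(specs$variant_id)]), collapse = ", "))
  .assert(all(specs$maf > 0 & specs$maf <= 0.5),
          "invalid maf (must be in (0, 0.5]) for: %s",
          paste(specs$variant_id[!(specs$maf > 0 & specs$maf <= 0.5)], collapse = ", "))
  .assert(all(specs$pos >= 1), "variant pos must be >= 1")
  bad <- !(.is_base(specs$effect_allele) & .is_base(specs$other_allele)) |
    specs$effect_allele == specs$other_allele
  .assert(!any(bad), "invalid allele pair for: %s",
          paste(specs$variant_id[bad], collapse = ", "))
  invisible(specs)
}

#' Simulate a dosage matrix under Hardy-Weinberg equilibrium
#'
#' Each variant's dosage is drawn as Binomial(2, maf), independently across
#' variants. Optional LD blocks induce pairwise correlation inside a block by
#' copying the block lead's haplotype alleles with probability `sqrt(r2)`
#' (member variants then share the lead's allele frequency, and the expected
#' squared dosage correlation with the lead is `r2`).
#'
#' @param n_samples Number of samples.
#' @param variant_specs Data.frame from [variant_specs()].
#' @param seed Integer seed; output is bit-reproducible given it.
#' @param ld_blocks Optional list of `list(variants = <ids>, r2 = <target>)`;
#'   the first id in each block is the lead.
#' @return An object of class `genotype_matrix`: a list with `sample_ids`,
#'   `variants` (the metadata data.frame) and `dosages` (samples x variants).
#' @export
simulate_genotypes <- function(n_samples, variant_specs, seed, ld_blocks = NULL) {
  .assert(n_samples >= 1, "simulate_genotypes: n_samples must be >= 1")
  .assert(nrow(variant_specs) >= 1, "simulate_genotypes: variant specs empty")
  .validate_variant_specs(variant_specs)
  set.seed(seed)
  m <- nrow(variant_specs)
  h1 <- matrix(0L, n_samples, m)
  h2 <- matrix(0L, n_samples, m)
  lead_of <- rep(NA_integer_, m)
  copy_p <- rep(NA_real_, m)
  if (!is.null(ld_blocks)) {
    for (b in ld_blocks) {
      .assert(all(b$variants %in% variant_specs$variant_id),
              "ld block references unknown variant id")
      .assert(b$r2 >= 0 && b$r2 <= 1, "ld block r2 must be in [0, 1]")
      idx <- match(b$variants, variant_specs$variant_id)
      lead_of[idx[-1]] <- idx[1]
      copy_p[idx[-1]] <- sqrt(b$r2)
    }
  }
  for (j in seq_len(m)) {
    if (is.na(lead_of[j])) {
      p <- variant_specs$maf[j]
      h1[, j] <- stats::rbinom(n_samples, 1, p)
      h2[, j] <- stats::rbinom(n_samples, 1, p)
    } else {
      lead <- lead_of[j]
      p <- variant_specs$maf[lead]
      keep1 <- stats::runif(n_samples) < copy_p[j]
      keep2 <- stats::runif(n_samples) < copy_p[j]
      h1[, j] <- ifelse(keep1, h1[, lead], stats::rbinom(n_samples, 1, p))
      h2[, j] <- ifelse(keep2, h2[, lead], stats::rbinom(n_samples, 1, p))
    }
  }
  dos <- h1 + h2
  storage.mode(dos) <- "double"
  colnames(dos) <- variant_specs$variant_id
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  rownames(dos) <- sample_ids
  structure(
    list(sample_ids = sample_ids, variants = variant_specs, dosages = dos),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants (dosages in [0, 2])\n",
              length(x$sample_ids), nrow(x$variants)))
  invisible(x)
}

#' Per-protein causal-regime table
#'
#' Convenience constructor for the regime table consumed by [sim_config()].
#' Regimes: `bmi_to_protein` (BMI raises/lowers the protein), `protein_to_bmi`
#' (the protein feeds into BMI), `bidirectional` (both edges, generated
#' sequentially), and `confounded_null` (a shared latent confounder, no causal
#' edge in either direction).
#'
#' @param n_per_regime Number of proteins per regime.
#' @param alpha Effect of standardized BMI on the protein (protein-SD per
#'   BMI-SD). The default 0.25 corresponds to ~0.06 per kg/m2 at a BMI SD of
#'   ~4, inside the range reported for strong BMI-protein associations.
#' @param theta Effect of the protein on BMI (kg/m2 per protein SD).
#' @param delta Cis-pQTL effect (protein-SD per SD of the cis genotype).
#' @return Data.frame with columns `protein_id`, `regime`, `alpha`, `theta`,
#'   `delta`.
#' @export
default_regimes <- function(n_per_regime = 2, alpha = 0.25, theta = 1.2,
                            delta = 0.35) {
  regs <- c("bmi_to_protein", "protein_to_bmi", "bidirectional", "confounded_null")
  regime <- rep(regs, each = n_per_regime)
  data.frame(
    protein_id = sprintf("P%02d_%s", seq_along(regime), regime),
    regime = regime,
    alpha = ifelse(regime %in% c("bmi_to_protein", "bidirectional"), alpha, 0),
    theta = ifelse(regime %in% c("protein_to_bmi", "bidirectional"), theta, 0),
    delta = delta,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Bundles and validates every generative parameter. Defaults emulate the
#' study conditions: 996 samples; a polygenic score explaining ~30% of BMI
#' variance under the linear link (`beta_gps = 2.2` kg/m2 per score SD against
#' a residual SD of 3.25); and a tail-amplified link with `amplification_k = 4`
#' ("almost quadrupled" effects in the extreme tail) hinged at the
#' `amplification_q = 0.92` quantile of the absolute score, just inside the 5%
#' tails. `amplification_k = 1` gives a strictly linear link.
#'
#' @param n_samples Cohort size.
#' @param n_score_variants Variants entering the polygenic score.
#' @param n_cis_variants_per_protein Cis instruments simulated per protein.
#' @param maf_range Allele-frequency bounds.
#' @param mu_bmi Intercept BMI in kg/m2.
#' @param beta_gps Slope of BMI on the (link-transformed) standardized score.
#' @param amplification_k Tail slope multiplier, >= 1.
#' @param amplification_q Quantile of |score| beyond which the slope is
#'   multiplied, in (0, 1).
#' @param beta_age,beta_sex Covariate effects (kg/m2 per year from age 60;
#'   kg/m2 for male sex).
#' @param noise_sd_bmi Residual SD of BMI, > 0.
#' @param protein_noise_sd Residual SD of latent (log2) protein levels, > 0.
#' @param regimes Data.frame as produced by [default_regimes()].
#' @param confound_bmi,confound_protein Loadings of the shared latent
#'   confounder on BMI (kg/m2) and on confounded-null proteins (protein SD).
#' @param log2_offset Constant added to latent protein values before the
#'   exp2 transform, so the emitted matrix is positive.
#' @param seed Integer seed for [simulate_traits()].
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 996,
                       n_score_variants = 100,
                       n_cis_variants_per_protein = 2,
                       maf_range = c(0.05, 0.5),
                       mu_bmi = 27.2,
                       beta_gps = 2.2,
                       amplification_k = 4,
                       amplification_q = 0.92,
                       beta_age = 0.04,
                       beta_sex = 0.5,
                       noise_sd_bmi = 3.25,
                       protein_noise_sd = 1,
                       regimes = default_regimes(),
                       confound_bmi = 2.0,
                       confound_protein = 0.5,
                       log2_offset = 10,
                       seed = 1) {
  cfg <- list(
    n_samples = as.integer(n_samples),
    n_score_variants = as.integer(n_score_variants),
    n_cis_variants_per_protein = as.integer(n_cis_variants_per_protein),
    maf_range = maf_range, mu_bmi = mu_bmi, beta_gps = beta_gps,
    amplification_k = amplification_k, amplification_q = amplification_q,
    beta_age = beta_age, beta_sex = beta_sex,
    noise_sd_bmi = noise_sd_bmi, protein_noise_sd = protein_noise_sd,
    regimes = regimes, confound_bmi = confound_bmi,
    confound_protein = confound_protein,
    log2_offset = log2_offset, seed = as.integer(seed)
  )
  .assert(cfg$n_samples > 0, "sim_config: n_samples must be > 0")
  .assert(cfg$amplification_k >= 1, "sim_config: amplification_k must be >= 1")
  .assert(cfg$amplification_q > 0 && cfg$amplification_q < 1,
          "sim_config: amplification_q must be in (0, 1)")
  .assert(cfg$noise_sd_bmi > 0 && cfg$protein_noise_sd > 0,
          "sim_config: noise SDs must be > 0")
  need <- c("protein_id", "regime", "alpha", "theta", "delta")
  .assert(all(need %in% names(regimes)),
          "sim_config: regimes must have columns %s", paste(need, collapse = ", "))
  known <- c("bmi_to_protein", "protein_to_bmi", "bidirectional", "confounded_null")
  .assert(all(regimes$regime %in% known),
          "sim_config: unknown regime tag(s): %s",
          paste(setdiff(regimes$regime, known), collapse = ", "))
  .assert(!anyNA(regimes$alpha) && !anyNA(regimes$theta) && !anyNA(regimes$delta),
          "sim_config: regimes contain missing effect sizes")
  structure(cfg, class = "sim_config")
}

#' Score slope needed for a target variance explained
#'
#' Returns the `beta_gps` under which a standardized score with a linear link
#' (`amplification_k = 1`) explains fraction `r2` of BMI variance. The
#' variance decomposition of the generative formula includes the covariate
#' effects, the residual noise, the protein feedback terms
#' (`theta^2 * (delta^2 + protein_noise_sd^2)` per protein-to-BMI or
#' bidirectional protein) and the latent-confounder loadings
#' (`confound_bmi^2` per confounded-null protein).
#'
#' @param r2 Target fraction of BMI variance in (0, 1).
#' @param config A [sim_config()].
#' @return The slope (kg/m2 per score SD).
#' @export
gps_slope_for_r2 <- function(r2, config = sim_config()) {
  .assert(r2 > 0 && r2 < 1, "r2 must be in (0, 1)")
  var_age <- config$beta_age^2 * (79 - 43)^2 / 12
  var_sex <- config$beta_sex^2 * 0.48 * 0.52
  reg <- config$regimes
  fb <- reg$regime %in% c("protein_to_bmi", "bidirectional")
  var_feedback <- sum(reg$theta[fb]^2 *
                        (reg$delta[fb]^2 + config$protein_noise_sd^2))
  var_conf <- sum(reg$regime == "confounded_null") * config$confound_bmi^2
  v_other <- var_age + var_sex + var_feedback + var_conf + config$noise_sd_bmi^2
  sqrt(r2 / (1 - r2) * v_other)
}

# Hinge link: identity inside the q-quantile of |s|, slope multiplied by k
# beyond it. k = 1 reduces to the identity for any q.
.hinge_link <- function(s, k, q) {
  qs <- stats::quantile(abs(s), q, names = FALSE)
  ifelse(abs(s) <= qs, s, sign(s) * (qs + k * (abs(s) - qs)))
}

#' Simulate phenotypes, proteins, weights and truth from genotypes
#'
#' Implements the generative model: the true raw score is the weighted dosage
#' sum over the first `n_score_variants` variants; BMI is
#' `mu + beta_gps * L(S) + age/sex effects + noise`, where `L` is the hinge
#' link; proteins are generated per causal regime (see [default_regimes()]),
#' with the bidirectional regime built sequentially (protein seed -> BMI ->
#' final protein) so the truth stays acyclic. The protein matrix is returned
#' on a positive `2^(P + offset)` scale so the log2 preprocessing step of the
#' association pipeline has real work to do.
#'
#' @param geno A `genotype_matrix`; must carry at least
#'   `n_score_variants + n_proteins * n_cis_variants_per_protein` variants.
#' @param config A [sim_config()].
#' @return A list of class `synthetic_cohort` with elements `phenotypes`
#'   (data.frame: sample_id, bmi, age, sex, smoking, alcohol,
#'   physical_activity, diabetes), `proteins` (positive samples x proteins
#'   matrix), `weights` (variant_id, effect_allele, weight), `truth`
#'   (per-protein regime, alpha, theta, delta, comma-separated cis ids) and
#'   `score_true` (the standardized generative score).
#' @export
simulate_traits <- function(geno, config = sim_config()) {
  .assert(inherits(geno, "genotype_matrix"), "geno must be a genotype_matrix")
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  n <- length(geno$sample_ids)
  reg <- config$regimes
  n_prot <- nrow(reg)
  n_cis <- config$n_cis_variants_per_protein
  need_var <- config$n_score_variants + n_prot * n_cis
  .assert(ncol(geno$dosages) >= need_var,
          "genotype matrix has %d variants but %d are needed (%d score + %d x %d cis)",
          ncol(geno$dosages), need_var, config$n_score_variants, n_prot, n_cis)
  set.seed(config$seed)

  score_idx <- seq_len(config$n_score_variants)
  w <- stats::rnorm(config$n_score_variants)
  s_raw <- drop(geno$dosages[, score_idx, drop = FALSE] %*% w)
  s <- standardize(s_raw, "raw polygenic score")
  l <- .hinge_link(s, config$amplification_k, config$amplification_q)

  age <- stats::runif(n, 43, 79)
  sex <- stats::rbinom(n, 1, 0.48)
  bmi <- config$mu_bmi + config$beta_gps * l +
    config$beta_age * (age - 60) + config$beta_sex * sex +
    stats::rnorm(n, 0, config$noise_sd_bmi)

  # cis genotype (standardized dosage sum) per protein
  cis_ids <- vector("list", n_prot)
  g_cis <- matrix(0, n, n_prot)
  for (i in seq_len(n_prot)) {
    idx <- config$n_score_variants + ((i - 1) * n_cis + 1):(i * n_cis)
    cis_ids[[i]] <- geno$variants$variant_id[idx]
    g_cis[, i] <- standardize(rowSums(geno$dosages[, idx, drop = FALSE]),
                              paste0("cis genotype of ", reg$protein_id[i]))
  }

  # protein seeds that feed back into BMI, and latent confounders
  p0 <- matrix(NA_real_, n, n_prot)
  u <- matrix(NA_real_, n, n_prot)
  for (i in seq_len(n_prot)) {
    if (reg$regime[i] %in% c("protein_to_bmi", "bidirectional")) {
      p0[, i] <- reg$delta[i] * g_cis[, i] +
        stats::rnorm(n, 0, config$protein_noise_sd)
      bmi <- bmi + reg$theta[i] * p0[, i]
    } else if (reg$regime[i] == "confounded_null") {
      u[, i] <- stats::rnorm(n)
      bmi <- bmi + config$confound_bmi * u[, i]
    }
  }
  z_bmi <- standardize(bmi, "bmi")

  prot <- matrix(NA_real_, n, n_prot,
                 dimnames = list(geno$sample_ids, reg$protein_id))
  for (i in seq_len(n_prot)) {
    prot[, i] <- switch(
      reg$regime[i],
      bmi_to_protein = reg$alpha[i] * z_bmi + reg$delta[i] * g_cis[, i] +
        stats::rnorm(n, 0, config$protein_noise_sd),
      protein_to_bmi = p0[, i],
      bidirectional = p0[, i] + reg$alpha[i] * z_bmi,
      confounded_null = config$confound_protein * u[, i] +
        reg$delta[i] * g_cis[, i] + stats::rnorm(n, 0, config$protein_noise_sd)
    )
  }

  phenotypes <- data.frame(
    sample_id = geno$sample_ids,
    bmi = bmi,
    age = age,
    sex = sex,
    smoking = stats::rbinom(n, 1, 0.2),
    alcohol = stats::rbinom(n, 1, 0.5),
    physical_activity = stats::rbinom(n, 1, 0.4),
    diabetes = stats::rbinom(n, 1, 0.1),
    stringsAsFactors = FALSE
  )
  weights <- data.frame(
    variant_id = geno$variants$variant_id[score_idx],
    effect_allele = geno$variants$effect_allele[score_idx],
    weight = w,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(
    protein_id = reg$protein_id,
    regime = reg$regime,
    alpha = reg$alpha,
    theta = reg$theta,
    delta = reg$delta,
    cis_variants = vapply(cis_ids, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  structure(
    list(phenotypes = phenotypes,
         proteins = 2^(prot + config$log2_offset),
         weights = weights,
         truth = truth,
         score_true = s),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d samples, %d proteins (%s)\n",
              nrow(x$phenotypes), ncol(x$proteins),
              paste(sort(unique(x$truth$regime)), collapse = ", ")))
  invisible(x)
}

#' Simulate a catalog of variant-confounder associations
#'
#' Produces one (variant, trait, p) row per variant x trait combination.
#' Variants named in `planted` are given genome-wide-significant p-values
#' (below `planted_p_max`) for every listed trait; all other p-values are
#' drawn well above the exclusion threshold.
#'
#' @param geno A `genotype_matrix`.
#' @param confounder_traits Character vector of trait names (non-empty).
#' @param seed Integer seed.
#' @param planted Character vector of variant ids to plant as
#'   confounder-associated (default none).
#' @param planted_p_max Upper bound for planted p-values.
#' @return Data.frame with columns `variant_id`, `trait`, `p`.
#' @export
make_confounder_catalog <- function(geno, confounder_traits, seed,
                                    planted = character(0),
                                    planted_p_max = 1e-9) {
  .assert(inherits(geno, "genotype_matrix"), "geno must be a genotype_matrix")
  .assert(length(confounder_traits) >= 1, "confounder_traits must be non-empty")
  .assert(all(planted %in% geno$variants$variant_id),
          "planted ids not in genotype matrix: %s",
          paste(setdiff(planted, geno$variants$variant_id), collapse = ", "))
  set.seed(seed)
  grid <- expand.grid(variant_id = geno$variants$variant_id,
                      trait = confounder_traits,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p <- stats::runif(nrow(grid), 0.01, 1)
  hit <- grid$variant_id %in% planted
  p[hit] <- 10^stats::runif(sum(hit), -12, log10(planted_p_max))
  grid$p <- p
  grid
}

#' Simulate two-sample MR summary statistics
#'
#' Generates per-SNP exposure and outcome summary statistics under a known
#' causal effect `theta` with no pleiotropy: true exposure effects are drawn
#' uniformly, observed exposure betas add `N(0, se_exposure)` noise, and
#' outcome betas are `theta * true effect + N(0, se_outcome)` (+ an optional
#' constant directional-pleiotropy term). Used for calibration studies of the
#' inverse-variance-weighted and MR-Egger estimators.
#'
#' @param n_snps Number of instruments.
#' @param theta True causal effect.
#' @param seed Integer seed.
#' @param beta_range Range of true exposure effects (positive).
#' @param se_exposure,se_outcome Per-SNP standard errors.
#' @param pleiotropy Constant added to every outcome beta (Egger intercept).
#' @return Data.frame with the harmonized summary-statistic columns used by
#'   [ivw()] and [mr_egger()].
#' @export
simulate_mr_summary <- function(n_snps, theta, seed,
                                beta_range = c(0.05, 0.15),
                                se_exposure = 0.002, se_outcome = 0.05,
                                pleiotropy = 0) {
  .assert(n_snps >= 1, "n_snps must be >= 1")
  set.seed(seed)
  bx_true <- stats::runif(n_snps, beta_range[1], beta_range[2])
  bx <- bx_true + stats::rnorm(n_snps, 0, se_exposure)
  by <- pleiotropy + theta * bx_true + stats::rnorm(n_snps, 0, se_outcome)
  sx <- rep(se_exposure, n_snps)
  data.frame(
    variant_id = paste0("snp", seq_len(n_snps)),
    effect_allele = "A", other_allele = "G",
    beta_exposure = bx, se_exposure = sx,
    p_exposure = 2 * stats::pnorm(-abs(bx / sx)),
    beta_outcome = by, se_outcome = rep(se_outcome, n_snps),
    f_stat = (bx / sx)^2,
    stringsAsFactors = FALSE
  )
}
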