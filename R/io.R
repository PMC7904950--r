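# Readers, writers and the pipeline orchestrator
#
# Everything on disk is tab-separated with a header row, UTF-8, '.' decimal
# separator. Readers validate the header against the documented schema and
# reject out-of-range values with row/column context.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

.read_tsv <- function(path, required = NULL) {
  .assert(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    .assert(length(missing) == 0, "%s: missing required column(s): %s",
            path, paste(missing, collapse = ", "))
  }
  df
}

#' Write a synthetic cohort (and its genotypes) as a TSV bundle
#'
#' Emits `dosages.tsv` (first column `sample_id`, one column per variant),
#' `variants.tsv`, `phenotypes.tsv`, `proteins.tsv`, `weights.tsv` and
#' `truth.tsv` into `dir`.
#'
#' @param cohort A `synthetic_cohort` from [simulate_traits()].
#' @param geno The `genotype_matrix` the cohort was generated from.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_cohort <- function(cohort, geno, dir) {
  .assert(inherits(cohort, "synthetic_cohort"), "cohort must be a synthetic_cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    dosages = file.path(dir, "dosages.tsv"),
    variants = file.path(dir, "variants.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    proteins = file.path(dir, "proteins.tsv"),
    weights = file.path(dir, "weights.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  .write_tsv(data.frame(sample_id = geno$sample_ids, geno$dosages,
                        check.names = FALSE), paths["dosages"])
  .write_tsv(geno$variants, paths["variants"])
  .write_tsv(cohort$phenotypes, paths["phenotypes"])
  .write_tsv(data.frame(sample_id = rownames(cohort$proteins), cohort$proteins,
                        check.names = FALSE), paths["proteins"])
  .write_tsv(cohort$weights, paths["weights"])
  .write_tsv(cohort$truth, paths["truth"])
  invisible(paths)
}

#' Read a dosage + variant-metadata bundle into a genotype matrix
#'
#' Validates the schema: the dosage file's variant columns must match the
#' metadata rows one-to-one, dosages must lie in [0, 2] (violations are
#' reported with sample and variant), and alleles must be single A/C/G/T
#' bases.
#'
#' @param dosage_path TSV with first column `sample_id`, then one numeric
#'   column per variant.
#' @param variants_path TSV with `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `maf`.
#' @return A `genotype_matrix`.
#' @export
read_dosage_bundle <- function(dosage_path, variants_path) {
  dos <- .read_tsv(dosage_path, required = "sample_id")
  meta <- .read_tsv(variants_path,
                    required = c("variant_id", "chrom", "pos",
                                 "effect_allele", "other_allele", "maf"))
  meta$chrom <- as.character(meta$chrom)
  .validate_variant_specs(meta)
  var_cols <- setdiff(names(dos), "sample_id")
  missing <- setdiff(meta$variant_id, var_cols)
  .assert(length(missing) == 0,
          "variant(s) in metadata absent from dosage header: %s",
          paste(missing, collapse = ", "))
  extra <- setdiff(var_cols, meta$variant_id)
  .assert(length(extra) == 0,
          "dosage column(s) absent from variant metadata: %s",
          paste(extra, collapse = ", "))
  m <- as.matrix(dos[, meta$variant_id, drop = FALSE])
  .assert(is.numeric(m), "dosage columns must be numeric")
  bad <- which(m < 0 | m > 2 | !is.finite(m), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("dosage out of [0, 2] at sample '%s', variant '%s' (value %s)",
                 dos$sample_id[bad[1, 1]], meta$variant_id[bad[1, 2]],
                 format(m[bad[1, , drop = FALSE]])), call. = FALSE)
  }
  rownames(m) <- dos$sample_id
  structure(list(sample_ids = dos$sample_id, variants = meta, dosages = m),
            class = "genotype_matrix")
}

#' Read a protein matrix written by [write_cohort()]
#' @param path TSV with first column `sample_id`, one column per protein.
#' @return Samples x proteins numeric matrix with sample-id rownames.
#' @export
read_protein_matrix <- function(path) {
  df <- .read_tsv(path, required = "sample_id")
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(m) <- df$sample_id
  m
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates the stages end-to-end: cohort generation (discovery and
#' replication), protein preprocessing, the BMI association scan (basic
#' age+sex model and the full sensitivity model), replication assessment,
#' replication power (p95) for the top associations, polygenic-score
#' computation and the score-protein scan, tail analysis with decile
#' summaries and protein classification, the bidirectional MR report, and a
#' bicor screen of the proteins against the quantitative traits. All stage
#' outputs are written as TSV under `out_dir` together with a JSON run
#' manifest (seed, thresholds, package version, input checksums). The run is
#' deterministic for a fixed config.
#'
#' @param config Named list; see [default_run_config()] for the fields and
#'   defaults. Unknown fields are rejected.
#' @return Invisibly, a named list with every stage's in-memory result and
#'   the manifest.
#' @export
run_pipeline <- function(config = default_run_config()) {
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  .assert(length(unknown) == 0, "unknown config field(s): %s",
          paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  .assert(!is.null(cfg$out_dir), "config$out_dir is required")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- sim_config(n_samples = cfg$n_samples,
                    n_score_variants = cfg$n_score_variants,
                    regimes = cfg$regimes, seed = cfg$seed)
  n_var <- sim$n_score_variants +
    nrow(sim$regimes) * sim$n_cis_variants_per_protein
  specs <- variant_specs(n_var, seed = cfg$seed)
  geno <- simulate_genotypes(sim$n_samples, specs, seed = cfg$seed + 1)
  cohort <- simulate_traits(geno, sim)
  write_cohort(cohort, geno, file.path(cfg$out_dir, "cohort"))

  # independent replication cohort, same generative truth
  sim_rep <- sim
  sim_rep$n_samples <- as.integer(cfg$n_replication)
  sim_rep$seed <- as.integer(cfg$seed + 1000)
  geno_rep <- simulate_genotypes(cfg$n_replication, specs, seed = cfg$seed + 1001)
  cohort_rep <- simulate_traits(geno_rep, sim_rep)

  prot <- preprocess_proteins(cohort$proteins)
  prot_rep <- preprocess_proteins(cohort_rep$proteins)
  ph <- cohort$phenotypes
  cov_basic <- ph[, c("age", "sex")]
  cov_full <- ph[, c("age", "sex", "smoking", "alcohol",
                     "physical_activity", "diabetes")]

  scan_bmi <- association_scan(prot, ph$bmi, cov_basic, "bmi", model = "basic")
  scan_full <- association_scan(prot, ph$bmi, cov_full, "bmi", model = "full")
  scan_rep <- association_scan(prot_rep, cohort_rep$phenotypes$bmi,
                               cohort_rep$phenotypes[, c("age", "sex")], "bmi",
                               model = "replication")
  alpha_scan <- bonferroni_threshold(0.05, ncol(prot))
  hits <- scan_bmi[scan_bmi$p < alpha_scan, , drop = FALSE]
  repl <- assess_replication(hits, scan_rep, alpha = 0.05)

  power <- do.call(rbind, lapply(seq_len(nrow(hits)), function(i) {
    pid <- hits$protein_id[i]
    cbind(protein_id = pid,
          subsample_power(prot[, pid], ph$bmi, as.matrix(cov_basic),
                          n_sub = min(cfg$n_power_sub, nrow(ph)),
                          reps = cfg$n_power_reps, seed = cfg$seed + 2))
  }))

  gps <- compute_gps(geno, cohort$weights)
  scan_gps <- association_scan(prot, gps$standardized_score, cov_basic, "gps")
  tails <- do.call(rbind, lapply(colnames(prot), function(pid) {
    tail_regression(prot[, pid], gps$standardized_score, as.matrix(cov_basic),
                    p = 5, y_name = pid)
  }))
  deciles <- decile_summary(ph$bmi, gps$standardized_score)
  classes <- classify_proteins(scan_bmi, scan_gps, tails, alpha_scan)

  mr_report <- run_bidirectional(geno, ph, prot, gps, cohort$truth)

  screen <- bicor_screen(t(prot), t(as.matrix(ph[, c("bmi", "age")])))

  outputs <- list(scan_bmi = scan_bmi, scan_full = scan_full,
                  scan_replication = scan_rep, replication = repl,
                  power = power, scan_gps = scan_gps, tails = tails,
                  deciles = deciles, classes = classes, mr = mr_report,
                  screen = screen)
  for (nm in names(outputs)) {
    .write_tsv(outputs[[nm]], file.path(cfg$out_dir, paste0(nm, ".tsv")))
  }
  cohort_files <- list.files(file.path(cfg$out_dir, "cohort"), full.names = TRUE)
  manifest <- list(
    package = "proteogps",
    version = as.character(utils::packageVersion("proteogps")),
    seed = cfg$seed,
    n_samples = cfg$n_samples,
    n_replication = cfg$n_replication,
    alpha_scan = alpha_scan,
    stages = names(outputs),
    input_md5 = as.list(tools::md5sum(cohort_files))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(outputs, list(manifest = manifest, gps = gps, cohort = cohort,
                            geno = geno)))
}

#' Default pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Integer seed used by every stochastic stage.
#' @param n_samples,n_replication Discovery and replication cohort sizes.
#' @param n_score_variants Variants in the polygenic score.
#' @param regimes Per-protein causal-regime table ([default_regimes()]).
#' @param n_power_sub,n_power_reps Subsample size and repetitions for the
#'   p95 power stage.
#' @return Named list of configuration fields.
#' @export
default_run_config <- function(out_dir = tempfile("proteogps_run_"), seed = 1,
                               n_samples = 996, n_replication = 356,
                               n_score_variants = 100,
                               regimes = default_regimes(),
                               n_power_sub = 356, n_power_reps = 200) {
  list(out_dir = out_dir, seed = as.integer(seed),
       n_samples = as.integer(n_samples),
       n_replication = as.integer(n_replication),
       n_score_variants = as.integer(n_score_variants),
       regimes = regimes,
       n_power_sub = as.integer(n_power_sub),
       n_power_reps = as.integer(n_power_reps))
}
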