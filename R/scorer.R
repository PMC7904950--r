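# Genome-wide polygenic score computation
#
# A score is the weighted sum of counted-allele dosages over the variants of
# a weight table, after harmonizing each weight row against the genotype
# metadata: strand-ambiguous (palindromic) variants are excluded, rows whose
# effect allele matches the dosage-counted allele contribute directly, and
# rows matching the other allele contribute via the complementary dosage
# (2 - dosage).

#' Harmonize a weight table against genotype metadata
#'
#' Retains weight rows whose `variant_id` exists in the genotype metadata and
#' whose allele pair is resolvable: palindromic variants (A/T or C/G in the
#' genotype metadata) are dropped as strand-ambiguous; for the rest the
#' orientation is `DIRECT` when the weight's effect allele equals the
#' dosage-counted allele and `FLIP` when it equals the other allele. Rows
#' matching neither allele are dropped and counted. Nothing here is fatal:
#' every exclusion is reported, not raised.
#'
#' @param variants Variant metadata data.frame (columns `variant_id`,
#'   `effect_allele`, `other_allele`, ...).
#' @param weights Data.frame with columns `variant_id`, `effect_allele`,
#'   `weight`.
#' @return A list with `weights` (the retained rows plus an `orientation`
#'   column) and `report` (counts: `n_input`, `n_retained`,
#'   `n_dropped_ambiguous`, `n_dropped_unmatched`).
#' @export
harmonize_weights <- function(variants, weights) {
  .assert(nrow(variants) >= 1 && nrow(weights) >= 1,
          "harmonize_weights: variants and weights must be non-empty")
  need <- c("variant_id", "effect_allele", "weight")
  .assert(all(need %in% names(weights)),
          "weights must have columns: %s", paste(need, collapse = ", "))
  .assert(all(is.finite(weights$weight)), "weights must be finite")
  .assert(!anyDuplicated(weights$variant_id), "duplicate variant_id in weights")

  idx <- match(weights$variant_id, variants$variant_id)
  present <- !is.na(idx)
  ea <- variants$effect_allele[idx]
  oa <- variants$other_allele[idx]
  ambiguous <- present & .is_palindromic(ifelse(present, ea, "A"),
                                         ifelse(present, oa, "C"))
  direct <- present & !ambiguous & weights$effect_allele == ea
  flip <- present & !ambiguous & weights$effect_allele == oa
  unmatched <- (!present) | (present & !ambiguous & !direct & !flip)

  kept <- weights[direct | flip, , drop = FALSE]
  kept$orientation <- ifelse(direct[direct | flip], "DIRECT", "FLIP")
  rownames(kept) <- NULL
  list(
    weights = kept,
    report = list(
      n_input = nrow(weights),
      n_retained = nrow(kept),
      n_dropped_ambiguous = sum(ambiguous),
      n_dropped_unmatched = sum(unmatched)
    )
  )
}

#' Compute a polygenic score from dosages and weights
#'
#' The raw score per sample is `sum_v w_v * d*_{s,v}` with `d* = dosage` for
#' `DIRECT` rows and `2 - dosage` for `FLIP` rows. An optional exclusion locus
#' removes all variants on the locus chromosome whose position lies within
#' `window_bp` of the gene interval (boundary-anchored, same chromosome only;
#' default 100 Mb) -- used to show an association is polygenic rather than
#' driven by cis effects near the encoding gene. The standardized score is
#' `(raw - mean) / sd` with the sample SD.
#'
#' @param geno A `genotype_matrix`.
#' @param weights Weight table; harmonized internally unless it already
#'   carries an `orientation` column (as returned by [harmonize_weights()]).
#' @param exclude Optional gene locus: a list or one-row data.frame with
#'   `gene`, `chrom`, `start`, `end` (1-based inclusive).
#' @param window_bp Exclusion window around the locus, default 1e8 (100 Mb).
#' @return An object of class `gps_vector`: list with `sample_ids`,
#'   `raw_score`, `standardized_score`, `n_variants_used` and drop counts
#'   (`n_dropped_ambiguous`, `n_dropped_unmatched`, `n_dropped_cis`).
#' @export
compute_gps <- function(geno, weights, exclude = NULL, window_bp = 1e8) {
  .assert(inherits(geno, "genotype_matrix"), "geno must be a genotype_matrix")
  if (is.null(weights$orientation)) {
    h <- harmonize_weights(geno$variants, weights)
    weights <- h$weights
    rep_amb <- h$report$n_dropped_ambiguous
    rep_unm <- h$report$n_dropped_unmatched
  } else {
    rep_amb <- 0L
    rep_unm <- 0L
  }

  n_cis <- 0L
  if (!is.null(exclude)) {
    exclude <- as.list(exclude)
    .assert(all(c("chrom", "start", "end") %in% names(exclude)),
            "exclude locus needs chrom, start, end")
    .assert(exclude$start <= exclude$end, "exclude locus start must be <= end")
    meta <- geno$variants[match(weights$variant_id, geno$variants$variant_id), ]
    in_win <- meta$chrom == as.character(exclude$chrom) &
      meta$pos >= (exclude$start - window_bp) &
      meta$pos <= (exclude$end + window_bp)
    n_cis <- sum(in_win)
    weights <- weights[!in_win, , drop = FALSE]
  }
  .assert(nrow(weights) > 0, "compute_gps: zero usable variants after exclusions")

  d <- geno$dosages[, weights$variant_id, drop = FALSE]
  w <- weights$weight
  flip <- weights$orientation == "FLIP"
  # flipped rows contribute w * (2 - dosage) = 2w - w * dosage
  w_signed <- ifelse(flip, -w, w)
  raw <- drop(d %*% w_signed) + 2 * sum(w[flip])
  std <- standardize(raw, "raw polygenic score")
  structure(
    list(sample_ids = geno$sample_ids,
         raw_score = raw,
         standardized_score = std,
         n_variants_used = nrow(weights),
         n_dropped_ambiguous = rep_amb,
         n_dropped_unmatched = rep_unm,
         n_dropped_cis = n_cis),
    class = "gps_vector"
  )
}

#' @export
print.gps_vector <- function(x, ...) {
  cat(sprintf(paste0("gps_vector: %d samples, %d variants used ",
                     "(%d ambiguous, %d unmatched, %d cis-excluded dropped)\n"),
              length(x$sample_ids), x$n_variants_used,
              x$n_dropped_ambiguous, x$n_dropped_unmatched, x$n_dropped_cis))
  invisible(x)
}

#' @export
as.data.frame.gps_vector <- function(x, ...) {
  data.frame(sample_id = x$sample_ids,
             raw_score = x$raw_score,
             standardized_score = x$standardized_score,
             stringsAsFactors = FALSE)
}
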