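# Biweight midcorrelation screen
#
# Robust (median/MAD-based) correlation of expression levels against
# quantitative traits, with joint retention thresholds on |r| and p.

#' Biweight midcorrelation
#'
#' Median-based robust correlation: deviations from the median are scaled by
#' nine times the (unscaled) median absolute deviation, downweighted by the
#' Tukey biweight `(1 - u^2)^2` (zero beyond |u| = 1), and correlated. Less
#' sensitive to outliers than the Pearson correlation. When either vector
#' has zero MAD (more than half its values tied at the median) the function
#' falls back to the Pearson correlation with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return A correlation in [-1, 1].
#' @examples
#' x <- rnorm(100)
#' bicor(x, x) # exactly 1
#' @export
bicor <- function(x, y) {
  .assert(length(x) == length(y), "bicor: length mismatch (%d vs %d)",
          length(x), length(y))
  .assert(length(x) >= 4, "bicor: need at least 4 observations")
  .assert(!anyNA(x) && !anyNA(y), "bicor: missing values not supported")
  weighted_dev <- function(v, label) {
    med <- stats::median(v)
    mad0 <- stats::median(abs(v - med)) # unscaled MAD, no consistency factor
    if (mad0 == 0) return(NULL)
    u <- (v - med) / (9 * mad0)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    d <- (v - med) * w
    if (all(d == 0)) {
      stop(sprintf("bicor: all biweights zero for %s (degenerate vector)", label),
           call. = FALSE)
    }
    d
  }
  xt <- weighted_dev(x, "x")
  yt <- weighted_dev(y, "y")
  if (is.null(xt) || is.null(yt)) {
    warning("bicor: zero median absolute deviation; falling back to Pearson correlation")
    return(stats::cor(x, y))
  }
  sum(xt * yt) / (sqrt(sum(xt^2)) * sqrt(sum(yt^2)))
}

#' Screen expression levels against traits by biweight midcorrelation
#'
#' Scores every gene x trait pair with [bicor()]; p-values use the t
#' approximation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom (two-sided). A pair is retained when `|bicor| > r_min` AND
#' `p < alpha` (joint rule). Significance tiers: `***` p < 0.001, `**`
#' p < 0.01, `*` p < 0.05.
#'
#' @param expr Genes x samples numeric matrix (rownames = genes).
#' @param traits Traits x samples numeric matrix (rownames = traits).
#' @param r_min Minimum absolute correlation (default 0.1).
#' @param alpha Maximum p-value (default 0.05).
#' @return Data.frame with `gene`, `trait`, `bicor`, `p`, `n`, `retained`,
#'   `stars`.
#' @export
bicor_screen <- function(expr, traits, r_min = 0.1, alpha = 0.05) {
  .assert(is.matrix(expr) && is.matrix(traits), "expr and traits must be matrices")
  .assert(ncol(expr) == ncol(traits),
          "expr and traits must share samples (columns): %d vs %d",
          ncol(expr), ncol(traits))
  n <- ncol(expr)
  .assert(n >= 4, "bicor_screen: fewer than 4 shared samples")
  genes <- rownames(expr); if (is.null(genes)) genes <- paste0("gene", seq_len(nrow(expr)))
  trs <- rownames(traits); if (is.null(trs)) trs <- paste0("trait", seq_len(nrow(traits)))
  grid <- expand.grid(gene = genes, trait = trs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  r <- mapply(function(g, tr) bicor(expr[match(g, genes), ], traits[match(tr, trs), ]),
              grid$gene, grid$trait)
  r <- pmin(1, pmax(-1, unname(r)))
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), n - 2)
  grid$bicor <- r
  grid$p <- p
  grid$n <- n
  grid$retained <- abs(r) > r_min & p < alpha
  grid$stars <- ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "")))
  grid
}
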