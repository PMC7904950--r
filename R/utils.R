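#' @keywords internal
"_PACKAGE"

# Internal validation helpers. All user-facing errors are signalled with
# stop(..., call. = FALSE) and carry enough context to locate the offending
# column/row.

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

.is_base <- function(x) is.character(x) & nchar(x) == 1L & x %in% c("A", "C", "G", "T")

# Palindromic (strand-ambiguous) allele pair: A/T or C/G.
.is_palindromic <- function(a1, a2) {
  p <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  p %in% c("A/T", "C/G")
}

#' Standardize a numeric vector to mean 0, sample SD 1
#'
#' Uses the sample standard deviation (n - 1 denominator), so
#' `standardize(c(1, 2, 3))` is exactly `c(-1, 0, 1)`.
#'
#' @param x Numeric vector, length >= 2.
#' @param name Label used in error messages (e.g. the column being scaled).
#' @return Numeric vector with mean 0 and sample SD 1.
#' @examples
#' standardize(c(1, 2, 3))
#' @export
standardize <- function(x, name = "values") {
  .assert(is.numeric(x), "standardize: '%s' must be numeric", name)
  .assert(length(x) >= 2L, "standardize: '%s' must have length >= 2", name)
  .assert(!anyNA(x), "standardize: '%s' contains missing values", name)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    stop(sprintf("standardize: zero variance in '%s'", name), call. = FALSE)
  }
  (x - mean(x)) / s
}

# z-score the columns of a numeric matrix (sample SD); errors name the column.
.standardize_cols <- function(m, what = "column") {
  out <- m
  for (j in seq_len(ncol(m))) {
    nm <- if (!is.null(colnames(m))) colnames(m)[j] else as.character(j)
    out[, j] <- standardize(m[, j], name = paste0(what, " '", nm, "'"))
  }
  out
}

# (X'X)^-1 from a full-rank QR decomposition, in original column order
# (chol2inv of qr.R is in pivoted order).
.xtx_inverse <- function(qrx) {
  inv_p <- chol2inv(qr.R(qrx))
  piv <- qrx$pivot
  out <- inv_p
  out[piv, piv] <- inv_p
  out
}

# Coerce covariates (NULL, vector, matrix, data.frame) to a numeric matrix
# with column names; NULL -> zero-column matrix.
.as_covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  if (is.data.frame(covariates)) covariates <- as.matrix(covariates)
  if (is.vector(covariates) && is.numeric(covariates)) {
    covariates <- matrix(covariates, ncol = 1,
                         dimnames = list(NULL, "covariate"))
  }
  .assert(is.matrix(covariates) && is.numeric(covariates),
          "covariates must be numeric (vector, matrix or data.frame)")
  .assert(nrow(covariates) == n,
          "covariates have %d rows but %d samples expected", nrow(covariates), n)
  if (is.null(colnames(covariates))) {
    colnames(covariates) <- paste0("covariate", seq_len(ncol(covariates)))
  }
  covariates
}
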