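# Core four-state Beta-Uniform mixture machinery.
#
# Per-SNP latent state l ranges over {00, 10, 01, 11}: null/null,
# non-null for trait 1 only, non-null for trait 2 only, non-null for both.
# Column order of every M x 4 matrix in the package is fixed as
# (00, 10, 01, 11).

STATE_LABELS <- c("z00", "z10", "z01", "z11")

# p-values of exactly 0 are clipped here so log(y) and y^(alpha-1) stay finite
PVALUE_MIN <- 1e-30
# raw alpha estimates >= 1 are capped so the Beta(alpha, 1) density keeps its
# enrichment near 0
ALPHA_MAX <- 0.999
# floor applied to E-step normalizers and log arguments
LIK_FLOOR <- 1e-300

#' Validate and normalize a matrix of GWAS association p-values
#'
#' Coerces the input to a numeric matrix with two trait columns and row names
#' giving SNP identifiers. P-values equal to zero are clipped to `1e-30` (with
#' a warning) so the Beta(alpha, 1) log-density stays finite; values outside
#' `[0, 1]` are rejected.
#'
#' @param x A numeric M x 2 matrix or data frame of p-values; row names (or a
#'   `snp_id` column in a data frame) identify SNPs.
#' @return A numeric M x 2 matrix with entries in `(0, 1]`, row names set to
#'   SNP identifiers and column names `p1`, `p2`.
#' @export
as_gwas_pvalues <- function(x) {
  if (is.data.frame(x)) {
    if ("snp_id" %in% names(x)) {
      ids <- as.character(x$snp_id)
      x <- x[, setdiff(names(x), "snp_id"), drop = FALSE]
      x <- as.matrix(x)
      rownames(x) <- ids
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop("p-values must be a numeric matrix or data frame")
  if (ncol(x) != 2L)
    stop("exactly two trait columns are required (got ", ncol(x), ")")
  if (nrow(x) < 1L)
    stop("at least one SNP is required")
  if (anyNA(x))
    stop("p-values contain missing values")
  if (any(x < 0) || any(x > 1))
    stop("p-values must lie in [0, 1]")
  nzero <- sum(x == 0)
  if (nzero > 0) {
    warning(nzero, " p-value(s) equal to 0 clipped to ", PVALUE_MIN)
    x[x == 0] <- PVALUE_MIN
  }
  if (is.null(rownames(x)))
    rownames(x) <- paste0("snp", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x)))
    stop("SNP identifiers must be unique")
  colnames(x) <- c("p1", "p2")
  x
}

#' Validate a binary functional annotation matrix
#'
#' @param x A numeric or logical M x K matrix (or data frame, optionally with a
#'   `snp_id` column) with entries in `{0, 1}`.
#' @return An integer M x K matrix with 0/1 entries, SNP identifiers as row
#'   names and annotation names as column names (`A1..AK` if unnamed).
#' @export
as_annotation_matrix <- function(x) {
  if (is.data.frame(x)) {
    if ("snp_id" %in% names(x)) {
      ids <- as.character(x$snp_id)
      x <- x[, setdiff(names(x), "snp_id"), drop = FALSE]
      x <- as.matrix(x)
      rownames(x) <- ids
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.matrix(x))
    stop("annotations must be a matrix or data frame")
  storage.mode(x) <- "double"
  if (anyNA(x))
    stop("annotations contain missing values")
  bad <- which(x != 0 & x != 1)
  if (length(bad) > 0) {
    i <- arrayInd(bad[1L], dim(x))
    stop("annotation entries must be 0 or 1; first offending cell at row ",
         i[1L], ", column ", i[2L])
  }
  if (is.null(rownames(x)))
    rownames(x) <- paste0("snp", seq_len(nrow(x)))
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- paste0("A", seq_len(ncol(x)))
  x
}

#' Beta(alpha, 1) density
#'
#' Density `alpha * y^(alpha - 1)` on `(0, 1]`. For `alpha < 1` it is
#' decreasing in `y`, concentrating mass near 0 — the working model for
#' p-values of risk-associated SNPs.
#'
#' @param y P-values in `(0, 1]` (vectorized).
#' @param alpha Shape parameter in `(0, 1)`.
#' @return Density values, strictly positive.
#' @export
beta_dens <- function(y, alpha) {
  if (any(y <= 0) || any(y > 1))
    stop("y must lie in (0, 1]")
  if (length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be a scalar in (0, 1)")
  alpha * y^(alpha - 1)
}

# M x 4 emission matrix: P(Y_i1, Y_i2 | Z_il = 1) for l in (00, 10, 01, 11).
# Conditional on the state, the two p-values are independent, so the state-11
# column is the product of the two marginal non-null densities.
emission_matrix <- function(pvals, alpha) {
  b1 <- beta_dens(pvals[, 1L], alpha[1L])
  b2 <- beta_dens(pvals[, 2L], alpha[2L])
  E <- cbind(1, b1, b2, b1 * b2)
  colnames(E) <- STATE_LABELS
  E
}

joint_emission <- function(y1, y2, alpha) {
  c(1,
    beta_dens(y1, alpha[1L]),
    beta_dens(y2, alpha[2L]),
    beta_dens(y1, alpha[1L]) * beta_dens(y2, alpha[2L]))
}

#' E-step: posterior state responsibilities
#'
#' Computes `z_il = pi_il P(Y_i | Z_il = 1) / sum_l' pi_il' P(Y_i | Z_il' = 1)`
#' for each SNP. Row normalizers are floored at `1e-300` to avoid division by
#' an underflowed zero.
#'
#' @param pvals M x 2 matrix from [as_gwas_pvalues()].
#' @param prior M x 4 matrix of prior state probabilities (rows sum to 1).
#' @param alpha Length-2 vector of Beta shape parameters.
#' @return M x 4 matrix of responsibilities; every row sums to 1.
#' @export
e_step <- function(pvals, prior, alpha) {
  E <- emission_matrix(pvals, alpha)
  num <- prior * E
  norm <- pmax(rowSums(num), LIK_FLOOR)
  num / norm
}

#' Closed-form update of the Beta shape parameters
#'
#' Weighted maximum-likelihood update
#' `alpha_d = -sum_i w_id / sum_i w_id log(y_id)` with `w_i1 = z_i10 + z_i11`
#' and `w_i2 = z_i01 + z_i11`. Raw estimates at or above 1 are capped at
#' 0.999 so the density keeps its enrichment near zero.
#'
#' @param pvals M x 2 p-value matrix.
#' @param post M x 4 posterior responsibility matrix.
#' @return Length-2 numeric vector `c(alpha1, alpha2)`.
#' @export
update_alpha <- function(pvals, post) {
  w1 <- post[, 2L] + post[, 4L]
  w2 <- post[, 3L] + post[, 4L]
  if (sum(w1) <= 0 || sum(w2) <= 0)
    stop("degenerate responsibilities: no weight on non-null states")
  a1 <- -sum(w1) / sum(w1 * log(pvals[, 1L]))
  a2 <- -sum(w2) / sum(w2 * log(pvals[, 2L]))
  pmin(pmax(c(a1, a2), 1e-6), ALPHA_MAX)
}

#' Incomplete-data log-likelihood
#'
#' `sum_i log sum_l pi_il P(Y_i1, Y_i2 | Z_il = 1)`, the objective monitored
#' for EM convergence. The inner sum is floored at `1e-300`.
#'
#' @inheritParams e_step
#' @return A finite scalar.
#' @export
incomplete_loglik <- function(pvals, prior, alpha) {
  E <- emission_matrix(pvals, alpha)
  sum(log(pmax(rowSums(prior * E), LIK_FLOOR)))
}

#' Complete-data log-likelihood (diagnostic)
#'
#' `sum_i sum_l z_il log(pi_il P(Y_i | Z_il = 1))`. Terms with `z_il = 0`
#' contribute zero.
#'
#' @inheritParams e_step
#' @param post M x 4 posterior responsibility matrix.
#' @return A scalar.
#' @export
complete_loglik <- function(pvals, prior, post, alpha) {
  E <- emission_matrix(pvals, alpha)
  lg <- log(pmax(prior * E, LIK_FLOOR))
  sum(ifelse(post > 0, post * lg, 0))
}

# clip rows into [floor, 1] and renormalize to the probability simplex
project_simplex <- function(p, floor = 1e-6) {
  p <- pmin(pmax(p, floor), 1)
  p / rowSums(p)
}
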