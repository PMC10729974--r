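# Local false discovery rates and direct posterior probability FDR control.

#' Per-SNP local false discovery rates
#'
#' From the posterior state responsibilities, the local fdr for a marginal
#' association is the posterior probability that the SNP is null for that
#' trait, and for the joint association that it is null for at least one
#' trait:
#' `fdr1 = z00 + z01`, `fdr2 = z00 + z10`, `fdr12 = z00 + z10 + z01`.
#' Consequently `fdr12 = fdr1 + z10 = fdr2 + z01 >= max(fdr1, fdr2)`.
#'
#' @param post M x 4 posterior matrix (or a fitted [pleiotree()] model).
#' @param snp_ids Optional SNP identifiers (taken from the fit or row names
#'   when available).
#' @return A data frame with columns `snp_id`, `z00`, `z10`, `z01`, `z11`,
#'   `fdr1`, `fdr2`, `fdr12`.
#' @export
compute_lfdr <- function(post, snp_ids = NULL) {
  if (inherits(post, "pleiotree")) {
    snp_ids <- post$snp_ids
    post <- post$posterior
  }
  if (is.null(snp_ids))
    snp_ids <- rownames(post)
  if (is.null(snp_ids))
    snp_ids <- paste0("snp", seq_len(nrow(post)))
  data.frame(snp_id = snp_ids,
             z00 = post[, 1L], z10 = post[, 2L],
             z01 = post[, 3L], z11 = post[, 4L],
             fdr1 = post[, 1L] + post[, 3L],
             fdr2 = post[, 1L] + post[, 2L],
             fdr12 = post[, 1L] + post[, 2L] + post[, 3L],
             row.names = NULL)
}

#' Direct posterior probability control of the global FDR
#'
#' Orders SNPs by ascending local fdr and declares the largest prefix whose
#' running mean local fdr does not exceed `level`; the realized average local
#' fdr among declared SNPs is then at most `level` by construction. SNPs tied
#' at the boundary value are declared only if the constraint holds with all
#' of them declared (all-or-none tie handling; the sort is stable by SNP
#' index, so calls are deterministic).
#'
#' @param lfdr Numeric vector of local fdr values in `[0, 1]`.
#' @param level Nominal global FDR level in `(0, 1)`.
#' @return Logical vector of calls in the original SNP order.
#' @export
control_global_fdr <- function(lfdr, level) {
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1)
    stop("level must be a scalar in (0, 1)")
  if (any(lfdr < 0 | lfdr > 1))
    stop("lfdr values must lie in [0, 1]")
  n <- length(lfdr)
  ord <- order(lfdr, seq_len(n))
  sorted <- lfdr[ord]
  ok <- cumsum(sorted) / seq_len(n) <= level
  k <- if (any(ok)) max(which(ok)) else 0L
  # all-or-none at the boundary value: if SNPs with the cutoff lfdr extend
  # past k, none of them can be declared (k is already maximal)
  if (k > 0L && k < n && sorted[k + 1L] == sorted[k])
    k <- sum(sorted < sorted[k])
  calls <- logical(n)
  if (k > 0L)
    calls[ord[seq_len(k)]] <- TRUE
  calls
}

#' Association calls at a nominal global FDR level
#'
#' Applies [control_global_fdr()] (or, optionally, a direct local-fdr
#' threshold) to the three local fdr vectors of a fit.
#'
#' @param fit A fitted [pleiotree()] model, or a data frame from
#'   [compute_lfdr()].
#' @param level Nominal level (default 0.05).
#' @param method `"global"` (default) for direct posterior probability global
#'   FDR control; `"local"` declares `lfdr <= level` directly.
#' @return The [compute_lfdr()] data frame with logical columns `assoc1`,
#'   `assoc2`, `assoc12` appended; the level is stored in attribute
#'   `fdr_level`.
#' @export
assoc <- function(fit, level = 0.05, method = c("global", "local")) {
  method <- match.arg(method)
  tab <- if (is.data.frame(fit)) fit else compute_lfdr(fit)
  call1 <- switch(method,
                  global = control_global_fdr(tab$fdr1, level),
                  local = tab$fdr1 <= level)
  call2 <- switch(method,
                  global = control_global_fdr(tab$fdr2, level),
                  local = tab$fdr2 <= level)
  call12 <- switch(method,
                   global = control_global_fdr(tab$fdr12, level),
                   local = tab$fdr12 <= level)
  tab$assoc1 <- call1
  tab$assoc2 <- call2
  tab$assoc12 <- call12
  attr(tab, "fdr_level") <- level
  tab
}

#' Count associated SNPs by category
#'
#' @param fdr_table Output of [assoc()].
#' @return List with `n_marginal_trait1`, `n_marginal_trait2`, `n_joint`,
#'   `level` and per-category SNP identifier vectors `ids`.
#' @export
summarize_associations <- function(fdr_table) {
  stopifnot(all(c("assoc1", "assoc2", "assoc12") %in% names(fdr_table)))
  list(n_marginal_trait1 = sum(fdr_table$assoc1),
       n_marginal_trait2 = sum(fdr_table$assoc2),
       n_joint = sum(fdr_table$assoc12),
       level = attr(fdr_table, "fdr_level"),
       ids = list(trait1 = fdr_table$snp_id[fdr_table$assoc1],
                  trait2 = fdr_table$snp_id[fdr_table$assoc2],
                  joint = fdr_table$snp_id[fdr_table$assoc12]))
}
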