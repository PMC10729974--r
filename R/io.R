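# Readers and writers for the delimited input/output formats.

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

read_table_sniffed <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = sniff_delim(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
}

#' Read and align p-value and annotation tables
#'
#' The p-value file must have columns `snp_id`, `p_trait1`, `p_trait2`; the
#' annotation file `snp_id` plus K binary columns. Files may be tab- or
#' comma-delimited (sniffed from the header line) and must have a header.
#' Rows are aligned by the inner join of the `snp_id` columns, preserving the
#' p-value file's order; SNPs present in only one file are dropped with a
#' message. P-values of 0 are clipped as in [as_gwas_pvalues()].
#'
#' @param pval_path,annot_path Paths to the two delimited files.
#' @return List with aligned `pvals` (M x 2) and `annotations` (M x K)
#'   matrices and `n_dropped`.
#' @examples
#' # a small synthetic example dataset ships with the package
#' inp <- read_gwas_inputs(
#'   system.file("extdata", "example_pvalues.tsv", package = "pleiotree"),
#'   system.file("extdata", "example_annotations.tsv", package = "pleiotree"))
#' dim(inp$pvals)
#' @export
read_gwas_inputs <- function(pval_path, annot_path) {
  pv <- read_table_sniffed(pval_path)
  an <- read_table_sniffed(annot_path)
  need <- c("snp_id", "p_trait1", "p_trait2")
  if (!all(need %in% names(pv)))
    stop("p-value file must have columns ", paste(need, collapse = ", "))
  if (!("snp_id" %in% names(an)) || ncol(an) < 2L)
    stop("annotation file must have a snp_id column plus annotation columns")
  for (col in c("p_trait1", "p_trait2"))
    if (!is.numeric(pv[[col]]))
      stop("non-numeric p-values in column ", col)
  common <- intersect(pv$snp_id, an$snp_id)
  if (length(common) == 0L)
    stop("no SNP identifiers shared between the two files")
  n_dropped <- (nrow(pv) - length(common)) + (nrow(an) - length(common))
  if (n_dropped > 0)
    message(n_dropped, " SNP(s) removed: present in only one input file")
  pv <- pv[pv$snp_id %in% common, , drop = FALSE]
  an <- an[match(pv$snp_id, an$snp_id), , drop = FALSE]
  Y <- as.matrix(pv[, c("p_trait1", "p_trait2")])
  rownames(Y) <- pv$snp_id
  A <- as.matrix(an[, setdiff(names(an), "snp_id"), drop = FALSE])
  rownames(A) <- an$snp_id
  list(pvals = as_gwas_pvalues(Y),
       annotations = as_annotation_matrix(A),
       n_dropped = n_dropped)
}

write_tsv_sig <- function(df, path, header_comment = NULL, digits = 10) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (j in which(num))
    df[[j]] <- sprintf(paste0("%.", digits, "g"), df[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the output bundle of a fit
#'
#' Writes, under `outdir`:
#' * `associations.tsv` — the [assoc()] table (posteriors, local fdrs,
#'   calls), numeric columns at 10 significant digits, with the nominal
#'   level in a `#` header comment;
#' * `tree.txt` and `tree.json` — the fitted annotation tree, human- and
#'   machine-readable;
#' * `selected_annotations.txt` — one selected annotation per line;
#' * `metadata.json` — alphas, log-likelihood, control parameters, seed (if
#'   supplied) and the per-stage likelihood traces.
#'
#' @param fit A [pleiotree()] fit.
#' @param outdir Output directory (created if needed).
#' @param level Nominal global FDR level for the association calls (default
#'   0.05).
#' @param seed Optional seed to record in the metadata.
#' @return Invisibly, the paths written.
#' @export
write_fit_outputs <- function(fit, outdir, level = 0.05, seed = NULL) {
  stopifnot(inherits(fit, "pleiotree"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  paths <- file.path(outdir, c("associations.tsv", "tree.txt", "tree.json",
                               "selected_annotations.txt", "metadata.json"))
  names(paths) <- c("associations", "tree_txt", "tree_json", "selected",
                    "metadata")
  tab <- assoc(fit, level = level)
  write_tsv_sig(tab, paths["associations"],
                header_comment = paste0("fdr_level=", level))
  writeLines(utils::capture.output(print(fit$tree)), paths["tree_txt"])
  writeLines(tree_to_json(fit), paths["tree_json"])
  writeLines(selected_annotations(fit), paths["selected"])
  meta <- list(alpha1 = fit$alpha[1L], alpha2 = fit$alpha[2L],
               loglik = fit$loglik,
               control = unclass(fit$control)[
                 c("alpha_init", "cp", "minsize", "max_iter_stage1",
                   "max_iter_stage2", "tol_loglik", "tol_alpha",
                   "probability_floor")],
               seed = seed,
               n_snps = length(fit$snp_ids),
               stage1_iterations = nrow(fit$stage1_trace),
               stage2_iterations = nrow(fit$stage2_trace),
               stage1_trace = fit$stage1_trace,
               stage2_trace = fit$stage2_trace,
               fdr_level = level)
  jsonlite::write_json(meta, paths["metadata"], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", null = "null")
  invisible(paths)
}

#' Write a simulated dataset as delimited text
#'
#' Writes `pvalues.tsv` and `annotations.tsv` in the format read by
#' [read_gwas_inputs()], plus `truth.tsv` with per-SNP true state and
#' L1/L2/L3 membership.
#'
#' @param sim A `pleio_sim` object.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_data <- function(sim, outdir) {
  stopifnot(inherits(sim, "pleio_sim"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  ids <- rownames(sim$pvals)
  paths <- file.path(outdir, c("pvalues.tsv", "annotations.tsv", "truth.tsv"))
  names(paths) <- c("pvalues", "annotations", "truth")
  write_tsv_sig(data.frame(snp_id = ids,
                           p_trait1 = sim$pvals[, 1L],
                           p_trait2 = sim$pvals[, 2L]),
                paths["pvalues"])
  ann <- data.frame(snp_id = ids, sim$annotations, check.names = FALSE)
  utils::write.table(ann, paths["annotations"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_tsv_sig(data.frame(snp_id = ids, true_state = sim$state,
                           L1 = as.integer(sim$L1), L2 = as.integer(sim$L2),
                           L3 = as.integer(sim$L3)),
                paths["truth"])
  invisible(paths)
}

#' Read a truth table written by [write_sim_data()]
#'
#' Reconstructs enough of a `pleio_sim` object (state and membership vectors,
#' aligned to the supplied data) for [evaluate_fit()].
#'
#' @param truth_path Path to `truth.tsv`.
#' @param pvals,annotations Aligned matrices the model was fitted to.
#' @param true_annotations Names of the causal annotations (default
#'   `A1..A6`).
#' @return A `pleio_sim` object.
#' @export
read_sim_truth <- function(truth_path, pvals, annotations,
                           true_annotations = paste0("A", 1:6)) {
  tr <- read_table_sniffed(truth_path)
  need <- c("snp_id", "true_state", "L1", "L2", "L3")
  if (!all(need %in% names(tr)))
    stop("truth file must have columns ", paste(need, collapse = ", "))
  idx <- match(rownames(pvals), tr$snp_id)
  if (anyNA(idx))
    stop("truth file is missing some fitted SNPs")
  tr <- tr[idx, , drop = FALSE]
  structure(list(pvals = pvals, annotations = annotations,
                 state = sprintf("%02d", as.integer(tr$true_state)),
                 L1 = tr$L1 == 1, L2 = tr$L2 == 1, L3 = tr$L3 == 1,
                 true_annotations = true_annotations, config = NULL),
            class = "pleio_sim")
}
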