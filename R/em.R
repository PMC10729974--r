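# Two-stage EM fitter.
#
# Stage 1 estimates (alpha1, alpha2) with a multivariate linear-regression
# M-step for the prior state probabilities. Stage 2 fixes the alphas and
# replaces the linear M-step with a pruned multivariate regression tree,
# run as a generalized EM: an iteration is retained only if it increases
# the incomplete log-likelihood over the last retained iteration.

#' Control parameters for the two-stage EM fit
#'
#' @param alpha_init Initial value for both Beta shape parameters (default
#'   0.1).
#' @param cp Complexity parameter for tree pruning in `[0, 1]`; a split
#'   survives only if its subtree reduces total deviance by more than
#'   `cp * root_deviance` per split (default 0.001).
#' @param minsize Minimum SNPs per tree leaf (default 20); small leaves give
#'   unstable prior estimates.
#' @param maxdepth Maximum tree depth (default `Inf`).
#' @param max_iter_stage1,max_iter_stage2 Iteration caps (defaults 200, 50).
#' @param tol_loglik Relative convergence tolerance on the incomplete
#'   log-likelihood (default 1e-4).
#' @param tol_alpha Absolute convergence tolerance on the alphas (default
#'   1e-4).
#' @param probability_floor Lower clip applied to prior probabilities before
#'   row renormalization (default 1e-6).
#' @return A list of class `pleio_control`.
#' @export
pleio_control <- function(alpha_init = 0.1, cp = 0.001, minsize = 20L,
                          maxdepth = Inf, max_iter_stage1 = 200L,
                          max_iter_stage2 = 50L, tol_loglik = 1e-4,
                          tol_alpha = 1e-4, probability_floor = 1e-6) {
  stopifnot(alpha_init > 0, alpha_init < 1,
            cp >= 0, cp <= 1, minsize >= 1,
            max_iter_stage1 >= 1, max_iter_stage2 >= 1,
            tol_loglik > 0, tol_alpha > 0,
            probability_floor > 0, probability_floor < 0.25)
  structure(list(alpha_init = alpha_init, cp = cp,
                 minsize = as.integer(minsize), maxdepth = maxdepth,
                 max_iter_stage1 = as.integer(max_iter_stage1),
                 max_iter_stage2 = as.integer(max_iter_stage2),
                 tol_loglik = tol_loglik, tol_alpha = tol_alpha,
                 probability_floor = probability_floor),
            class = "pleio_control")
}

#' Stage-1 M-step: linear regression of responsibilities on annotations
#'
#' Ordinary least squares of each of the four responsibility columns on the K
#' annotations with intercept; the fitted values, clipped to
#' `[probability_floor, 1]` and renormalized row-wise, become the prior state
#' probabilities. Because the row sums of the responsibilities are constant 1,
#' the raw fitted rows also sum to 1 exactly. Rank-deficient designs are
#' handled by the pivoting QR decomposition.
#'
#' @param post M x 4 responsibility matrix.
#' @param annotations M x K binary matrix.
#' @param floor Probability floor (default 1e-6).
#' @param qr_x Optional precomputed `qr(cbind(1, annotations))`, reused across
#'   EM iterations.
#' @return M x 4 prior matrix with attribute `coefficients` (the
#'   (K+1) x 4 regression coefficients, as a diagnostic).
#' @export
stage1_mstep_linear <- function(post, annotations, floor = 1e-6,
                                qr_x = NULL) {
  if (is.null(qr_x))
    qr_x <- qr(cbind(`(Intercept)` = 1, annotations))
  fitted <- qr.fitted(qr_x, post)
  prior <- project_simplex(fitted, floor)
  attr(prior, "coefficients") <- qr.coef(qr_x, post)
  prior
}

#' Stage 1: estimate the Beta shape parameters
#'
#' Starting from uniform priors (`pi_il = 1/4`) and `alpha_d = alpha_init`,
#' iterates E-step, linear M-step for the priors and the closed-form alpha
#' update until both the incomplete log-likelihood (relative) and the alphas
#' (absolute) move less than their tolerances, or the iteration cap is hit
#' (reported as a warning).
#'
#' @param pvals M x 2 p-value matrix.
#' @param annotations M x K binary annotation matrix.
#' @param control A [pleio_control()] list.
#' @return List with `alpha` (length-2), `prior` (M x 4), `trace`
#'   (data frame: iter, loglik, alpha1, alpha2, retained), `converged`.
#' @export
run_stage1 <- function(pvals, annotations, control = pleio_control()) {
  M <- nrow(pvals)
  alpha <- c(control$alpha_init, control$alpha_init)
  prior <- matrix(0.25, M, 4L, dimnames = list(NULL, STATE_LABELS))
  qr_x <- qr(cbind(`(Intercept)` = 1, annotations))
  ll_old <- incomplete_loglik(pvals, prior, alpha)
  trace <- vector("list", control$max_iter_stage1)
  converged <- FALSE
  for (it in seq_len(control$max_iter_stage1)) {
    post <- e_step(pvals, prior, alpha)
    prior <- stage1_mstep_linear(post, annotations,
                                 control$probability_floor, qr_x)
    alpha_new <- update_alpha(pvals, post)
    ll <- incomplete_loglik(pvals, prior, alpha_new)
    trace[[it]] <- data.frame(iter = it, loglik = ll,
                              alpha1 = alpha_new[1L], alpha2 = alpha_new[2L],
                              retained = TRUE)
    dalpha <- max(abs(alpha_new - alpha))
    dll <- abs(ll - ll_old)
    alpha <- alpha_new
    ll_old <- ll
    if (dll < control$tol_loglik * abs(ll) && dalpha < control$tol_alpha) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("Stage 1 did not converge in ", control$max_iter_stage1,
            " iterations")
  list(alpha = alpha, prior = prior,
       trace = do.call(rbind, trace[!vapply(trace, is.null, TRUE)]),
       converged = converged)
}

#' Stage 2: annotation-tree EM with fixed alphas
#'
#' Iterates E-step and a tree M-step (grow a full multivariate regression
#' tree on the responsibilities, prune at `cp`, predict, project to the
#' probability simplex) with the alphas held at their Stage-1 estimates.
#' Because the tree M-step does not maximize the expected complete
#' log-likelihood, the run is a generalized EM: after each iteration the
#' incomplete log-likelihood is compared with the last retained value; on the
#' first non-increase the previous retained state is restored and iteration
#' stops. If the very first tree iteration decreases the log-likelihood the
#' Stage-1 priors are returned with a single-leaf tree and a warning.
#'
#' @param pvals,annotations Aligned input matrices.
#' @param alpha Fixed length-2 Beta shape vector from Stage 1.
#' @param prior_init M x 4 Stage-1 prior matrix.
#' @param control A [pleio_control()] list.
#' @return List with `tree` (`mvtree`), `prior`, `posterior`, `trace`,
#'   `loglik` (last retained incomplete log-likelihood).
#' @export
run_stage2 <- function(pvals, annotations, alpha, prior_init,
                       control = pleio_control()) {
  ll_best <- incomplete_loglik(pvals, prior_init, alpha)
  best <- list(prior = prior_init, tree = NULL)
  trace <- list()
  for (it in seq_len(control$max_iter_stage2)) {
    post <- e_step(pvals, best$prior, alpha)
    tree <- mvtree_grow(post, annotations, minsize = control$minsize,
                        maxdepth = control$maxdepth)
    tree <- mvtree_prune(tree, control$cp)
    prior <- project_simplex(predict(tree, annotations),
                             control$probability_floor)
    colnames(prior) <- STATE_LABELS
    ll <- incomplete_loglik(pvals, prior, alpha)
    retained <- ll > ll_best
    trace[[it]] <- data.frame(iter = it, loglik = ll,
                              alpha1 = alpha[1L], alpha2 = alpha[2L],
                              retained = retained)
    if (!retained) {
      if (it == 1L) {
        warning("first tree iteration decreased the incomplete ",
                "log-likelihood; returning Stage-1 priors with a ",
                "single-leaf tree")
        best$tree <- single_leaf_tree(post, annotations)
      }
      break
    }
    converged <- ll - ll_best < control$tol_loglik * abs(ll)
    ll_best <- ll
    best <- list(prior = prior, tree = tree)
    if (converged) break
  }
  if (is.null(best$tree))   # retention never triggered and loop exhausted
    best$tree <- single_leaf_tree(e_step(pvals, best$prior, alpha),
                                  annotations)
  list(tree = best$tree, prior = best$prior,
       posterior = e_step(pvals, best$prior, alpha),
       trace = do.call(rbind, trace), loglik = ll_best)
}

single_leaf_tree <- function(responses, annotations) {
  t1 <- mvtree_grow(responses, annotations, minsize = nrow(responses))
  t1
}

#' Fit the pleiotropy-informed annotation-tree mixture model
#'
#' Main entry point. Runs Stage 1 (alpha estimation with a linear M-step)
#' followed by Stage 2 (tree M-step with alphas fixed) and assembles the
#' fitted model.
#'
#' @param pvals M x 2 p-value matrix or data frame (see [as_gwas_pvalues()]).
#' @param annotations M x K binary matrix or data frame (see
#'   [as_annotation_matrix()]). Rows must align with `pvals`; if both carry
#'   identifiers they are checked.
#' @param control A [pleio_control()] list.
#' @return An object of class `pleiotree`: list with `alpha`, `tree`
#'   (`mvtree`), `prior`, `posterior` (M x 4 matrices), `stage1_trace`,
#'   `stage2_trace`, `snp_ids`, `annotation_names`, `control`, `converged`.
#' @examples
#' sim <- simulate_pleio(sim_config(M = 2000, seed = 7))
#' fit <- pleiotree(sim$pvals, sim$annotations)
#' selected_annotations(fit)
#' @export
pleiotree <- function(pvals, annotations, control = pleio_control()) {
  pvals <- as_gwas_pvalues(pvals)
  annotations <- as_annotation_matrix(annotations)
  if (nrow(pvals) != nrow(annotations))
    stop("p-value and annotation matrices must have the same number of rows")
  if (!identical(rownames(pvals), rownames(annotations)))
    stop("SNP identifiers of p-value and annotation matrices disagree; ",
         "align them first (see read_gwas_inputs)")
  s1 <- run_stage1(pvals, annotations, control)
  s2 <- run_stage2(pvals, annotations, s1$alpha, s1$prior, control)
  structure(list(alpha = s1$alpha, tree = s2$tree, prior = s2$prior,
                 posterior = s2$posterior, loglik = s2$loglik,
                 stage1_trace = s1$trace, stage2_trace = s2$trace,
                 snp_ids = rownames(pvals),
                 annotation_names = colnames(annotations),
                 control = control, converged = s1$converged),
            class = "pleiotree")
}

#' @export
print.pleiotree <- function(x, ...) {
  cat("Pleiotropy-informed annotation-tree mixture fit\n")
  cat("  SNPs:", length(x$snp_ids),
      "  annotations:", length(x$annotation_names), "\n")
  cat(sprintf("  alpha1 = %.4f, alpha2 = %.4f\n", x$alpha[1L], x$alpha[2L]))
  cat("  incomplete log-likelihood:", format(x$loglik), "\n")
  sel <- selected_annotations(x)
  cat("  selected annotations:",
      if (length(sel)) paste(sel, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
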