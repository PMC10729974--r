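# Synthetic GWAS + annotation data generator and evaluation metrics.
#
# The generator emulates a two-trait study in which risk-associated SNPs are
# characterized by intersections of binary functional annotations:
#   L1 = A1 & A2  -> marginally associated with trait 1 only (state 10)
#   L2 = A3 & A4  -> marginally associated with trait 2 only (state 01)
#   L3 = A5 & A6  -> jointly associated with both traits    (state 11)
# The three intersections are placed on disjoint SNP blocks so every SNP has
# a unique true state. Non-null p-value coordinates are Beta(alpha_d, 1)
# draws; null coordinates are U[0, 1]. Annotations A7..AK are noise, each
# annotating a random fraction of SNPs drawn from Uniform(noise_range).

#' Configuration for the synthetic-data generator
#'
#' @param M Number of SNPs (default 10000).
#' @param K Number of annotations, at least 6 (default 25).
#' @param u Fraction of SNPs annotated by each of the six true annotations
#'   (default 0.10; realized counts are `round(u * M)` exactly).
#' @param v Overlap fraction within each true annotation pair (default 0.50;
#'   the pair intersection holds `round(v * u * M)` SNPs).
#' @param alpha1,alpha2 Beta shape parameters for non-null p-values (default
#'   0.4 each).
#' @param noise_range Range of per-annotation densities for the noise
#'   annotations (default `c(0.1, 0.3)`).
#' @param seed Integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(M = 10000L, K = 25L, u = 0.10, v = 0.50,
                       alpha1 = 0.4, alpha2 = 0.4,
                       noise_range = c(0.1, 0.3), seed = 1L) {
  stopifnot(M >= 1, K >= 6, u > 0, u < 1, v > 0, v <= 1,
            alpha1 > 0, alpha1 < 1, alpha2 > 0, alpha2 < 1,
            length(noise_range) == 2L, noise_range[1L] <= noise_range[2L],
            noise_range[1L] >= 0, noise_range[2L] <= 1)
  n_a <- round(u * M)
  n_ov <- round(v * n_a)
  if (3 * (2 * n_a - n_ov) > M)
    stop("infeasible configuration: the six true annotation sets need ",
         3 * (2 * n_a - n_ov), " SNPs but only ", M, " are available")
  structure(list(M = as.integer(M), K = as.integer(K), u = u, v = v,
                 alpha1 = alpha1, alpha2 = alpha2,
                 noise_range = noise_range, seed = as.integer(seed)),
            class = "sim_config")
}

# allocate the noise annotations and assemble the annotation matrix given
# per-true-annotation index sets
assemble_annotations <- function(M, K, true_sets, noise_range) {
  A <- matrix(0, M, K)
  for (k in seq_along(true_sets))
    A[true_sets[[k]], k] <- 1
  # noise annotations: density drawn from the configured range
  for (k in seq.int(length(true_sets) + 1L, length.out = K - length(true_sets))) {
    frac <- stats::runif(1L, noise_range[1L], noise_range[2L])
    A[sample.int(M, round(frac * M)), k] <- 1
  }
  rownames(A) <- paste0("snp", seq_len(M))
  colnames(A) <- paste0("A", seq_len(K))
  A
}

draw_pvalues <- function(M, nonnull1, nonnull2, alpha1, alpha2) {
  y1 <- stats::runif(M)
  y2 <- stats::runif(M)
  y1[nonnull1] <- stats::rbeta(sum(nonnull1), alpha1, 1)
  y2[nonnull2] <- stats::rbeta(sum(nonnull2), alpha2, 1)
  Y <- cbind(p1 = y1, p2 = y2)
  rownames(Y) <- paste0("snp", seq_len(M))
  Y
}

finish_sim <- function(Y, A, L1, L2, L3, true_annotations, config) {
  state <- rep("00", nrow(Y))
  state[L1] <- "10"
  state[L2] <- "01"
  state[L3] <- "11"
  structure(list(pvals = Y, annotations = A, state = state,
                 L1 = L1, L2 = L2, L3 = L3,
                 true_annotations = true_annotations, config = config),
            class = "pleio_sim")
}

#' Generate a synthetic two-trait GWAS dataset with annotation structure
#'
#' See the module header: three disjoint annotation-pair intersections define
#' the SNPs marginally associated with trait 1 (`L1 = A1 & A2`), marginally
#' associated with trait 2 (`L2 = A3 & A4`) and jointly associated
#' (`L3 = A5 & A6`); the remaining `K - 6` annotations are noise. The RNG is
#' fully determined by `config$seed`.
#'
#' @param config A [sim_config()] list.
#' @return A list of class `pleio_sim` with elements `pvals` (M x 2),
#'   `annotations` (M x K), `state` (character vector over
#'   `"00","10","01","11"`), logical membership vectors `L1`, `L2`, `L3`,
#'   `true_annotations` and the `config`.
#' @export
simulate_pleio <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  M <- config$M
  n_a <- round(config$u * M)
  n_ov <- round(config$v * n_a)
  block <- 2L * n_a - n_ov
  perm <- sample.int(M)
  true_sets <- vector("list", 6L)
  inter <- vector("list", 3L)
  for (j in 1:3) {
    b <- perm[seq.int((j - 1L) * block + 1L, j * block)]
    true_sets[[2L * j - 1L]] <- b[seq_len(n_a)]                  # A_{2j-1}
    true_sets[[2L * j]] <- b[seq.int(n_a - n_ov + 1L, block)]    # A_{2j}
    inter[[j]] <- b[seq.int(n_a - n_ov + 1L, n_a)]
  }
  A <- assemble_annotations(M, config$K, true_sets, config$noise_range)
  L1 <- L2 <- L3 <- logical(M)
  L1[inter[[1L]]] <- TRUE
  L2[inter[[2L]]] <- TRUE
  L3[inter[[3L]]] <- TRUE
  Y <- draw_pvalues(M, L1 | L3, L2 | L3, config$alpha1, config$alpha2)
  finish_sim(Y, A, L1, L2, L3, paste0("A", 1:6), config)
}

#' Scenarios with annotations shared between marginal and joint SNPs
#'
#' Variants of [simulate_pleio()] in which the jointly associated SNPs are
#' characterized by (some of) the same annotations as the marginally
#' associated SNPs:
#'
#' * `"shared_plus_unique"`: `L1 = A1 & A2`, `L2 = A3 & A4`, and the joint
#'   SNPs satisfy `A1 & A3 & A5` — they share one annotation with each
#'   marginal combination and additionally require the unique annotation
#'   `A5`. `A6` is then the first noise annotation, so the true annotation
#'   set is `{A1, ..., A5}`.
#' * `"shared_only"`: joint SNPs satisfy `A1 & A2 & A3 & A4`, i.e. both
#'   marginal combinations simultaneously and no unique annotation; the true
#'   annotation set is `{A1, ..., A4}` and `A5`, `A6` are noise. With
#'   `v = 1` the pairs collapse (`A2 = A1`, `A4 = A3`) and the design
#'   degenerates to two annotations.
#'
#' All blocks of associated SNPs are disjoint and hold `round(v * u * M)`
#' SNPs each; each true annotation still annotates `round(u * M)` SNPs
#' except when `2 * round(v*u*M) > round(u*M)` forces a larger set for shared
#' annotations. P-values follow the same per-state distributions as
#' [simulate_pleio()].
#'
#' @param config A [sim_config()] list.
#' @param scenario `"shared_plus_unique"` or `"shared_only"`.
#' @return A `pleio_sim` list (see [simulate_pleio()]).
#' @export
simulate_shared <- function(config = sim_config(),
                            scenario = c("shared_plus_unique", "shared_only")) {
  stopifnot(inherits(config, "sim_config"))
  scenario <- match.arg(scenario)
  set.seed(config$seed)
  M <- config$M
  n_a <- round(config$u * M)
  n_ov <- round(config$v * n_a)
  perm <- sample.int(M)
  take <- local({
    pos <- 0L
    function(n) {
      stopifnot(pos + n <= M)
      out <- perm[seq.int(pos + 1L, pos + n)]
      pos <<- pos + n
      out
    }
  })
  b1 <- take(n_ov)   # L1 block: marginal trait 1
  b2 <- take(n_ov)   # L2 block: marginal trait 2
  b3 <- take(n_ov)   # L3 block: joint
  if (scenario == "shared_plus_unique") {
    # A1 covers L1 and L3 (shared with the joint SNPs); A3 covers L2 and L3;
    # A2, A4 stay pair-private; A5 is unique to the joint SNPs
    s <- list(A1 = c(b1, b3), A2 = b1, A3 = c(b2, b3), A4 = b2, A5 = b3,
              A6 = integer(0))
    true_annotations <- paste0("A", 1:5)
  } else {
    # joint SNPs satisfy both marginal combinations: A1..A4 all cover L3
    s <- list(A1 = c(b1, b3), A2 = c(b1, b3), A3 = c(b2, b3), A4 = c(b2, b3),
              A5 = integer(0), A6 = integer(0))
    true_annotations <- paste0("A", 1:4)
  }
  # pad every true annotation up to round(u * M) SNPs with private filler
  for (k in seq_along(s)) {
    pad <- n_a - length(s[[k]])
    if (pad > 0)
      s[[k]] <- c(s[[k]], take(pad))
  }
  A <- assemble_annotations(M, config$K, s, config$noise_range)
  L1 <- L2 <- L3 <- logical(M)
  L1[b1] <- TRUE
  L2[b2] <- TRUE
  L3[b3] <- TRUE
  Y <- draw_pvalues(M, L1 | L3, L2 | L3, config$alpha1, config$alpha2)
  finish_sim(Y, A, L1, L2, L3, true_annotations, config)
}

# Exact ROC curve of a local-fdr vector against a truth labelling: sweeping
# the global FDR level from 0 to 1 declares nested prefixes of the
# lfdr-sorted SNPs, so the achievable (FPR, TPR) points are the per-distinct-
# lfdr prefix points; the area is computed by trapezoidal integration.
auc_from_lfdr <- function(lfdr, truth) {
  npos <- sum(truth)
  nneg <- sum(!truth)
  if (npos == 0L || nneg == 0L)
    return(NA_real_)
  ord <- order(lfdr)
  l <- lfdr[ord]
  t <- truth[ord]
  keep <- c(l[-1L] != l[-length(l)], TRUE)   # last index of each tie group
  tpr <- c(0, cumsum(t)[keep] / npos)
  fpr <- c(0, cumsum(!t)[keep] / nneg)
  sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
}

category_metrics <- function(lfdr, truth, level) {
  calls <- control_global_fdr(lfdr, level)
  n_called <- sum(calls)
  list(auc = auc_from_lfdr(lfdr, truth),
       power = if (sum(truth) > 0) sum(calls & truth) / sum(truth)
               else NA_real_,
       fdp = if (n_called > 0) sum(calls & !truth) / n_called else 0,
       mean_lfdr_declared = if (n_called > 0) mean(lfdr[calls]) else 0)
}

#' Evaluate a fitted model against simulation truth
#'
#' Computes, for each association category (marginal trait 1, marginal trait
#' 2, joint): the area under the ROC curve traced by sweeping the global FDR
#' control level, the power (true positive rate) and the truth-based false
#' discovery proportion among SNPs declared at `level`, and the mean declared
#' local fdr; plus the alpha estimates and annotation-selection metrics
#' (whether all true annotations were selected, and the proportions of true
#' and of noise annotations among the selected set).
#'
#' @param sim A `pleio_sim` object the model was fitted to.
#' @param fit The corresponding [pleiotree()] fit.
#' @param level Nominal global FDR level for power/FDP (default 0.20).
#' @return A one-row data frame of metrics.
#' @export
evaluate_fit <- function(sim, fit, level = 0.20) {
  stopifnot(inherits(sim, "pleio_sim"), inherits(fit, "pleiotree"))
  if (length(fit$snp_ids) != nrow(sim$pvals))
    stop("fit and simulation have different numbers of SNPs")
  tab <- compute_lfdr(fit)
  truth1 <- sim$state %in% c("10", "11")
  truth2 <- sim$state %in% c("01", "11")
  truth12 <- sim$state == "11"
  m1 <- category_metrics(tab$fdr1, truth1, level)
  m2 <- category_metrics(tab$fdr2, truth2, level)
  m12 <- category_metrics(tab$fdr12, truth12, level)
  sel <- selected_annotations(fit)
  true_ann <- sim$true_annotations
  noise_ann <- setdiff(colnames(sim$annotations), true_ann)
  data.frame(
    auc1 = m1$auc, auc2 = m2$auc, auc12 = m12$auc,
    power1 = m1$power, power2 = m2$power, power12 = m12$power,
    fdp1 = m1$fdp, fdp2 = m2$fdp, fdp12 = m12$fdp,
    mean_lfdr1 = m1$mean_lfdr_declared, mean_lfdr2 = m2$mean_lfdr_declared,
    mean_lfdr12 = m12$mean_lfdr_declared,
    alpha1 = fit$alpha[1L], alpha2 = fit$alpha[2L],
    n_selected = length(sel),
    all_true_selected = all(true_ann %in% sel),
    exact_true_selected = setequal(sel, true_ann),
    prop_true_among_selected =
      if (length(sel) > 0) mean(sel %in% true_ann) else 0,
    prop_noise_among_selected =
      if (length(sel) > 0) mean(sel %in% noise_ann) else 0,
    level = level)
}

#' Run replicated simulation-fit-evaluate experiments
#'
#' Replicate `r` is generated with seed `config$seed + r`, fitted with
#' [pleiotree()] and evaluated with [evaluate_fit()]. A failing replicate is
#' recorded with its seed and excluded from the aggregate, never silently
#' dropped.
#'
#' @param config Base [sim_config()]; per-replicate seeds derive from its
#'   `seed`.
#' @param n_reps Number of replicates.
#' @param control [pleio_control()] passed to the fitter.
#' @param level Nominal FDR level for the evaluation (default 0.20).
#' @param scenario `"standard"` for [simulate_pleio()], otherwise passed to
#'   [simulate_shared()].
#' @return List with `reports` (data frame, one row per successful
#'   replicate, including its seed), `failures` (data frame of seed +
#'   condition message), `mean` and `sd` (named numeric aggregates).
#' @export
run_replications <- function(config, n_reps, control = pleio_control(),
                             level = 0.20, scenario = "standard") {
  reports <- list()
  failures <- list()
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r
    res <- tryCatch({
      sim <- if (scenario == "standard") simulate_pleio(cfg)
             else simulate_shared(cfg, scenario)
      fit <- pleiotree(sim$pvals, sim$annotations, control)
      cbind(data.frame(rep = r, seed = cfg$seed),
            evaluate_fit(sim, fit, level))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(rep = r, seed = cfg$seed,
                   message = conditionMessage(res))
    } else {
      reports[[length(reports) + 1L]] <- res
    }
  }
  reports <- if (length(reports)) do.call(rbind, reports) else NULL
  failures <- if (length(failures)) do.call(rbind, failures) else NULL
  num <- if (!is.null(reports))
    reports[, !(names(reports) %in% c("rep", "seed")), drop = FALSE]
  list(reports = reports, failures = failures,
       mean = if (!is.null(reports)) colMeans(data.matrix(num)),
       sd = if (!is.null(reports)) apply(data.matrix(num), 2L, stats::sd))
}
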