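# Two-stage EM: linear M-step, Stage-1 alpha estimation, Stage-2 tree EM
# with the generalized-EM retention rule, and full-fit invariants.

test_that("linear M-step reduces to column means with no informative design", {
  set.seed(5)
  z <- matrix(rgamma(200, 1), 50, 4)
  z <- z / rowSums(z)
  A <- matrix(0, 50, 1, dimnames = list(NULL, "A1"))   # constant column
  prior <- stage1_mstep_linear(z, A)
  expect_equal(prior, matrix(rep(colMeans(z), each = 50), 50, 4),
               tolerance = 1e-10, ignore_attr = TRUE)
  # raw fitted rows sum to 1 exactly because the z rows do
  expect_true(all(abs(rowSums(prior) - 1) < 1e-10))
})

test_that("linear M-step reproduces a noiseless linear response", {
  set.seed(6)
  a1 <- rbinom(100, 1, 0.5)
  A <- cbind(A1 = a1, A2 = rbinom(100, 1, 0.3))
  z <- cbind(0.40 - 0.20 * a1, 0.20 + 0.10 * a1,
             0.20 + 0.05 * a1, 0.20 + 0.05 * a1)
  prior <- stage1_mstep_linear(z, A)
  expect_equal(unname(prior), unname(z), tolerance = 1e-10,
               ignore_attr = TRUE)
  # coefficients are exposed as a diagnostic
  expect_equal(dim(attr(prior, "coefficients")), c(3L, 4L))
})

test_that("linear M-step tolerates rank-deficient designs", {
  set.seed(8)
  a1 <- rbinom(60, 1, 0.5)
  A <- cbind(A1 = a1, A2 = a1, A3 = 1 - a1)   # collinear block
  z <- matrix(rgamma(240, 1), 60, 4)
  z <- z / rowSums(z)
  prior <- stage1_mstep_linear(z, A)
  expect_true(all(is.finite(prior)))
  expect_true(all(abs(rowSums(prior) - 1) < 1e-10))
})

test_that("Stage 1 recovers the Beta shapes within the reported band", {
  sim <- simulate_pleio(sim_config(seed = 301))
  s1 <- run_stage1(sim$pvals, sim$annotations)
  expect_true(all(s1$alpha > 0.35 & s1$alpha < 0.55))
  expect_true(s1$converged)
  # trace determinism: EM has no internal randomness
  s1b <- run_stage1(sim$pvals, sim$annotations)
  expect_identical(s1$trace, s1b$trace)
})

test_that("pure-null data yields no joint discoveries", {
  set.seed(77)
  M <- 5000
  pv <- as_gwas_pvalues(matrix(runif(2 * M), M, 2))
  A <- as_annotation_matrix(matrix(rbinom(M * 5, 1, 0.2), M, 5))
  fit <- suppressWarnings(pleiotree(pv, A))
  expect_lt(mean(fit$prior[, 4]), 0.05)
  counts <- summarize_associations(assoc(fit, level = 0.05))
  expect_equal(counts$n_joint, 0L)
})

test_that("Stage-2 retained log-likelihood sequence increases strictly", {
  sim <- simulate_pleio(sim_config(M = 2000, seed = 17))
  fit <- pleiotree(sim$pvals, sim$annotations)
  kept <- fit$stage2_trace$loglik[fit$stage2_trace$retained]
  expect_true(all(diff(kept) > 0))
  # the one non-retained iteration, if any, terminates the trace
  notkept <- which(!fit$stage2_trace$retained)
  if (length(notkept) > 0)
    expect_equal(notkept, nrow(fit$stage2_trace))
})

test_that("cp = 1 forces a single-leaf tree with no annotations selected", {
  sim <- simulate_pleio(sim_config(M = 2000, seed = 19))
  # a constant prior cannot beat the annotation-informed Stage-1 prior, so
  # the first tree iteration is rejected and the Stage-1 priors are kept
  # with a single-leaf tree, under a warning
  expect_warning(
    fit <- pleiotree(sim$pvals, sim$annotations, pleio_control(cp = 1)),
    "single-leaf")
  expect_equal(n_leaves(fit$tree), 1L)
  expect_length(selected_annotations(fit), 0L)
})

test_that("full fit satisfies its structural invariants", {
  sim <- simulate_pleio(sim_config(M = 2000, seed = 23))
  fit <- pleiotree(sim$pvals, sim$annotations)
  # prior equals tree prediction after simplex projection
  expect_equal(unname(fit$prior),
               unname(pleiotree:::project_simplex(
                 predict(fit$tree, sim$annotations),
                 fit$control$probability_floor)))
  # posterior equals a recomputed E-step, bitwise
  expect_identical(fit$posterior, e_step(sim$pvals, fit$prior, fit$alpha))
  expect_true(all(abs(rowSums(fit$posterior) - 1) < 1e-10))
  expect_true(all(fit$prior >= fit$control$probability_floor - 1e-15))
})

test_that("swapping the trait columns swaps the model symmetrically", {
  sim <- simulate_pleio(sim_config(M = 2000, seed = 29, u = 0.12))
  fit <- pleiotree(sim$pvals, sim$annotations)
  swapped <- sim$pvals[, c(2, 1)]
  colnames(swapped) <- c("p1", "p2")
  fit2 <- pleiotree(swapped, sim$annotations)
  expect_equal(fit2$alpha, fit$alpha[c(2, 1)], tolerance = 1e-10)
  tab <- compute_lfdr(fit)
  tab2 <- compute_lfdr(fit2)
  expect_equal(tab2$fdr1, tab$fdr2, tolerance = 1e-10)
  expect_equal(tab2$fdr2, tab$fdr1, tolerance = 1e-10)
  expect_equal(tab2$fdr12, tab$fdr12, tolerance = 1e-10)
})

test_that("zero annotations reduce the model to an annotation-free mixture", {
  set.seed(37)
  M <- 1500
  pv <- matrix(runif(2 * M), M, 2)
  pv[1:150, 1] <- rbeta(150, 0.4, 1)
  pv[101:250, 2] <- rbeta(150, 0.4, 1)
  pv <- as_gwas_pvalues(pmax(pv, 1e-30))
  A <- as_annotation_matrix(matrix(numeric(0), M, 0))
  fit <- suppressWarnings(pleiotree(pv, A))
  expect_true(all(apply(fit$prior, 2, function(col) diff(range(col)) == 0)))
  expect_equal(n_leaves(fit$tree), 1L)
})
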