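# Multivariate regression tree: growth, pruning, prediction, combinations.

test_that("a single informative annotation gives one split and pure leaves", {
  set.seed(3)
  M <- 100
  a1 <- rep(c(0L, 1L), each = M / 2)
  A <- as_annotation_matrix(cbind(A1 = a1, A2 = 0L))
  Z <- matrix(rep(c(0.1, 0.3, 0.3, 0.3), each = M), M, 4)
  Z[a1 == 1, ] <- matrix(rep(c(0.9, 0.1, 0, 0), each = M / 2), M / 2, 4)
  tr <- mvtree_grow(Z, A, minsize = 5)
  expect_equal(n_leaves(tr), 2L)
  expect_equal(tr$annotation_names[tr$root$split], "A1")
  expect_equal(unname(tr$root$children[[1]]$pred), c(0.1, 0.3, 0.3, 0.3))
  expect_equal(unname(tr$root$children[[2]]$pred), c(0.9, 0.1, 0, 0))
  expect_equal(tr$root$children[[1]]$dev, 0)
})

test_that("constant responses give a single-leaf tree", {
  A <- as_annotation_matrix(matrix(rbinom(200, 1, 0.5), 50, 4))
  Z <- matrix(0.25, 50, 4)
  expect_equal(n_leaves(mvtree_grow(Z, A, minsize = 5)), 1L)
})

test_that("grown trees match the exhaustive split-search oracle", {
  set.seed(99)
  for (i in 1:100) {
    M <- sample(40:200, 1)
    K <- sample(2:8, 1)
    minsize <- sample(c(5L, 10L, 20L), 1)
    inst <- random_tree_instance(M, K, minsize)
    tr <- mvtree_grow(inst$responses, inst$annotations, minsize = minsize)
    or <- oracle_grow(inst$responses, inst$annotations, minsize)
    expect_identical(tree_signature(tr$root), tree_signature(or))
  }
})

test_that("pruning clears splits below cp times the root deviance", {
  # engineered two-split tree: the A2 split inside the A1=1 branch reduces
  # total deviance by a known small fraction of the root deviance
  a1 <- rep(c(0L, 1L), each = 40)
  a2 <- rep(c(0L, 1L, 0L, 1L), each = 20)
  A <- as_annotation_matrix(cbind(A1 = a1, A2 = a2))
  y <- numeric(80)
  y[a1 == 0] <- 0                       # pure left branch
  delta <- 0.2
  y[a1 == 1 & a2 == 0] <- 1 - delta / 2
  y[a1 == 1 & a2 == 1] <- 1 + delta / 2
  Z <- cbind(y)
  tr <- mvtree_grow(Z, A, minsize = 5)
  expect_equal(n_leaves(tr), 3L)
  # independent arithmetic: root SSE and the gain of the second split
  root_sse <- sum((y - mean(y))^2)
  gain2 <- 20 * 20 / 40 * delta^2        # n1*n0/n * (mean diff)^2
  rel <- gain2 / root_sse
  expect_equal(tr$root_dev, root_sse)
  expect_equal(n_leaves(mvtree_prune(tr, cp = rel * 1.25)), 2L)
  expect_equal(n_leaves(mvtree_prune(tr, cp = rel * 0.75)), 3L)
  # limits
  expect_equal(n_leaves(mvtree_prune(tr, cp = 1)), 1L)
  expect_identical(mvtree_prune(tr, cp = 0), tr)
  expect_error(mvtree_prune(tr, cp = 2), "cp")
})

test_that("prediction routes rows to leaf means and checks annotations", {
  set.seed(11)
  inst <- random_tree_instance(150, 5, 10L)
  tr <- mvtree_grow(inst$responses, inst$annotations, minsize = 10)
  pred <- predict(tr, inst$annotations)
  # self-consistency: per-leaf mean of training responses = leaf prediction
  key <- apply(pred, 1, paste, collapse = ",")
  for (g in unique(key)) {
    rows <- key == g
    expect_equal(unname(pred[which(rows)[1], ]),
                 unname(colMeans(inst$responses[rows, , drop = FALSE])),
                 tolerance = 1e-12)
  }
  # single-leaf tree predicts its constant everywhere
  tr1 <- mvtree_prune(tr, 1)
  pred1 <- predict(tr1, inst$annotations)
  expect_true(all(pred1 == rep(tr1$root$pred, each = nrow(pred1))))
  # a split annotation missing from new data is an error
  if (length(selected_annotations(tr)) > 0) {
    Abad <- inst$annotations[, setdiff(colnames(inst$annotations),
                                       selected_annotations(tr)[1]),
                             drop = FALSE]
    expect_error(predict(tr, Abad), "missing")
  }
})

test_that("row sums of training responses are preserved by leaf predictions", {
  set.seed(21)
  M <- 120
  Z <- matrix(rgamma(4 * M, 1), M, 4)
  Z <- Z / rowSums(Z)
  A <- as_annotation_matrix(matrix(rbinom(M * 4, 1, 0.4), M, 4))
  tr <- mvtree_grow(Z, A, minsize = 10)
  pred <- predict(tr, A)
  expect_true(all(abs(rowSums(pred) - 1) < 1e-10))
})

test_that("node deviance dominates the sum of child deviances", {
  set.seed(31)
  inst <- random_tree_instance(200, 6, 10L)
  tr <- mvtree_grow(inst$responses, inst$annotations, minsize = 10)
  check <- function(node) {
    if (is.null(node$children)) return(invisible())
    expect_gte(node$dev + 1e-9,
               node$children[[1]]$dev + node$children[[2]]$dev)
    check(node$children[[1]])
    check(node$children[[2]])
  }
  check(tr$root)
})

test_that("leaf count is non-increasing in cp", {
  set.seed(41)
  inst <- random_tree_instance(200, 6, 5L)
  tr <- mvtree_grow(inst$responses, inst$annotations, minsize = 5)
  counts <- vapply(c(0, 1e-4, 1e-3, 1e-2, 0.1, 0.5, 1),
                   function(cp) n_leaves(mvtree_prune(tr, cp)), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 1L)
})

test_that("combinations enumerate root-to-leaf annotation conjunctions", {
  # fixture: split on A1, then on A2 within the A1=1 branch
  a1 <- rep(c(0L, 1L), each = 40)
  a2 <- rep(c(0L, 1L, 0L, 1L), each = 20)
  A <- as_annotation_matrix(cbind(A1 = a1, A2 = a2))
  Z <- cbind(a1 * 2 + a1 * a2)   # A2 only matters inside the A1=1 branch
  tr <- mvtree_grow(Z, A, minsize = 5)
  cc <- tree_combinations(tr)
  expect_equal(cc$selected, c("A1", "A2"))
  paths <- lapply(cc$combinations, function(co)
    paste(co$conditions$annotation, co$conditions$value, sep = "=",
          collapse = " & "))
  expect_setequal(unlist(paths), c("A1=0", "A1=1 & A2=0", "A1=1 & A2=1"))
  # single leaf: one empty combination, no selected annotations
  cc1 <- tree_combinations(mvtree_prune(tr, 1))
  expect_length(cc1$combinations, 1L)
  expect_equal(nrow(cc1$combinations[[1]]$conditions), 0L)
  expect_length(cc1$selected, 0L)
})

test_that("JSON serialization round-trips byte-identically", {
  set.seed(51)
  inst <- random_tree_instance(100, 4, 10L)
  tr <- mvtree_grow(inst$responses, inst$annotations, minsize = 10)
  js <- tree_to_json(tr)
  tr2 <- tree_from_json(js)
  expect_identical(as.character(tree_to_json(tr2)), as.character(js))
  expect_equal(predict(tr2, inst$annotations), predict(tr, inst$annotations))
})
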