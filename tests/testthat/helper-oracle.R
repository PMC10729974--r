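# Brute-force multivariate CART oracle: enumerates every (node, annotation)
# split directly from sums of squared deviations, independently of the
# closed-form gain used by mvtree_grow. Used to verify split optimality.

oracle_sse <- function(mat) {
  mu <- colMeans(mat)
  sum(sweep(mat, 2L, mu)^2)
}

oracle_grow <- function(responses, annotations, minsize, maxdepth = Inf) {
  grow <- function(idx, depth) {
    n <- length(idx)
    Zs <- responses[idx, , drop = FALSE]
    dev <- oracle_sse(Zs)
    node <- list(n = n, pred = colMeans(Zs), split = NA_integer_,
                 children = NULL)
    if (n < 2L * minsize || depth >= maxdepth || dev <= 0)
      return(node)
    best_k <- NA_integer_
    best_child_sse <- Inf
    for (k in seq_len(ncol(annotations))) {
      right <- annotations[idx, k] == 1
      n1 <- sum(right)
      if (n1 < minsize || n - n1 < minsize) next
      child_sse <- oracle_sse(responses[idx[right], , drop = FALSE]) +
        oracle_sse(responses[idx[!right], , drop = FALSE])
      if (child_sse < best_child_sse) {   # strict: ties keep lowest index
        best_child_sse <- child_sse
        best_k <- k
      }
    }
    if (is.na(best_k) || !(dev - best_child_sse > 1e-10 * dev))
      return(node)
    right <- annotations[idx, best_k] == 1
    node$split <- best_k
    node$children <- list(grow(idx[!right], depth + 1L),
                          grow(idx[right], depth + 1L))
    node
  }
  grow(seq_len(nrow(responses)), 0L)
}

# flatten a tree (mvtree root node or oracle node) into a comparable
# signature: preorder list of split indices and leaf means
tree_signature <- function(node) {
  if (is.null(node$children))
    return(list(list(split = NA_integer_, n = node$n,
                     pred = round(unname(node$pred), 10))))
  c(list(list(split = node$split, n = node$n, pred = NULL)),
    tree_signature(node$children[[1L]]),
    tree_signature(node$children[[2L]]))
}

# small random problem instance for property tests
random_tree_instance <- function(M, K, minsize) {
  A <- matrix(rbinom(M * K, 1L, runif(K, 0.2, 0.8)[rep(seq_len(K), each = M)]),
              M, K, dimnames = list(NULL, paste0("A", seq_len(K))))
  # responses loosely driven by a couple of annotations plus noise
  Z <- matrix(runif(M * 4L), M, 4L)
  Z <- Z + A[, 1L] %o% runif(4L) + A[, min(2L, K)] %o% runif(4L)
  list(responses = Z, annotations = pleiotree::as_annotation_matrix(A))
}
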