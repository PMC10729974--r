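# Multivariate-response regression tree over binary annotation predictors.
#
# Splits minimize the within-node sum of squared deviations from the node
# mean, summed over all response columns (De'ath-style multivariate CART).
# Each binary annotation admits exactly one split (0 vs 1). Leaves predict
# the mean response vector of their training rows, so row sums of the
# training responses are preserved by prediction.
#
# For a candidate split of a node of size n into groups of size n1 and
# n0 = n - n1, the per-column SSE reduction has the closed form
#   d_j^2 * n / (n1 * n0),  d_j = S1_j - n1 * S_j / n,
# where S_j and S1_j are the column sums over the node and over group 1.
# This lets all K candidate gains at a node be computed with one crossprod.

# relative tolerance below which a gain is treated as no impurity reduction
GAIN_EPS <- 1e-10

#' Grow a full multivariate regression tree
#'
#' Recursively selects at each node the annotation split that maximizes the
#' reduction in total (across all response columns) within-node sum of
#' squares. Splitting stops when no candidate reduces the impurity, when the
#' node has fewer than `2 * minsize` rows, when either child would fall below
#' `minsize` rows, or at `maxdepth`.
#'
#' Ties in gain are broken toward the lowest annotation index, so the tree is
#' a deterministic function of its inputs.
#'
#' @param responses Numeric M x J response matrix (here J = 4 state
#'   probabilities, but any J works).
#' @param annotations M x K binary matrix from [as_annotation_matrix()].
#' @param minsize Minimum rows per leaf (default 20).
#' @param maxdepth Maximum tree depth; `Inf` (default) for unlimited.
#' @return An object of class `mvtree`.
#' @export
mvtree_grow <- function(responses, annotations, minsize = 20L, maxdepth = Inf) {
  responses <- as.matrix(responses)
  if (nrow(responses) != nrow(annotations))
    stop("responses and annotations must have the same number of rows")
  if (nrow(responses) < 1L)
    stop("empty input")
  K <- ncol(annotations)
  anames <- colnames(annotations)
  next_id <- 0L

  grow <- function(idx, depth) {
    next_id <<- next_id + 1L
    n <- length(idx)
    Zs <- responses[idx, , drop = FALSE]
    S <- colSums(Zs)
    mu <- S / n
    dev <- sum(Zs * Zs) - sum(S * mu)
    node <- list(id = next_id, n = n, dev = max(dev, 0), pred = mu,
                 split = NA_integer_, children = NULL)
    if (n < 2L * minsize || depth >= maxdepth || dev <= 0 || K == 0L)
      return(node)
    As <- annotations[idx, , drop = FALSE]
    n1 <- colSums(As)
    ok <- n1 >= minsize & (n - n1) >= minsize
    if (!any(ok))
      return(node)
    D <- crossprod(As, Zs) - outer(n1, mu)
    gains <- rowSums(D * D) * n / (n1 * (n - n1))
    gains[!ok] <- -Inf
    k <- which.max(gains)               # ties -> lowest annotation index
    if (!(gains[k] > GAIN_EPS * dev))
      return(node)
    right <- As[, k] == 1
    node$split <- as.integer(k)
    node$children <- list(grow(idx[!right], depth + 1L),
                          grow(idx[right], depth + 1L))
    node
  }

  root <- grow(seq_len(nrow(responses)), 0L)
  structure(list(root = root, annotation_names = anames,
                 root_dev = root$dev, minsize = as.integer(minsize)),
            class = "mvtree")
}

#' Cost-complexity pruning of a multivariate regression tree
#'
#' Collapses, bottom-up, every internal node whose subtree achieves an average
#' deviance reduction per split of at most `cp * root_deviance`. Collapsing at
#' equality yields the smallest tree among equal-cost candidates. `cp = 0`
#' leaves a tree grown by [mvtree_grow()] unchanged; `cp = 1` always reduces
#' to a single leaf.
#'
#' @param tree An `mvtree` object.
#' @param cp Complexity parameter in `[0, 1]`.
#' @return The pruned `mvtree`.
#' @export
mvtree_prune <- function(tree, cp) {
  if (!inherits(tree, "mvtree")) stop("not an mvtree")
  if (length(cp) != 1L || is.na(cp) || cp < 0 || cp > 1)
    stop("cp must be a scalar in [0, 1]")
  threshold <- cp * tree$root_dev

  prune <- function(node) {
    if (is.null(node$children))
      return(list(node = node, nsplit = 0L, leafdev = node$dev))
    l <- prune(node$children[[1L]])
    r <- prune(node$children[[2L]])
    node$children <- list(l$node, r$node)
    nsplit <- 1L + l$nsplit + r$nsplit
    reduction <- node$dev - (l$leafdev + r$leafdev)
    if (reduction / nsplit <= threshold) {
      node$split <- NA_integer_
      node$children <- NULL
      return(list(node = node, nsplit = 0L, leafdev = node$dev))
    }
    list(node = node, nsplit = nsplit, leafdev = l$leafdev + r$leafdev)
  }

  tree$root <- prune(tree$root)$node
  tree
}

#' Predict from a multivariate regression tree
#'
#' Routes each annotation vector to its leaf (left child for annotation value
#' 0, right for 1) and returns the leaf mean responses.
#'
#' @param object An `mvtree`.
#' @param annotations M x K binary matrix whose column names include every
#'   annotation used in a split.
#' @param ... Unused.
#' @return M x J matrix of leaf predictions.
#' @export
predict.mvtree <- function(object, annotations, ...) {
  anames <- colnames(annotations)
  used <- tree_selected_indices(object$root)
  missing_ann <- setdiff(object$annotation_names[used], anames)
  if (length(missing_ann) > 0)
    stop("annotations used in tree splits are missing: ",
         paste(missing_ann, collapse = ", "))
  out <- matrix(NA_real_, nrow(annotations), length(object$root$pred))
  route <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (is.null(node$children)) {
      out[idx, ] <<- rep(node$pred, each = length(idx))
      return(invisible())
    }
    col <- match(object$annotation_names[node$split], anames)
    right <- annotations[idx, col] == 1
    route(node$children[[1L]], idx[!right])
    route(node$children[[2L]], idx[right])
  }
  route(object$root, seq_len(nrow(annotations)))
  rownames(out) <- rownames(annotations)
  out
}

tree_selected_indices <- function(node) {
  if (is.null(node$children)) return(integer(0))
  sort(unique(c(node$split,
                tree_selected_indices(node$children[[1L]]),
                tree_selected_indices(node$children[[2L]]))))
}

#' Annotations used in any split of a tree
#'
#' @param tree An `mvtree` (or a fitted [pleiotree()] model).
#' @return Character vector of annotation names, in annotation order; empty
#'   for a single-leaf tree.
#' @export
selected_annotations <- function(tree) {
  if (inherits(tree, "pleiotree")) tree <- tree$tree
  if (!inherits(tree, "mvtree")) stop("not an mvtree")
  tree$annotation_names[tree_selected_indices(tree$root)]
}

#' Root-to-leaf annotation combinations
#'
#' One entry per leaf, giving the conjunction of `annotation = value`
#' conditions along the path, the leaf's mean prediction and its training
#' size. A single-leaf tree yields one combination with no conditions.
#'
#' @param tree An `mvtree` (or fitted `pleiotree` model).
#' @return A list with elements `combinations` (list of
#'   `list(conditions, prediction, n)` where `conditions` is a data frame
#'   with columns `annotation`, `value`) and `selected` (deduplicated
#'   annotation names used in splits).
#' @export
tree_combinations <- function(tree) {
  if (inherits(tree, "pleiotree")) tree <- tree$tree
  if (!inherits(tree, "mvtree")) stop("not an mvtree")
  combos <- list()
  walk <- function(node, conds) {
    if (is.null(node$children)) {
      combos[[length(combos) + 1L]] <<-
        list(conditions = conds, prediction = node$pred, n = node$n)
      return(invisible())
    }
    nm <- tree$annotation_names[node$split]
    walk(node$children[[1L]],
         rbind(conds, data.frame(annotation = nm, value = 0L)))
    walk(node$children[[2L]],
         rbind(conds, data.frame(annotation = nm, value = 1L)))
  }
  walk(tree$root, data.frame(annotation = character(0), value = integer(0)))
  list(combinations = combos, selected = selected_annotations(tree))
}

#' Number of leaves of a tree
#' @param tree An `mvtree`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(tree) {
  if (inherits(tree, "pleiotree")) tree <- tree$tree
  count <- function(node) {
    if (is.null(node$children)) return(1L)
    count(node$children[[1L]]) + count(node$children[[2L]])
  }
  count(tree$root)
}

#' @export
print.mvtree <- function(x, digits = 4, ...) {
  cat("Multivariate regression tree (", n_leaves(x), " leaves)\n", sep = "")
  show <- function(node, prefix, label) {
    cat(prefix, label, " n=", node$n,
        "  pred=(", paste(formatC(node$pred, digits = digits, format = "f"),
                          collapse = ", "), ")",
        if (!is.null(node$children))
          paste0("  split: ", x$annotation_names[node$split]),
        "\n", sep = "")
    if (!is.null(node$children)) {
      nm <- x$annotation_names[node$split]
      show(node$children[[1L]], paste0(prefix, "  "), paste0(nm, "=0"))
      show(node$children[[2L]], paste0(prefix, "  "), paste0(nm, "=1"))
    }
  }
  show(x$root, "", "root")
  invisible(x)
}

# --- JSON serialization ----------------------------------------------------

node_to_list <- function(node, anames) {
  out <- list(node_id = node$id, n = node$n, deviance = node$dev,
              prediction = as.numeric(node$pred))
  if (is.null(node$children)) {
    out$split <- NULL
  } else {
    out$split <- anames[node$split]
    out$children <- list(node_to_list(node$children[[1L]], anames),
                         node_to_list(node$children[[2L]], anames))
  }
  out
}

#' Serialize a tree to canonical JSON
#' @param tree An `mvtree`.
#' @return A JSON string (class `json`).
#' @export
tree_to_json <- function(tree) {
  if (inherits(tree, "pleiotree")) tree <- tree$tree
  jsonlite::toJSON(
    list(annotation_names = tree$annotation_names,
         root_deviance = tree$root_dev,
         minsize = tree$minsize,
         root = node_to_list(tree$root, tree$annotation_names)),
    auto_unbox = TRUE, digits = NA)
}

#' Reconstruct a tree from its JSON serialization
#' @param json A JSON string produced by [tree_to_json()].
#' @return An `mvtree`.
#' @export
tree_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  anames <- unlist(obj$annotation_names)
  build <- function(nd) {
    node <- list(id = as.integer(nd$node_id), n = as.integer(nd$n),
                 dev = as.numeric(nd$deviance),
                 pred = as.numeric(unlist(nd$prediction)),
                 split = NA_integer_, children = NULL)
    if (!is.null(nd$split)) {
      node$split <- match(nd$split, anames)
      node$children <- list(build(nd$children[[1L]]), build(nd$children[[2L]]))
    }
    node
  }
  structure(list(root = build(obj$root), annotation_names = anames,
                 root_dev = as.numeric(obj$root_deviance),
                 minsize = as.integer(obj$minsize)),
            class = "mvtree")
}
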