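#' Decision-tree training parameters
#'
#' Controls for greedy CART induction on rank-percentile data. The defaults
#' produce the shallow 3-5 gene trees that make good single-sample
#' classifiers on realistic cohorts; tests and forests override them.
#'
#' @param min_samples_split Minimum node size eligible for splitting.
#' @param min_leaf Minimum samples in each child of an accepted split.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param complexity Minimum impurity decrease to accept a split, as a
#'   fraction of the root Gini impurity (rpart-style `cp`).
#' @param feature_subset Optional character vector restricting the genes the
#'   tree may split on.
#' @return A `tree_params` list.
#' @export
tree_params <- function(min_samples_split = 20L, min_leaf = 7L,
                        max_depth = 5L, complexity = 0.01,
                        feature_subset = NULL) {
  stopifnot(min_samples_split >= 2L, min_leaf >= 1L, max_depth >= 1L,
            complexity >= 0)
  structure(list(min_samples_split = as.integer(min_samples_split),
                 min_leaf = as.integer(min_leaf),
                 max_depth = as.integer(max_depth),
                 complexity = as.numeric(complexity),
                 feature_subset = feature_subset),
            class = "tree_params")
}

# Best (feature, threshold) by weighted Gini for one node.
# X: samples x features percentile matrix (columns already in lexicographic
# gene-ID order so ties resolve to the lowest gene ID); y: 0/1 (1 = hypoxic);
# idx: row indices of the node; cand: candidate column indices.
# Returns NULL or list(col, threshold, gini).
best_split <- function(X, y, idx, cand, min_leaf) {
  n <- length(idx)
  best <- NULL
  yi <- y[idx]
  pos_tot <- sum(yi)
  for (j in cand) {
    v <- X[idx, j]
    ord <- order(v)
    vs <- v[ord]
    cum_pos <- cumsum(yi[ord])
    i <- seq_len(n - 1L)
    ok <- vs[i] < vs[i + 1L] & i >= min_leaf & (n - i) >= min_leaf
    if (!any(ok)) next
    i <- i[ok]
    nl <- i
    nr <- n - i
    pl <- cum_pos[i]
    pr <- pos_tot - pl
    # weighted Gini = (nl*gl + nr*gr)/n with g = 2p(1-p)
    wg <- (2 * pl * (nl - pl) / nl + 2 * pr * (nr - pr) / nr) / n
    k <- which.min(wg)                       # first minimum = lowest threshold
    if (is.null(best) || wg[k] < best$gini - 1e-12) {
      best <- list(col = j, threshold = (vs[i[k]] + vs[i[k] + 1L]) / 2,
                   gini = wg[k])
    }
  }
  best
}

# Core grower shared by fit_tree() and the random forest. X: samples x genes
# percentile matrix with lexicographically ordered columns; y: 0/1 integer.
# mtry: if not NULL, a fresh random feature subset of this size per split.
# Returns the flat node table (parent-before-child order).
grow_tree <- function(X, y, params, mtry = NULL) {
  n_root <- length(y)
  gini_root <- {
    p <- mean(y)
    2 * p * (1 - p)
  }
  p_feat <- ncol(X)
  nodes <- new.env(parent = emptyenv())
  nodes$rows <- list()
  add_node <- function(rec) {
    nodes$rows[[length(nodes$rows) + 1L]] <- rec
    length(nodes$rows)
  }
  build <- function(idx, depth) {
    n <- length(idx)
    p_hyp <- mean(y[idx])
    rec <- list(depth = depth, is_leaf = TRUE, gene = NA_character_,
                threshold = NA_real_,
                class = if (p_hyp > 0.5) "H" else "N",
                prob = p_hyp, frac = n / n_root,
                low_child = NA_integer_, high_child = NA_integer_)
    id <- add_node(rec)
    gini_node <- 2 * p_hyp * (1 - p_hyp)
    if (depth >= params$max_depth || n < params$min_samples_split ||
        gini_node == 0) {
      return(id)
    }
    cand <- if (is.null(mtry)) seq_len(p_feat) else sort(sample.int(p_feat, mtry))
    sp <- best_split(X, y, idx, cand, params$min_leaf)
    if (is.null(sp)) return(id)
    # sp$gini is already the weighted child impurity within this node
    decrease <- (n / n_root) * (gini_node - sp$gini)
    if (gini_root > 0 && decrease < params$complexity * gini_root) return(id)
    v <- X[idx, sp$col]
    lo <- build(idx[v < sp$threshold], depth + 1L)
    hi <- build(idx[v >= sp$threshold], depth + 1L)
    rec$is_leaf <- FALSE
    rec$gene <- colnames(X)[sp$col]
    rec$threshold <- sp$threshold
    rec$low_child <- lo
    rec$high_child <- hi
    nodes$rows[[id]] <- rec
    id
  }
  build(seq_len(n_root), 0L)
  rows <- nodes$rows
  tibble::tibble(
    node_id = seq_along(rows),
    depth = vapply(rows, `[[`, integer(1), "depth"),
    is_leaf = vapply(rows, `[[`, logical(1), "is_leaf"),
    gene = vapply(rows, `[[`, character(1), "gene"),
    threshold = vapply(rows, `[[`, numeric(1), "threshold"),
    class = vapply(rows, `[[`, character(1), "class"),
    prob = vapply(rows, `[[`, numeric(1), "prob"),
    frac = vapply(rows, `[[`, numeric(1), "frac"),
    low_child = vapply(rows, `[[`, integer(1), "low_child"),
    high_child = vapply(rows, `[[`, integer(1), "high_child")
  )
}

new_hypoxia_tree <- function(nodes, tree_id = "1", metadata = list()) {
  structure(list(nodes = nodes, tree_id = tree_id, metadata = metadata),
            class = "hypoxia_tree")
}

# 0/1 hypoxia indicator from a label vector or labels tibble
as_hypoxia_indicator <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("normoxic", "hypoxic"))
  if (length(bad)) {
    stop("unknown label(s): ", paste(bad, collapse = ", "),
         " (expected 'normoxic' or 'hypoxic')", call. = FALSE)
  }
  as.integer(labels == "hypoxic")
}

#' Fit a CART decision tree on rank percentiles
#'
#' Greedy binary recursive partitioning. At each node the (gene, threshold)
#' pair minimizing the weighted Gini impurity of the two children is chosen;
#' thresholds are midpoints between consecutive distinct observed
#' percentiles, and samples with percentile `>= threshold` follow the high
#' branch. Recursion stops on depth, node size, leaf size, purity, or
#' insufficient impurity decrease. Each leaf stores the fraction of hypoxic
#' training samples as its hypoxia probability. Ties in the split search are
#' broken toward the lexicographically smallest gene ID, then the lowest
#' threshold, so training is deterministic.
#'
#' @param rpm Rank-percentile matrix (genes x samples) restricted or not;
#'   see [rank_percentile()].
#' @param labels Sample labels: tibble with `sample_id`/`label` columns or a
#'   character vector in `{normoxic, hypoxic}` aligned with `colnames(rpm)`.
#'   A single-class dataset yields a single-leaf tree.
#' @param params A [tree_params()].
#' @param tree_id Identifier stored in the tree.
#' @return A `hypoxia_tree`: flat node table (`$nodes`), `$tree_id`,
#'   `$metadata`.
#' @export
fit_tree <- function(rpm, labels, params = tree_params(), tree_id = "1") {
  if (!is.matrix(rpm) || ncol(rpm) == 0L) {
    stop("rpm must be a non-empty percentile matrix", call. = FALSE)
  }
  y <- as_hypoxia_indicator(labels)
  if (length(y) != ncol(rpm)) {
    stop("labels length must match the number of samples", call. = FALSE)
  }
  genes <- rownames(rpm)
  if (!is.null(params$feature_subset)) {
    rpm <- subset_genes(rpm, params$feature_subset, on_missing = "error")
    genes <- rownames(rpm)
  }
  ord <- order(genes, method = "radix")
  X <- t(rpm[ord, , drop = FALSE])
  nodes <- grow_tree(X, y, params)
  new_hypoxia_tree(nodes, tree_id = tree_id)
}

#' Genes referenced by a tree's internal nodes
#' @param tree A `hypoxia_tree`.
#' @return Character vector of gene IDs (possibly empty for a single leaf).
#' @export
tree_genes <- function(tree) {
  unique(tree$nodes$gene[!tree$nodes$is_leaf])
}

#' Per-sample hypoxia probability from one tree
#'
#' Routes each sample (column) from the root to a leaf: at an internal node
#' the sample follows the high branch iff its percentile for the node's gene
#' is `>=` the node's threshold. Returns the reached leaf's hypoxia
#' probability.
#'
#' @param tree A `hypoxia_tree`.
#' @param rpm Rank-percentile matrix containing every gene the tree uses.
#' @return Named numeric vector of probabilities in `[0, 1]`.
#' @export
predict_tree <- function(tree, rpm) {
  nodes <- tree$nodes
  need <- tree_genes(tree)
  absent <- setdiff(need, rownames(rpm))
  if (length(absent)) {
    stop("tree ", tree$tree_id, " requires gene(s) absent from matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  n <- ncol(rpm)
  cur <- rep(1L, n)
  repeat {
    live <- which(!nodes$is_leaf[cur])
    if (!length(live)) break
    nid <- cur[live]
    val <- rpm[cbind(match(nodes$gene[nid], rownames(rpm)), live)]
    cur[live] <- ifelse(val >= nodes$threshold[nid],
                        nodes$high_child[nid], nodes$low_child[nid])
  }
  stats::setNames(nodes$prob[cur], colnames(rpm))
}

format_node_line <- function(nodes, id) {
  leaf_part <- sprintf("%s p=%.2f n=%.0f%%",
                       nodes$class[id], nodes$prob[id], 100 * nodes$frac[id])
  if (nodes$is_leaf[id]) leaf_part
  else sprintf("%s >= %s? %s", nodes$gene[id],
               format(nodes$threshold[id], digits = 6), leaf_part)
}

#' Render a tree as indented text
#'
#' One line per node: gene and threshold for internal nodes, then class
#' (N/H), hypoxia probability and the percentage of training samples that
#' reached the node. The low (`no`) branch precedes the high (`yes`) branch.
#' Rendering is a pure function of the node table, so it is identical before
#' and after a serialization round-trip.
#'
#' @param tree A `hypoxia_tree`.
#' @return Character scalar (lines joined with newline).
#' @export
render_tree <- function(tree) {
  nodes <- tree$nodes
  walk <- function(id, indent, prefix) {
    line <- paste0(strrep("  ", indent), prefix, format_node_line(nodes, id))
    if (nodes$is_leaf[id]) return(line)
    c(line,
      walk(nodes$low_child[id], indent + 1L, "no:  "),
      walk(nodes$high_child[id], indent + 1L, "yes: "))
  }
  paste(walk(1L, 0L, ""), collapse = "\n")
}

#' @export
print.hypoxia_tree <- function(x, ...) {
  cat("<hypoxia_tree ", x$tree_id, ">\n", render_tree(x), "\n", sep = "")
  if (!is.null(x$metadata$holdout_accuracy)) {
    cat(sprintf("holdout accuracy %.3f, F1 %.3f\n",
                x$metadata$holdout_accuracy, x$metadata$holdout_f1))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Node table of a fitted tree
#' @param x A `hypoxia_tree`.
#' @param ... Unused.
#' @return Tibble with one row per node (id, depth, gene, threshold, class,
#'   hypoxia probability, training fraction, child ids).
#' @export
tidy.hypoxia_tree <- function(x, ...) x$nodes

#' One-row summary of a fitted tree
#' @param x A `hypoxia_tree`.
#' @param ... Unused.
#' @export
glance.hypoxia_tree <- function(x, ...) {
  tibble::tibble(
    tree_id = x$tree_id,
    n_nodes = nrow(x$nodes),
    n_leaves = sum(x$nodes$is_leaf),
    depth = max(x$nodes$depth),
    n_genes = length(tree_genes(x)),
    holdout_accuracy = x$metadata$holdout_accuracy %||% NA_real_,
    holdout_f1 = x$metadata$holdout_f1 %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
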