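# Small builders shared across test files.

random_expression <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rexp(n_genes * n_samples, rate = 0.1),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  # sprinkle zeros so tie blocks are exercised
  m[sample(length(m), ceiling(length(m) * 0.15))] <- 0
  m
}

random_percentiles <- function(n_genes, n_samples, seed) {
  suppressWarnings(rank_percentile(random_expression(n_genes, n_samples, seed)))
}

# Leaf-only tree with a fixed hypoxia probability.
leaf_tree <- function(prob, id = "leaf") {
  nodes <- tibble::tibble(
    node_id = 1L, depth = 0L, is_leaf = TRUE, gene = NA_character_,
    threshold = NA_real_, class = if (prob > 0.5) "H" else "N",
    prob = prob, frac = 1, low_child = NA_integer_, high_child = NA_integer_
  )
  structure(list(nodes = nodes, tree_id = id, metadata = list()),
            class = "hypoxia_tree")
}

# Depth-1 tree splitting on one gene: low branch prob_low, high prob_high.
stump_tree <- function(gene, threshold, prob_low = 0, prob_high = 1,
                       id = gene, accuracy = NA_real_, f1 = NA_real_) {
  nodes <- tibble::tibble(
    node_id = 1:3,
    depth = c(0L, 1L, 1L),
    is_leaf = c(FALSE, TRUE, TRUE),
    gene = c(gene, NA, NA),
    threshold = c(threshold, NA, NA),
    class = c(if (mean(c(prob_low, prob_high)) > 0.5) "H" else "N",
              if (prob_low > 0.5) "H" else "N",
              if (prob_high > 0.5) "H" else "N"),
    prob = c(mean(c(prob_low, prob_high)), prob_low, prob_high),
    frac = c(1, 0.5, 0.5),
    low_child = c(2L, NA, NA),
    high_child = c(3L, NA, NA)
  )
  structure(list(nodes = nodes, tree_id = id,
                 metadata = list(holdout_accuracy = accuracy, holdout_f1 = f1)),
            class = "hypoxia_tree")
}

as_ensemble <- function(...) {
  structure(list(trees = list(...), provenance = list()),
            class = "hypoxia_ensemble")
}

as_population <- function(...) structure(list(...), class = "tree_population")

# quick labeled percentile dataset wrapper for validation-set arguments
val_set <- function(rpm, labels) list(matrix = rpm, labels = labels)
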