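#' Random-forest parameters
#'
#' Defaults follow the tuned values used throughout the workflow: 200 trees
#' with 10 candidate genes per split, grown on bootstrap resamples.
#'
#' @param n_trees Number of trees (>= 1).
#' @param features_per_split Genes sampled afresh at each split (mtry); must
#'   not exceed the number of candidate genes.
#' @param bootstrap Grow each tree on a bootstrap resample (out-of-bag
#'   samples are recorded either way; with `bootstrap = FALSE` every tree
#'   sees all samples and has no OOB set).
#' @param seed Integer seed for bootstrap and per-split feature draws.
#' @return A `forest_params` list.
#' @export
forest_params <- function(n_trees = 200L, features_per_split = 10L,
                          bootstrap = TRUE, seed = 1L) {
  stopifnot(n_trees >= 1L, features_per_split >= 1L)
  structure(list(n_trees = as.integer(n_trees),
                 features_per_split = as.integer(features_per_split),
                 bootstrap = isTRUE(bootstrap),
                 seed = as.integer(seed)),
            class = "forest_params")
}

# Tree controls used inside forests: essentially unpruned CART, as is
# standard for classification forests.
forest_tree_params <- function() {
  tree_params(min_samples_split = 2L, min_leaf = 1L, max_depth = 12L,
              complexity = 0)
}

#' Fit a random forest on rank percentiles
#'
#' Grows `n_trees` CART trees (see [fit_tree()]) on bootstrap resamples with
#' a fresh random subset of `features_per_split` genes considered at every
#' split. Out-of-bag (OOB) sample indices are recorded per tree; the forest
#' predicts by majority vote over per-tree leaf classes. The forest is used
#' for feature selection via permutation importance, not as the final
#' classifier.
#'
#' @param rpm Rank-percentile matrix (genes x samples).
#' @param labels Labels as in [fit_tree()]; both classes must be present.
#' @param params A [forest_params()].
#' @param tree_control [tree_params()] for the individual trees.
#' @return A `hypoxia_forest`: `$trees` (node tables), `$oob` (list of OOB
#'   column indices), `$genes`, `$params`.
#' @export
fit_forest <- function(rpm, labels, params = forest_params(),
                       tree_control = forest_tree_params()) {
  y <- as_hypoxia_indicator(labels)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to fit a forest", call. = FALSE)
  }
  if (params$features_per_split > nrow(rpm)) {
    stop("features_per_split (", params$features_per_split,
         ") exceeds the number of genes (", nrow(rpm), ")", call. = FALSE)
  }
  ord <- order(rownames(rpm), method = "radix")
  X <- t(rpm[ord, , drop = FALSE])
  n <- nrow(X)
  with_local_seed(params$seed, {
    trees <- vector("list", params$n_trees)
    oob <- vector("list", params$n_trees)
    for (t in seq_len(params$n_trees)) {
      inbag <- if (params$bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      oob[[t]] <- setdiff(seq_len(n), inbag)
      trees[[t]] <- grow_tree(X[inbag, , drop = FALSE], y[inbag],
                              tree_control, mtry = params$features_per_split)
    }
    structure(list(trees = trees, oob = oob, genes = colnames(X),
                   params = params, n_samples = n),
              class = "hypoxia_forest")
  })
}

#' @export
print.hypoxia_forest <- function(x, ...) {
  cat("<hypoxia_forest> ", length(x$trees), " trees, ",
      length(x$genes), " genes, mtry = ", x$params$features_per_split,
      "\n", sep = "")
  invisible(x)
}

# Route samples (rows of X, columns already gene-sorted) through one node
# table; returns leaf probabilities.
route_tree <- function(nodes, X, gene_index) {
  n <- nrow(X)
  cur <- rep(1L, n)
  repeat {
    live <- which(!nodes$is_leaf[cur])
    if (!length(live)) break
    nid <- cur[live]
    val <- X[cbind(live, gene_index[nodes$gene[nid]])]
    cur[live] <- ifelse(val >= nodes$threshold[nid],
                        nodes$high_child[nid], nodes$low_child[nid])
  }
  nodes$prob[cur]
}

#' Majority-vote forest prediction
#'
#' @param forest A `hypoxia_forest`.
#' @param rpm Rank-percentile matrix with all forest genes present.
#' @return Named character vector of labels (`hypoxic` when more than half
#'   of the trees vote hypoxic).
#' @export
predict_forest <- function(forest, rpm) {
  absent <- setdiff(forest$genes, rownames(rpm))
  if (length(absent)) {
    stop("matrix lacks gene(s): ", paste(utils::head(absent, 5), collapse = ", "),
         call. = FALSE)
  }
  X <- t(rpm[forest$genes, , drop = FALSE])
  gi <- stats::setNames(seq_along(forest$genes), forest$genes)
  votes <- vapply(forest$trees,
                  function(nd) as.integer(route_tree(nd, X, gi) > 0.5),
                  integer(nrow(X)))
  votes <- matrix(votes, nrow = nrow(X))
  stats::setNames(ifelse(rowMeans(votes) > 0.5, "hypoxic", "normoxic"),
                  colnames(rpm))
}

# OOB majority-vote accuracy of a fitted forest on its training matrix.
oob_accuracy <- function(forest, X, y) {
  n <- nrow(X)
  gi <- stats::setNames(seq_along(forest$genes), forest$genes)
  vote_h <- numeric(n)
  vote_n <- numeric(n)
  for (t in seq_along(forest$trees)) {
    o <- forest$oob[[t]]
    if (!length(o)) next
    ph <- route_tree(forest$trees[[t]], X[o, , drop = FALSE], gi)
    h <- ph > 0.5
    vote_h[o[h]] <- vote_h[o[h]] + 1
    vote_n[o[!h]] <- vote_n[o[!h]] + 1
  }
  seen <- vote_h + vote_n > 0
  pred <- vote_h[seen] > vote_n[seen]
  mean(pred == (y[seen] == 1L))
}

#' Out-of-bag accuracy of a forest
#'
#' @param forest A `hypoxia_forest`.
#' @param rpm The training rank-percentile matrix.
#' @param labels The training labels.
#' @return OOB majority-vote accuracy over samples that were OOB at least
#'   once.
#' @export
forest_oob_accuracy <- function(forest, rpm, labels) {
  y <- as_hypoxia_indicator(labels)
  X <- t(rpm[forest$genes, , drop = FALSE])
  oob_accuracy(forest, X, y)
}

#' Permutation importance (mean decrease in accuracy)
#'
#' The feature-selection statistic of the workflow. At each of
#' `n_iterations` iterations, 70% of the samples are drawn without
#' replacement and a forest is grown on them. For every gene, each tree's
#' OOB accuracy is compared with its OOB accuracy after permuting that
#' gene's values among the tree's OOB samples; the per-tree decreases are
#' averaged over all trees of the forest (trees that never split on the gene
#' contribute exactly zero, since permuting an unused gene cannot change
#' routing). The per-iteration values are averaged and reported as raw
#' accuracy percentage points, the scale on which the selection threshold
#' (default 4 points) is applied.
#'
#' @param rpm Rank-percentile matrix (genes x samples), typically already
#'   restricted to a candidate signature.
#' @param labels Labels as in [fit_tree()].
#' @param params [forest_params()] for the per-iteration forests.
#' @param n_iterations Number of resample-and-refit iterations (>= 1).
#' @param resample_frac Fraction of samples drawn (without replacement) per
#'   iteration.
#' @param scale If `TRUE`, divide each gene's mean decrease by its standard
#'   error over iterations (z-score-style scaling, the randomForest display
#'   convention; `sd_mda` stays on the raw scale). Off by default, so
#'   `mean_mda` reads in accuracy points. When many informative genes are
#'   mutually redundant, each is consulted by few trees and raw MDA is
#'   diluted proportionally; an absolute threshold such as the selection
#'   default of 4 is then only meaningful on the scaled statistic, which is
#'   what the selection pipeline uses.
#' @return An importance table: tibble with `gene`, `mean_mda`, `sd_mda`,
#'   `n_iter`, sorted by decreasing `mean_mda`.
#' @export
permutation_importance <- function(rpm, labels, params = forest_params(),
                                   n_iterations = 1000L,
                                   resample_frac = 0.7, scale = FALSE) {
  if (n_iterations < 1L) stop("n_iterations must be >= 1", call. = FALSE)
  y_all <- as_hypoxia_indicator(labels)
  ord <- order(rownames(rpm), method = "radix")
  X_all <- t(rpm[ord, , drop = FALSE])
  genes <- colnames(X_all)
  p <- length(genes)
  gi <- stats::setNames(seq_len(p), genes)
  n_all <- nrow(X_all)
  n_sub <- max(2L, floor(resample_frac * n_all))
  tree_control <- forest_tree_params()
  mda <- matrix(0, nrow = n_iterations, ncol = p, dimnames = list(NULL, genes))
  with_local_seed(params$seed, {
    for (it in seq_len(n_iterations)) {
      sub <- sample.int(n_all, n_sub)
      X <- X_all[sub, , drop = FALSE]
      y <- y_all[sub]
      if (length(unique(y)) < 2L) next   # degenerate resample: no signal
      n <- nrow(X)
      drops <- numeric(p)
      for (t in seq_len(params$n_trees)) {
        inbag <- if (params$bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
        oob <- setdiff(seq_len(n), inbag)
        nd <- grow_tree(X[inbag, , drop = FALSE], y[inbag], tree_control,
                        mtry = min(params$features_per_split, p))
        if (!length(oob)) next
        Xo <- X[oob, , drop = FALSE]
        yo <- y[oob]
        base_acc <- mean((route_tree(nd, Xo, gi) > 0.5) == (yo == 1L))
        used <- unique(nd$gene[!nd$is_leaf])
        for (g in used) {
          Xp <- Xo
          Xp[, gi[[g]]] <- Xp[sample.int(nrow(Xp)), gi[[g]]]
          perm_acc <- mean((route_tree(nd, Xp, gi) > 0.5) == (yo == 1L))
          drops[gi[[g]]] <- drops[gi[[g]]] + (base_acc - perm_acc)
        }
      }
      mda[it, ] <- 100 * drops / params$n_trees
    }
  })
  out <- tibble::tibble(
    gene = genes,
    mean_mda = unname(colMeans(mda)),
    sd_mda = unname(apply(mda, 2L, stats::sd)),
    n_iter = n_iterations
  )
  if (scale) {
    se <- out$sd_mda / sqrt(n_iterations)
    out$mean_mda <- ifelse(se > 0, out$mean_mda / se, 0)
  }
  dplyr::arrange(out, dplyr::desc(.data$mean_mda), .data$gene)
}

#' Select genes by importance threshold
#'
#' Keeps genes whose mean decrease in accuracy strictly exceeds
#' `mda_threshold`, ordered by decreasing importance.
#'
#' @param importance Importance table from [permutation_importance()].
#' @param mda_threshold Threshold in accuracy percentage points (default 4).
#' @return Character vector of selected gene IDs (warns when empty).
#' @export
select_features <- function(importance, mda_threshold = 4) {
  stopifnot(is.data.frame(importance), nrow(importance) > 0,
            all(c("gene", "mean_mda") %in% names(importance)))
  keep <- importance |>
    dplyr::filter(.data$mean_mda > mda_threshold) |>
    dplyr::arrange(dplyr::desc(.data$mean_mda), .data$gene)
  if (nrow(keep) == 0L) {
    warning("no gene exceeds MDA threshold ", mda_threshold, call. = FALSE)
  }
  keep$gene
}

#' Tune forest hyperparameters by cross-validation accuracy
#'
#' For every grid point, a forest is trained on a random 70% of the samples
#' and scored on the remaining 30%, repeated `n_cv` times; the grid point
#' with the highest mean holdout accuracy wins, ties going to the smaller
#' model (fewer trees, then smaller `features_per_split`).
#'
#' @param rpm Rank-percentile matrix.
#' @param labels Labels as in [fit_tree()].
#' @param grid Data frame with columns `features_per_split` and `n_trees`.
#' @param n_cv Number of random 70/30 splits per grid point.
#' @param train_frac Training fraction per split.
#' @param seed Integer seed.
#' @return List with `params` (the chosen [forest_params()]) and `accuracy`
#'   (tibble: one row per grid point with `mean_accuracy`).
#' @export
tune_hyperparameters <- function(rpm, labels, grid, n_cv = 100L,
                                 train_frac = 0.7, seed = 1L) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0,
            all(c("features_per_split", "n_trees") %in% names(grid)))
  if (any(grid$features_per_split > nrow(rpm)) || any(grid$n_trees < 1)) {
    stop("grid contains invalid forest parameters", call. = FALSE)
  }
  y <- as_hypoxia_indicator(labels)
  n <- ncol(rpm)
  acc <- with_local_seed(seed, {
    purrr::pmap_dbl(grid[c("features_per_split", "n_trees")], function(features_per_split, n_trees) {
      mean(vapply(seq_len(n_cv), function(i) {
        tr <- sample.int(n, max(2L, floor(train_frac * n)))
        if (length(unique(y[tr])) < 2L) return(NA_real_)
        f <- fit_forest(rpm[, tr, drop = FALSE], ifelse(y[tr] == 1L, "hypoxic", "normoxic"),
                        forest_params(n_trees = n_trees,
                                      features_per_split = features_per_split,
                                      seed = sample.int(.Machine$integer.max, 1)))
        pred <- predict_forest(f, rpm[, -tr, drop = FALSE])
        mean((pred == "hypoxic") == (y[-tr] == 1L))
      }, numeric(1)), na.rm = TRUE)
    })
  })
  tab <- tibble::as_tibble(grid)
  tab$mean_accuracy <- acc
  best <- tab |>
    dplyr::arrange(dplyr::desc(.data$mean_accuracy), .data$n_trees,
                   .data$features_per_split) |>
    dplyr::slice(1L)
  list(params = forest_params(n_trees = best$n_trees,
                              features_per_split = best$features_per_split,
                              seed = seed),
       accuracy = tab)
}
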