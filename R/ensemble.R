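#' Mass-generate candidate decision trees with holdout scores
#'
#' Implements the tree-generation stage of the workflow: each candidate tree
#' is trained on an independent random `train_frac` split of the samples,
#' restricted to `candidate_genes`, and scored (accuracy and F1, hypoxic as
#' the positive class) on its own held-out remainder. Defaults are 10000
#' candidates and a 70/30 split. A split that leaves a single class in the
#' training set is redrawn (up to 50 retries, then an error).
#'
#' @param rpm Rank-percentile matrix (genes x samples).
#' @param labels Labels as in [fit_tree()].
#' @param candidate_genes Genes the trees may split on; must all be present
#'   in `rpm`.
#' @param n_candidates Number of candidate trees (0 gives an empty
#'   population).
#' @param train_frac Training fraction in (0, 1).
#' @param params [tree_params()] for individual trees.
#' @param seed Integer seed.
#' @return A `tree_population`: list of `hypoxia_tree` with
#'   `metadata$holdout_accuracy` / `metadata$holdout_f1` set and
#'   `tree_id` = "1", "2", ...
#' @export
generate_tree_population <- function(rpm, labels, candidate_genes,
                                     n_candidates = 10000L, train_frac = 0.7,
                                     params = tree_params(), seed = 1L) {
  stopifnot(train_frac > 0, train_frac < 1)
  absent <- setdiff(candidate_genes, rownames(rpm))
  if (length(absent)) {
    stop("candidate gene(s) absent from matrix: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  }
  y <- as_hypoxia_indicator(labels)
  sub <- rpm[candidate_genes, , drop = FALSE]
  n <- ncol(sub)
  n_train <- max(2L, floor(train_frac * n))
  trees <- with_local_seed(seed, {
    purrr::map(seq_len(n_candidates), function(i) {
      for (try in seq_len(50L)) {
        tr <- sample.int(n, n_train)
        if (length(unique(y[tr])) == 2L) break
        if (try == 50L) {
          stop("could not draw a training split containing both classes",
               call. = FALSE)
        }
      }
      tree <- fit_tree(sub[, tr, drop = FALSE],
                       ifelse(y[tr] == 1L, "hypoxic", "normoxic"),
                       params, tree_id = as.character(i))
      ho <- setdiff(seq_len(n), tr)
      prob <- predict_tree(tree, sub[, ho, drop = FALSE])
      m <- binary_metrics(y[ho], as.integer(prob > 0.5))
      tree$metadata$holdout_accuracy <- m$accuracy
      tree$metadata$holdout_f1 <- m$f1
      tree
    })
  })
  structure(trees, class = "tree_population")
}

#' @export
print.tree_population <- function(x, ...) {
  acc <- vapply(x, function(t) t$metadata$holdout_accuracy, numeric(1))
  cat("<tree_population> ", length(x), " candidate trees",
      if (length(x)) sprintf(", holdout accuracy %.2f-%.2f", min(acc), max(acc)),
      "\n", sep = "")
  invisible(x)
}

#' Per-tree metric table for a population or ensemble
#' @param x A `tree_population` or `hypoxia_ensemble`.
#' @param ... Unused.
#' @return Tibble with `tree_id`, `holdout_accuracy`, `holdout_f1`,
#'   `n_genes`, `genes` (list-column).
#' @export
tidy.tree_population <- function(x, ...) {
  trees <- if (inherits(x, "hypoxia_ensemble")) x$trees else x
  purrr::map_dfr(trees, function(t) {
    tibble::tibble(tree_id = t$tree_id,
                   holdout_accuracy = t$metadata$holdout_accuracy %||% NA_real_,
                   holdout_f1 = t$metadata$holdout_f1 %||% NA_real_,
                   mean_f1 = t$metadata$mean_f1 %||% NA_real_,
                   n_genes = length(tree_genes(t)),
                   genes = list(tree_genes(t)))
  })
}

#' @export
tidy.hypoxia_ensemble <- tidy.tree_population

new_hypoxia_ensemble <- function(trees, provenance = list()) {
  structure(list(trees = trees, provenance = provenance),
            class = "hypoxia_ensemble")
}

#' @export
print.hypoxia_ensemble <- function(x, ...) {
  cat("<hypoxia_ensemble> ", length(x$trees), " trees using ",
      length(unique(unlist(purrr::map(x$trees, tree_genes)))), " genes\n",
      sep = "")
  invisible(x)
}

#' @export
length.hypoxia_ensemble <- function(x) length(x$trees)

#' One-row ensemble summary
#' @param x A `hypoxia_ensemble`.
#' @param ... Unused.
#' @export
glance.hypoxia_ensemble <- function(x, ...) {
  acc <- vapply(x$trees, function(t) t$metadata$holdout_accuracy %||% NA_real_,
                numeric(1))
  tibble::tibble(
    n_trees = length(x$trees),
    n_genes = length(unique(unlist(purrr::map(x$trees, tree_genes)))),
    min_holdout_accuracy = if (length(acc)) suppressWarnings(min(acc, na.rm = TRUE)) else NA_real_,
    mean_holdout_accuracy = if (length(acc)) mean(acc, na.rm = TRUE) else NA_real_
  )
}

#' Keep candidate trees above a holdout-accuracy cutoff
#'
#' Retains trees whose holdout accuracy is strictly greater than
#' `min_accuracy` (default 0.95, the workflow's published cutoff).
#'
#' @param population A `tree_population`.
#' @param min_accuracy Strict lower bound on holdout accuracy.
#' @param deduplicate Drop structurally identical trees (same node table),
#'   keeping the one with the lowest `tree_id`.
#' @return A `hypoxia_ensemble` (warns when empty).
#' @export
filter_by_accuracy <- function(population, min_accuracy = 0.95,
                               deduplicate = FALSE) {
  stopifnot(inherits(population, "tree_population"), length(population) > 0)
  keep <- purrr::keep(unclass(population),
                      function(t) t$metadata$holdout_accuracy > min_accuracy)
  if (deduplicate && length(keep) > 1L) {
    sig <- vapply(keep, function(t) {
      paste(capture_node_signature(t), collapse = ";")
    }, character(1))
    keep <- keep[!duplicated(sig)]
  }
  if (length(keep) == 0L) {
    warning("no tree exceeds accuracy ", min_accuracy,
            "; returning an empty ensemble", call. = FALSE)
  }
  new_hypoxia_ensemble(keep, provenance = list(min_accuracy = min_accuracy,
                                               n_candidates = length(population)))
}

capture_node_signature <- function(tree) {
  with(tree$nodes, sprintf("%s|%.10g|%s|%.10g|%d|%d",
                           ifelse(is.na(gene), "", gene),
                           ifelse(is.na(threshold), -1, threshold),
                           class, prob,
                           ifelse(is.na(low_child), 0L, low_child),
                           ifelse(is.na(high_child), 0L, high_child)))
}

#' Keep the top-k trees by mean F1 across validation sets
#'
#' Scores every tree on each validation set (F1 with hypoxic positive,
#' probability threshold 0.5) and keeps the `k` trees with the highest
#' unweighted mean F1. A validation set lacking a gene a tree needs is
#' skipped for that tree with a warning. Ties go to the higher holdout
#' accuracy, then the lower `tree_id`.
#'
#' @param ensemble A `hypoxia_ensemble`.
#' @param k Number of trees to keep (<= ensemble size).
#' @param validation_sets List of validation sets; each is a
#'   `labeled_dataset` whose `$matrix` is a rank-percentile matrix, or a
#'   list with `$matrix` and `$labels`.
#' @return A `hypoxia_ensemble` of `k` trees with `metadata$mean_f1` set.
#' @export
select_top_k_by_f1 <- function(ensemble, k = 20L, validation_sets) {
  stopifnot(inherits(ensemble, "hypoxia_ensemble"),
            k >= 1L, k <= length(ensemble$trees),
            is.list(validation_sets), length(validation_sets) >= 1L)
  scored <- purrr::map(ensemble$trees, function(tree) {
    f1s <- purrr::map_dbl(validation_sets, function(vs) {
      need <- tree_genes(tree)
      if (length(setdiff(need, rownames(vs$matrix)))) {
        warning("tree ", tree$tree_id, ": validation set lacks gene(s) ",
                paste(setdiff(need, rownames(vs$matrix)), collapse = ", "),
                "; skipping this set", call. = FALSE)
        return(NA_real_)
      }
      prob <- predict_tree(tree, vs$matrix)
      y <- as_hypoxia_indicator(vs$labels)
      binary_metrics(y, as.integer(prob > 0.5))$f1
    })
    tree$metadata$mean_f1 <- mean(f1s, na.rm = TRUE)
    tree
  })
  ord <- order(-vapply(scored, function(t) t$metadata$mean_f1, numeric(1)),
               -vapply(scored, function(t) t$metadata$holdout_accuracy %||% -Inf,
                       numeric(1)),
               vapply(scored, function(t) t$tree_id, character(1)),
               method = "radix")
  new_hypoxia_ensemble(scored[ord[seq_len(k)]],
                       provenance = c(ensemble$provenance,
                                      list(top_k_by_f1 = k)))
}

#' Drop trees that need unavailable genes
#'
#' Retains exactly the trees whose referenced genes are all in
#' `available_genes`. This is the supported way to apply the classifier to
#' datasets missing signature genes (e.g. a lncRNA with no ortholog in the
#' target species): rather than imputing, use the trees that never consult
#' the missing gene.
#'
#' @param ensemble A non-empty `hypoxia_ensemble`.
#' @param available_genes Character vector of genes present in the target
#'   data.
#' @return A `hypoxia_ensemble`. If no tree survives, an error lists the
#'   missing genes whose addition would unblock the most trees.
#' @export
filter_by_available_features <- function(ensemble, available_genes) {
  stopifnot(inherits(ensemble, "hypoxia_ensemble"), length(ensemble$trees) > 0)
  ok <- purrr::map_lgl(ensemble$trees,
                       function(t) length(setdiff(tree_genes(t), available_genes)) == 0L)
  if (!any(ok)) {
    missing_counts <- sort(table(unlist(purrr::map(
      ensemble$trees, function(t) setdiff(tree_genes(t), available_genes)
    ))), decreasing = TRUE)
    stop("no tree is compatible with the available genes; ",
         "providing these genes would unblock the most trees: ",
         paste(utils::head(names(missing_counts), 5), collapse = ", "),
         call. = FALSE)
  }
  new_hypoxia_ensemble(ensemble$trees[ok],
                       provenance = c(ensemble$provenance,
                                      list(feature_filtered = TRUE)))
}

#' Consensus classification of samples by a tree ensemble
#'
#' Each tree contributes its leaf hypoxia probability; the consensus score
#' is the unweighted mean over trees, and a sample is labeled hypoxic iff
#' its mean probability is strictly greater than `threshold` (default 0.5,
#' i.e. "over 50%").
#'
#' @param ensemble A non-empty `hypoxia_ensemble` whose genes are all
#'   present in `rpm` (use [filter_by_available_features()] first if not).
#' @param rpm Rank-percentile matrix of the samples to classify.
#' @param threshold Strict decision threshold in `[0, 1]`.
#' @return A `classification_result`: `$samples` tibble (`sample_id`,
#'   `mean_prob`, `label`, `n_trees_used`), `$tree_probs` (trees x samples
#'   matrix), `$threshold`.
#' @export
ensemble_predict <- function(ensemble, rpm, threshold = 0.5) {
  stopifnot(inherits(ensemble, "hypoxia_ensemble"))
  if (length(ensemble$trees) == 0L) {
    stop("cannot predict with an empty ensemble", call. = FALSE)
  }
  probs <- t(vapply(ensemble$trees, function(t) predict_tree(t, rpm),
                    numeric(ncol(rpm))))
  rownames(probs) <- vapply(ensemble$trees, function(t) t$tree_id, character(1))
  colnames(probs) <- colnames(rpm)
  mean_prob <- colMeans(probs)
  structure(list(
    samples = tibble::tibble(
      sample_id = colnames(rpm),
      mean_prob = unname(mean_prob),
      label = ifelse(mean_prob > threshold, "hypoxic", "normoxic"),
      n_trees_used = length(ensemble$trees)
    ),
    tree_probs = probs,
    threshold = threshold
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat("<classification_result> ", nrow(x$samples), " samples, ",
      sum(x$samples$label == "hypoxic"), " called hypoxic (threshold ",
      x$threshold, ", ", x$samples$n_trees_used[1], " trees)\n", sep = "")
  invisible(x)
}

#' Per-sample classification table
#' @param x A `classification_result`.
#' @param ... Unused.
#' @export
tidy.classification_result <- function(x, ...) x$samples

# Confusion-matrix metrics; y and pred are 0/1 with 1 = hypoxic (positive).
binary_metrics <- function(y, pred) {
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  tn <- sum(pred == 0L & y == 0L)
  precision_defined <- (tp + fp) > 0
  precision <- if (precision_defined) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = (tp + tn) / length(y),
       precision = precision, recall = recall, f1 = f1,
       precision_defined = precision_defined)
}

#' Score a classification against known labels
#'
#' Confusion counts and derived metrics with hypoxic as the positive class.
#' When no sample is called hypoxic, precision is undefined; it is reported
#' as 0 with `precision_defined = FALSE`.
#'
#' @param labels True labels: tibble with `sample_id`/`label` or a character
#'   vector aligned with the result's samples.
#' @param result A `classification_result` (or a tibble with `sample_id`
#'   and `label` columns).
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`, `accuracy`, `precision`,
#'   `recall`, `f1`, `precision_defined`.
#' @export
evaluate <- function(labels, result) {
  pred_tab <- if (inherits(result, "classification_result")) result$samples else result
  stopifnot(all(c("sample_id", "label") %in% names(pred_tab)))
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$label, labels$sample_id)[pred_tab$sample_id]
    if (anyNA(labels)) stop("labels missing for some samples", call. = FALSE)
  }
  y <- as_hypoxia_indicator(as.character(labels))
  pred <- as_hypoxia_indicator(pred_tab$label)
  if (length(y) != length(pred)) {
    stop("labels do not align with classified samples", call. = FALSE)
  }
  m <- binary_metrics(y, pred)
  tibble::as_tibble(m[c("tp", "fp", "fn", "tn", "accuracy", "precision",
                        "recall", "f1", "precision_defined")])
}

#' ROC curve and AUC for consensus scores
#'
#' Sweeps the decision threshold over every distinct score: at each cutoff a
#' sample is called hypoxic iff its score is `>=` the cutoff. The curve
#' starts at (0, 0) and ends at (1, 1); the area is computed by the
#' trapezoid rule, so tied scores contribute 1/2 per discordant-tie pair
#' (equivalently, AUC is the Mann-Whitney concordance probability).
#'
#' @param labels True labels (both classes required).
#' @param scores Per-sample scores (e.g. `mean_prob` from
#'   [ensemble_predict()]), aligned with `labels`.
#' @return A `roc_curve`: `$roc` tibble (`threshold`, `fpr`, `tpr`) and
#'   `$auc`.
#' @export
roc_auc <- function(labels, scores) {
  y <- as_hypoxia_indicator(labels)
  stopifnot(length(y) == length(scores), !anyNA(scores))
  if (length(unique(y)) < 2L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  P <- sum(y == 1L)
  N <- sum(y == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  ys <- y[ord]
  last <- !duplicated(s, fromLast = TRUE)      # last index of each tied block
  tpr <- c(0, cumsum(ys)[last] / P)
  fpr <- c(0, cumsum(1 - ys)[last] / N)
  thr <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(roc = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.4f (%d thresholds)\n", x$auc, nrow(x$roc)))
  invisible(x)
}

#' ROC points of a fitted curve
#' @param x A `roc_curve`.
#' @param ... Unused.
#' @export
tidy.roc_curve <- function(x, ...) x$roc

#' @export
glance.roc_curve <- function(x, ...) tibble::tibble(auc = x$auc)
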