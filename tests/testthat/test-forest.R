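sep_cohort <- function(seed = 31, effect = 40, noise_sd = 0.1) {
  generate_cohort(synthetic_config(n_genes = 200, de_genes = 10,
                                   n_samples_per_class = 20, effect = effect,
                                   noise_sd = noise_sd, dropout_p = 0.05,
                                   seed = seed))
}

test_that("a one-tree forest without bootstrap equals a plain CART fit", {
  rpm <- random_percentiles(15, 30, seed = 41)
  y <- rep(c("normoxic", "hypoxic"), 15)
  f <- fit_forest(rpm, y, forest_params(n_trees = 1, features_per_split = 15,
                                        bootstrap = FALSE, seed = 1))
  solo <- fit_tree(rpm, y, tree_params(min_samples_split = 2, min_leaf = 1,
                                       max_depth = 12, complexity = 0))
  expect_equal(f$trees[[1]], tidy(solo))
})

test_that("forests are reproducible given the seed", {
  rpm <- random_percentiles(20, 24, seed = 42)
  y <- rep(c("normoxic", "hypoxic"), 12)
  p <- forest_params(n_trees = 10, features_per_split = 5, seed = 77)
  expect_identical(fit_forest(rpm, y, p), fit_forest(rpm, y, p))
})

test_that("OOB accuracy is high on a well-separated cohort", {
  ds <- sep_cohort()
  rpm <- suppressWarnings(rank_percentile(ds$matrix))
  f <- fit_forest(rpm, ds$labels,
                  forest_params(n_trees = 100, features_per_split = 10,
                                seed = 5))
  expect_gte(forest_oob_accuracy(f, rpm, ds$labels), 0.95)
})

test_that("invalid forest configurations are rejected", {
  rpm <- random_percentiles(5, 10, seed = 2)
  y <- rep(c("normoxic", "hypoxic"), 5)
  expect_error(fit_forest(rpm, y, forest_params(features_per_split = 6)),
               "features_per_split")
  expect_error(fit_forest(rpm, rep("hypoxic", 10)), "both classes")
  expect_error(permutation_importance(rpm, y, n_iterations = 0),
               "n_iterations")
})

test_that("a constant gene has exactly zero importance", {
  set.seed(8)
  rpm <- random_percentiles(6, 30, seed = 8)
  rpm["g004", ] <- 50
  y <- ifelse(rpm["g001", ] > 50, "hypoxic", "normoxic")
  if (length(unique(y)) < 2) y[1:2] <- c("hypoxic", "normoxic")
  imp <- permutation_importance(rpm, y,
                                forest_params(n_trees = 20,
                                              features_per_split = 3,
                                              seed = 3),
                                n_iterations = 10)
  expect_identical(imp$mean_mda[imp$gene == "g004"], 0)
})

test_that("a lone informative gene dominates; duplication splits importance", {
  set.seed(19)
  n <- 50
  inform <- sample(seq(0, 100, 2), n, replace = TRUE)
  y <- ifelse(inform > 50, "hypoxic", "normoxic")
  noise <- matrix(runif(4 * n, 0, 100), nrow = 4)
  lone <- rbind(A = inform, noise)
  rownames(lone) <- c("A", paste0("n", 1:4))
  colnames(lone) <- paste0("s", 1:n)
  dup <- rbind(lone, A2 = inform)
  rownames(dup) <- c(rownames(lone), "A2")

  p <- forest_params(n_trees = 30, features_per_split = 2, seed = 10)
  imp_lone <- permutation_importance(lone, y, p, n_iterations = 30)
  imp_dup <- permutation_importance(dup, y, p, n_iterations = 30)

  mda <- function(imp, g) imp$mean_mda[imp$gene == g]
  expect_gt(mda(imp_lone, "A"), 10)
  expect_lt(max(imp_lone$mean_mda[imp_lone$gene != "A"]), mda(imp_lone, "A"))
  # permutation importance is shared between duplicated copies
  expect_lt(mda(imp_dup, "A"), mda(imp_lone, "A"))
  expect_lt(mda(imp_dup, "A2"), mda(imp_lone, "A"))
})

test_that("feature selection applies a strict threshold in MDA order", {
  imp <- tibble::tibble(gene = c("A", "B", "C"),
                        mean_mda = c(6.1, 4.0, 3.9),
                        sd_mda = 0, n_iter = 10)
  expect_identical(select_features(imp, 4), "A")
  expect_identical(select_features(imp, -1), c("A", "B", "C"))
  expect_warning(out <- select_features(imp, 100), "no gene")
  expect_length(out, 0)
  # output is always a subset of the input genes
  expect_true(all(select_features(imp, -Inf) %in% imp$gene))
})

test_that("importance agrees in ranking with randomForest on the same data", {
  skip_if_not_installed("randomForest")
  ds <- sep_cohort(seed = 52)
  rpm <- suppressWarnings(rank_percentile(ds$matrix))
  sub <- rpm[c(ds$truth, sample(setdiff(rownames(rpm), ds$truth), 20)), ]
  imp <- permutation_importance(sub, ds$labels,
                                forest_params(n_trees = 100,
                                              features_per_split = 5,
                                              seed = 4),
                                n_iterations = 10)
  rf <- randomForest::randomForest(
    x = as.data.frame(t(sub)), y = factor(ds$labels$label),
    ntree = 300, mtry = 5, importance = TRUE
  )
  rf_mda <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  top_ours <- utils::head(imp$gene, 10)
  top_rf <- names(sort(rf_mda, decreasing = TRUE))[1:10]
  expect_gte(length(intersect(top_ours, top_rf)), 7)
})

test_that("hyperparameter tuning returns the grid argmax, smaller on ties", {
  ds <- generate_cohort(synthetic_config(n_genes = 60, de_genes = 6,
                                         n_samples_per_class = 10,
                                         effect = 80, noise_sd = 0,
                                         dropout_p = 0, seed = 15))
  rpm <- rank_percentile(ds$matrix)
  one <- tibble::tibble(features_per_split = 5, n_trees = 10)
  res1 <- tune_hyperparameters(rpm, ds$labels, one, n_cv = 3, seed = 2)
  expect_equal(res1$params$features_per_split, 5)
  expect_equal(res1$params$n_trees, 10)
  expect_equal(nrow(res1$accuracy), 1)

  grid <- tibble::tibble(features_per_split = c(2, 60), n_trees = c(10, 10))
  res <- tune_hyperparameters(rpm, ds$labels, grid, n_cv = 5, seed = 3)
  expect_equal(nrow(res$accuracy), 2)
  # fully separable: both reach accuracy 1.0, the tie goes to the smaller model
  if (diff(range(res$accuracy$mean_accuracy)) < 1e-12) {
    expect_equal(res$params$features_per_split, 2)
  }
  expect_error(
    tune_hyperparameters(rpm, ds$labels,
                         tibble::tibble(features_per_split = 1000,
                                        n_trees = 10)),
    "invalid"
  )
})
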