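test_that("population generation scores every candidate on its own holdout", {
  ds <- generate_cohort(synthetic_config(n_genes = 100, de_genes = 8,
                                         n_samples_per_class = 15,
                                         effect = 60, noise_sd = 0.05,
                                         dropout_p = 0, seed = 9))
  rpm <- rank_percentile(ds$matrix)
  pop <- generate_tree_population(rpm, ds$labels, ds$truth,
                                  n_candidates = 30, train_frac = 0.7,
                                  params = tree_params(min_samples_split = 4,
                                                       min_leaf = 2),
                                  seed = 4)
  expect_length(pop, 30)
  tab <- tidy(pop)
  # near-separable cohort: every candidate should classify its holdout well
  expect_true(all(tab$holdout_accuracy == 1))
  expect_identical(tab$tree_id, as.character(1:30))

  empty <- generate_tree_population(rpm, ds$labels, ds$truth,
                                    n_candidates = 0, seed = 1)
  expect_length(empty, 0)
  expect_error(generate_tree_population(rpm, ds$labels, c("nope"), 5),
               "absent")
})

test_that("accuracy filtering is strict and preserves metadata", {
  pop <- as_population(
    stump_tree("A", 50, id = "1", accuracy = 0.96, f1 = 0.95),
    stump_tree("B", 50, id = "2", accuracy = 0.95, f1 = 0.99),
    stump_tree("C", 50, id = "3", accuracy = 0.80, f1 = 0.70)
  )
  ens <- filter_by_accuracy(pop, 0.95)
  expect_equal(length(ens), 1)
  expect_equal(ens$trees[[1]]$tree_id, "1")
  expect_equal(length(filter_by_accuracy(pop, 0)), 3)
  expect_warning(empty <- filter_by_accuracy(pop, 0.99), "empty")
  expect_equal(length(empty), 0)
})

test_that("deduplication drops structurally identical trees", {
  pop <- as_population(
    stump_tree("A", 50, id = "1", accuracy = 0.99),
    stump_tree("A", 50, id = "2", accuracy = 0.98),
    stump_tree("A", 60, id = "3", accuracy = 0.97)
  )
  ens <- filter_by_accuracy(pop, 0.9, deduplicate = TRUE)
  expect_equal(length(ens), 2)
})

test_that("top-k-by-F1 selection reproduces a hand-computed ordering", {
  # validation fixtures: 4 samples each, percentiles chosen so per-tree
  # predictions and hence F1 are computable by hand
  rpm1 <- matrix(c(10, 90, 60, 20, 80, 30, 40, 70), nrow = 2,
                 dimnames = list(c("A", "B"), paste0("v", 1:4)))
  lab1 <- c("normoxic", "hypoxic", "hypoxic", "normoxic")
  rpm2 <- matrix(c(90, 90, 10, 10, 20, 60, 70, 30), nrow = 2,
                 dimnames = list(c("A", "B"), paste0("w", 1:4)))
  lab2 <- c("hypoxic", "normoxic", "hypoxic", "normoxic")
  sets <- list(val_set(rpm1, lab1), val_set(rpm2, lab2))

  t_a <- stump_tree("A", 50, id = "a", accuracy = 0.9)   # predicts A>=50
  t_b <- stump_tree("B", 50, id = "b", accuracy = 0.9)   # predicts B>=50
  t_c <- leaf_tree(1, id = "c")                          # always hypoxic
  t_c$metadata$holdout_accuracy <- 0.9

  # hand-computed F1 (hypoxic positive):
  # set1 truth H = {v2, v3}; tree a calls {v2, v3} -> F1 1.0;
  #   tree b calls {v1, v4} -> tp 0, F1 0; tree c calls all -> F1 2*2/(4+2)=2/3
  # set2 truth H = {w1, w3}; tree a calls {w1, w2} -> tp 1 F1 1/2;
  #   tree b calls {w2, w3} -> tp 1 F1 1/2; tree c -> F1 2/3
  ens <- as_ensemble(t_a, t_b, t_c)
  top2 <- select_top_k_by_f1(ens, 2, sets)
  ids <- vapply(top2$trees, function(t) t$tree_id, character(1))
  expect_identical(ids, c("a", "c"))   # means: a 0.75, c 2/3, b 0.25
  f1s <- vapply(top2$trees, function(t) t$metadata$mean_f1, numeric(1))
  expect_equal(f1s, c(0.75, 2 / 3), tolerance = 1e-12)

  # k = ensemble size is the identity up to ordering
  expect_setequal(vapply(select_top_k_by_f1(ens, 3, sets)$trees,
                         function(t) t$tree_id, character(1)),
                  c("a", "b", "c"))
})

test_that("a validation set missing a gene is skipped with a warning", {
  rpm <- matrix(c(10, 90), nrow = 1, dimnames = list("A", c("v1", "v2")))
  sets <- list(val_set(rpm, c("normoxic", "hypoxic")))
  ens <- as_ensemble(stump_tree("A", 50, id = "a"),
                     stump_tree("Z", 50, id = "z"))
  expect_warning(top <- select_top_k_by_f1(ens, 2, sets), "lacks gene")
  tab <- tidy(top)
  expect_true(is.nan(tab$mean_f1[tab$tree_id == "z"]))
})

test_that("feature-availability filtering keeps exactly the compatible trees", {
  ens <- as_ensemble(stump_tree("A", 50, id = "1"),
                     stump_tree("MIR210HG", 70, id = "2"))
  kept <- filter_by_available_features(ens, c("A", "B", "C"))
  expect_equal(length(kept), 1)
  expect_equal(kept$trees[[1]]$tree_id, "1")
  # all genes available: identity
  all_kept <- filter_by_available_features(ens, c("A", "MIR210HG"))
  expect_equal(length(all_kept), 2)
  err <- expect_error(filter_by_available_features(ens, "Q"), "unblock")
  expect_match(conditionMessage(err), "A|MIR210HG")
})

test_that("consensus prediction averages probabilities with a strict cut", {
  rpm <- random_percentiles(4, 3, seed = 6)
  ens <- as_ensemble(leaf_tree(0.9), leaf_tree(0.8), leaf_tree(0.1))
  res <- ensemble_predict(ens, rpm)
  expect_equal(res$samples$mean_prob, rep(0.6, 3))
  expect_true(all(res$samples$label == "hypoxic"))
  expect_true(all(res$samples$n_trees_used == 3))

  # mean exactly at the threshold is NOT hypoxic ("over", strictly)
  res50 <- ensemble_predict(as_ensemble(leaf_tree(0.4), leaf_tree(0.6)), rpm)
  expect_true(all(res50$samples$mean_prob == 0.5))
  expect_true(all(res50$samples$label == "normoxic"))

  res07 <- ensemble_predict(ens, rpm, threshold = 0.7)
  expect_true(all(res07$samples$label == "normoxic"))
  expect_error(ensemble_predict(as_ensemble(), rpm), "empty")
})

test_that("consensus probability is bounded by the per-tree extremes", {
  rpm <- random_percentiles(30, 10, seed = 23)
  y <- rep(c("normoxic", "hypoxic"), 5)
  pop <- generate_tree_population(rpm, y, rownames(rpm), n_candidates = 8,
                                  params = tree_params(min_samples_split = 2,
                                                       min_leaf = 1),
                                  seed = 2)
  ens <- filter_by_accuracy(pop, 0)
  res <- ensemble_predict(ens, rpm)
  expect_true(all(res$samples$mean_prob >= apply(res$tree_probs, 2, min) - 1e-12))
  expect_true(all(res$samples$mean_prob <= apply(res$tree_probs, 2, max) + 1e-12))
  # an ensemble of identical trees equals the single tree
  t1 <- ens$trees[[1]]
  solo <- ensemble_predict(as_ensemble(t1, t1, t1), rpm)
  expect_equal(solo$samples$mean_prob, unname(predict_tree(t1, rpm)))
})

test_that("hypoxic-call counts are non-increasing in the threshold", {
  rpm <- random_percentiles(30, 20, seed = 29)
  y <- rep(c("normoxic", "hypoxic"), 10)
  pop <- generate_tree_population(rpm, y, rownames(rpm), n_candidates = 10,
                                  params = tree_params(min_samples_split = 2,
                                                       min_leaf = 1),
                                  seed = 5)
  ens <- filter_by_accuracy(pop, 0)
  calls <- vapply(seq(0, 1, by = 0.05), function(th) {
    sum(ensemble_predict(ens, rpm, threshold = th)$samples$label == "hypoxic")
  }, numeric(1))
  expect_true(all(diff(calls) <= 0))
})

test_that("evaluation reproduces closed-form confusion metrics", {
  truth <- c(rep("hypoxic", 4), rep("normoxic", 6))
  pred <- tibble::tibble(
    sample_id = paste0("s", 1:10),
    label = c("hypoxic", "hypoxic", "hypoxic", "normoxic",
              "hypoxic", rep("normoxic", 5))
  )
  rep_ <- evaluate(truth, pred)
  expect_equal(rep_$tp, 3); expect_equal(rep_$fp, 1)
  expect_equal(rep_$fn, 1); expect_equal(rep_$tn, 5)
  expect_equal(rep_$accuracy, 0.8)
  expect_equal(rep_$precision, 0.75)
  expect_equal(rep_$recall, 0.75)
  expect_equal(rep_$f1, 0.75)

  perfect <- evaluate(truth, tibble::tibble(sample_id = paste0("s", 1:10),
                                            label = truth))
  expect_true(all(unlist(perfect[c("accuracy", "precision", "recall", "f1")]) == 1))

  all_n <- evaluate(rep(c("hypoxic", "normoxic"), 5),
                    tibble::tibble(sample_id = paste0("s", 1:10),
                                   label = rep("normoxic", 10)))
  expect_equal(all_n$accuracy, 0.5)
  expect_equal(all_n$f1, 0)
  expect_false(all_n$precision_defined)

  expect_error(evaluate(rep("oxygenated", 10), pred), "unknown label")
})

test_that("trapezoid AUC equals the pair-counting oracle, ties at half", {
  lab <- c("hypoxic", "hypoxic", "normoxic", "normoxic")
  expect_equal(roc_auc(lab, c(0.9, 0.8, 0.4, 0.2))$auc, 1)
  expect_equal(roc_auc(lab, c(0.1, 0.2, 0.8, 0.9))$auc, 0)
  expect_error(roc_auc(rep("hypoxic", 4), c(1, 2, 3, 4)), "both classes")

  for (s in 1:25) {
    set.seed(s)
    y <- sample(0:1, 40, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    scores <- sample(seq(0, 1, by = 0.1), 40, replace = TRUE)  # many ties
    r <- roc_auc(ifelse(y == 1, "hypoxic", "normoxic"), scores)
    expect_equal(r$auc, oracle_auc(y, scores), tolerance = 1e-12)
    expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[1], 0)
    expect_equal(r$roc$fpr[nrow(r$roc)], 1)
    expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  }
})

test_that("roc curves agree with pROC as an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  y <- rep(c(0, 1), 25)
  scores <- y * 0.3 + runif(50)
  ours <- roc_auc(ifelse(y == 1, "hypoxic", "normoxic"), scores)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(y, scores)))
  expect_equal(ours, ref, tolerance = 1e-12)
})
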