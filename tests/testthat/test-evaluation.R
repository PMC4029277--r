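toy_pairs <- function(n, n_pos = n %/% 2) {
  tibble::tibble(compound_id = sprintf("c%d", seq_len(n)),
                 protein_id = "p1",
                 label = c(rep(1L, n_pos), rep(-1L, n - n_pos)))
}

test_that("pairwise folds partition the pairs with near-equal, reproducible sizes", {
  sp <- pairwise_cv_split(toy_pairs(10), 5, seed = 3)
  expect_equal(sort(unique(sp$fold)), 1:5)
  expect_equal(as.numeric(table(sp$fold)), rep(2, 5))
  sp2 <- pairwise_cv_split(toy_pairs(10), 5, seed = 3)
  expect_identical(sp$fold, sp2$fold)
  sp3 <- pairwise_cv_split(toy_pairs(10), 5, seed = 4)
  expect_false(identical(sp$fold, sp3$fold))

  # remainder goes to the lowest-indexed folds
  sp4 <- pairwise_cv_split(toy_pairs(12), 5, seed = 1)
  expect_equal(as.numeric(table(sp4$fold)), c(3, 3, 2, 2, 2))

  # stratified: 50/50 labels -> 10 of each per fold
  st <- pairwise_cv_split(toy_pairs(100, 50), 5, seed = 9, stratified = TRUE)
  counts <- table(st$fold, st$label)
  expect_true(all(counts == 10))

  expect_error(pairwise_cv_split(toy_pairs(3), 5),
               class = "cpisketch_validation_error")
})

test_that("blockwise folds keep test entities out of training", {
  cids <- sprintf("c%d", 1:25); pids <- sprintf("p%d", 1:25)
  bw <- blockwise_cv_split(cids, pids, 5, seed = 2)
  expect_equal(as.numeric(table(bw$compound_folds$fold)), rep(5, 5))
  expect_equal(as.numeric(table(bw$protein_folds$fold)), rep(5, 5))

  pairs <- tidyr::expand_grid(compound_id = cids, protein_id = pids)
  seen_test_compounds <- character(0)
  for (i in 1:5) {
    ix <- cpisketch:::fold_indices(bw, pairs, i)
    test <- pairs[ix$test, ]; train <- pairs[ix$train, ]
    expect_length(intersect(test$compound_id, train$compound_id), 0)
    expect_length(intersect(test$protein_id, train$protein_id), 0)
    seen_test_compounds <- c(seen_test_compounds, unique(test$compound_id))
  }
  # the 5-fold sweep covers every compound exactly once as a test entity
  expect_identical(sort(seen_test_compounds), sort(cids))
})

test_that("negative sampling draws uniformly from the complement", {
  cids <- sprintf("c%d", 1:10); pids <- sprintf("p%d", 1:10)
  pos <- tibble::tibble(compound_id = sprintf("c%d", 1:5),
                        protein_id = sprintf("p%d", 1:5))
  neg <- sample_negatives(pos, cids, pids, ratio = 4, seed = 1)
  expect_equal(nrow(neg), 20)
  expect_true(all(neg$label == -1L))
  expect_false(any(paste(neg$compound_id, neg$protein_id) %in%
                   paste(pos$compound_id, pos$protein_id)))
  expect_identical(neg, sample_negatives(pos, cids, pids, ratio = 4, seed = 1))

  # ratio = Inf returns the whole complement
  small_pos <- tibble::tibble(compound_id = c("c1", "c2"),
                              protein_id = c("p1", "p2"))
  all_neg <- sample_negatives(small_pos, sprintf("c%d", 1:3),
                              sprintf("p%d", 1:3), ratio = Inf)
  expect_equal(nrow(all_neg), 7)

  err <- expect_error(sample_negatives(pos, cids, pids, ratio = 100),
                      class = "cpisketch_validation_error")
  expect_match(conditionMessage(err), "at most")

  # uniformity across seeds (chi-square over complement cells)
  counts <- table(unlist(lapply(1:400, function(s) {
    n <- sample_negatives(small_pos, sprintf("c%d", 1:3), sprintf("p%d", 1:3),
                          ratio = 1, seed = s)
    paste(n$compound_id, n$protein_id)
  })))
  expect_equal(length(counts), 7)
  expect_gt(stats::chisq.test(as.numeric(counts))$p.value, 1e-3)
})

test_that("AUC follows the Mann-Whitney midrank convention and the ROC area", {
  expect_equal(auc_score(c(0.9, 0.8, 0.2, 0.1), c(1, 1, -1, -1)), 1)
  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9), c(1, 1, -1, -1)), 0)
  expect_equal(auc_score(rep(0.5, 6), c(1, 1, 1, -1, -1, -1)), 0.5)
  expect_error(auc_score(1:3, c(1, 1, 1)),
               class = "cpisketch_undefined_auc_error")

  set.seed(8)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    scores <- round(rnorm(n), 1)  # rounding forces ties
    labels <- sample(c(-1, 1), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    expect_equal(auc_score(scores, labels),
                 oracle_auc_trapezoid(scores, labels), tolerance = 1e-10)
  }
})

test_that("cross-validation recovers planted signal and collapses on permuted labels", {
  sim <- generate_synthetic_dataset(strong_config(11))
  res <- run_cv_experiment(sim$dataset, scheme = "pairwise", mode = "compact",
                           regularization = "L2", C = 10^(-3:1), ell = 70,
                           seed = 2, skip_empty = TRUE)
  expect_gt(res$mean_auc, 0.9)
  # fold table covers all folds for every C; test sizes partition the pairs
  folds <- tidy(res)
  expect_equal(sort(unique(folds$fold)), 1:5)
  one_c <- folds[folds$C == res$best_C, ]
  expect_equal(sum(one_c$n_test), nrow(sim$dataset$pairs))

  g <- glance(res)
  expect_equal(g$best_C, res$best_C)

  # label permutation destroys the signal: mean AUC near 1/2
  perm <- sim$dataset
  set.seed(5)
  perm$pairs$label <- sample(perm$pairs$label)
  null_res <- run_cv_experiment(perm, scheme = "pairwise", mode = "direct",
                                regularization = "L2", C = 1, seed = 2,
                                skip_empty = TRUE)
  expect_lt(abs(null_res$mean_auc - 0.5), 0.05)
})

test_that("blockwise experiments never leak test entities and plot cleanly", {
  sim <- generate_synthetic_dataset(strong_config(12))
  res <- run_cv_experiment(sim$dataset, scheme = "blockwise", mode = "compact",
                           regularization = "L2", C = 0.1, ell = 30,
                           seed = 3, skip_empty = TRUE)
  expect_true(all(res$folds$auc >= 0 & res$folds$auc <= 1))
  expect_lt(sum(res$folds$n_test), nrow(sim$dataset$pairs))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  p2 <- plot_collision_law()
  expect_s3_class(p2, "ggplot")
})
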