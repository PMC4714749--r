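test_that("AUC follows the Mann-Whitney pair count", {
  expect_equal(term_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(term_auc(c(3, 2, 1, 0), c(1, 1, 0, 0)), 1)
  expect_equal(term_auc(c(3, 2, 1, 0), c(0, 0, 1, 1)), 0)
  # ties count one half; monotone transform invariance
  expect_equal(term_auc(c(1, 1), c(1, 0)), 0.5)
  s <- c(0.9, 0.4, 0.6, 0.1); l <- c(1, 1, 0, 0)
  expect_equal(term_auc(exp(5 * s), l), term_auc(s, l))
  expect_error(term_auc(1:3, c(1, 1, 1)), "one class")
})

test_that("hierarchical metrics follow the ancestor-overlap definitions", {
  d <- chain_dag(3)                       # A root, B, C
  truth <- rbind(s1 = c(A = 1, B = 1, C = 1))
  pred <- rbind(s1 = c(A = 1, B = 1, C = 0))
  h <- hierarchical_prf(d, pred, truth)   # P={B}, T={B,C}, root excluded
  expect_equal(h$HP, 1)
  expect_equal(h$HR, 0.5)
  expect_equal(h$HF, 2 / 3)

  h2 <- hierarchical_prf(d, truth, truth)
  expect_equal(c(h2$HP, h2$HR, h2$HF), c(1, 1, 1))

  # disjoint non-empty sets on a two-branch dag
  d2 <- go_dag(c("R", "X", "Y"),
               data.frame(child = c("X", "Y"), parent = "R"))
  h3 <- hierarchical_prf(d2, rbind(s1 = c(R = 1, X = 1, Y = 0)),
                         rbind(s1 = c(R = 1, X = 0, Y = 1)))
  expect_equal(c(h3$HP, h3$HR, h3$HF), c(0, 0, 0))

  # empty prediction conventions
  h4 <- hierarchical_prf(d, rbind(s1 = c(A = 0, B = 0, C = 0)),
                         rbind(s1 = c(A = 0, B = 0, C = 0)))
  expect_equal(c(h4$HP, h4$HR), c(1, 1))
  # non-closed input is refused
  expect_error(hierarchical_prf(d, rbind(s1 = c(A = 0, B = 0, C = 1)), truth),
               "repair")
})

test_that("rank-sum comparison uses the exact distribution when it can", {
  a <- c(1.1, 1.2, 1.3, 1.4, 1.5)
  b <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  r <- ranksum_compare(a, b, alpha = 0.01, names = c("m1", "m2"))
  expect_equal(r$p_value, 2 / choose(10, 5), tolerance = 1e-12)
  expect_equal(r$winner, "m1")
  r2 <- ranksum_compare(b, a, alpha = 0.01, names = c("m1", "m2"))
  expect_equal(r2$p_value, r$p_value)
  expect_equal(r2$winner, "m2")

  same <- c(0.5, 0.6, 0.7)
  r3 <- ranksum_compare(same, same)
  expect_equal(r3$winner, "tie")
  expect_gt(r3$p_value, 0.9)
  expect_error(ranksum_compare(numeric(0), a), "non-empty")
})

test_that("folds partition genes and stratify positives", {
  d <- random_godag(8, n_levels = 3, seed = 12)
  ann <- sample_annotations(d, 0.6, 100, seed = 13)
  f <- make_folds(ann, 5, seed = 9)
  expect_setequal(names(f), rownames(ann))
  expect_false(anyNA(f))
  expect_identical(f, make_folds(ann, 5, seed = 9))
  expect_false(identical(f, make_folds(ann, 5, seed = 10)))
  # per-term positive counts balanced within +-1 for the rarest term handled
  # first (later terms are constrained by earlier assignments)
  counts <- colSums(ann)
  rarest <- names(which.min(counts[counts > 0]))
  per_fold <- table(f[ann[, rarest] == 1])
  if (length(per_fold) > 1) {
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_error(make_folds(ann, 1), "k must be")
})

test_that("cross-validation compares flat, TPR-DAG and factor-graph routes", {
  d <- random_godag(6, n_levels = 3, max_parents = 2, seed = 21)
  ann <- sample_annotations(d, 0.75, 80, seed = 22)
  set.seed(23)
  feats <- ann + matrix(rnorm(length(ann), 0, 0.4), nrow(ann))
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  rownames(feats) <- rownames(ann)
  cv <- suppressWarnings(
    cross_validate(ann, feats, d, k = 3, seed = 24))
  expect_setequal(unique(cv$metrics$method), c("flat", "tpr_dag", "fgga"))
  expect_equal(nrow(cv$metrics), 9)
  expect_true(all(cv$metrics$HF >= 0 & cv$metrics$HF <= 1))
  expect_setequal(names(cv$folds), rownames(ann))
  expect_true(is.null(cv$auc) || all(cv$auc$fgga >= 0 & cv$auc$fgga <= 1))
})

test_that("leaf pruning removes weak leaves iteratively", {
  d <- chain_dag(3)
  marg <- c(A = 0.99, B = 0.90, C = 0.99)
  pr <- prune_predicted_graph(d, marg, leaf_cut = 0.95)
  # C passes but sits under B; C is the only leaf and survives, so B stays
  expect_setequal(pr$kept, c("A", "B", "C"))

  marg2 <- c(A = 0.99, B = 0.99, C = 0.90)
  pr2 <- prune_predicted_graph(d, marg2, leaf_cut = 0.95)
  # C is cut; B becomes a leaf and passes
  expect_setequal(pr2$kept, c("A", "B"))
  expect_equal(pr2$leaves$term, "B")

  marg3 <- c(A = 0.99, B = 0.94, C = 0.90)
  pr3 <- prune_predicted_graph(d, marg3, leaf_cut = 0.95)
  # cascade: C cut, then the exposed B cut too
  expect_setequal(pr3$kept, "A")

  pr4 <- prune_predicted_graph(d, c(A = 1, B = 1, C = 1))
  expect_setequal(pr4$kept, c("A", "B", "C"))

  # output stays closed and within the positive set on random fixtures
  for (i in 1:10) {
    d2 <- random_godag(10, n_levels = 4, seed = i)
    set.seed(i)
    marg <- stats::setNames(runif(10), term_ids(d2))
    pr5 <- prune_predicted_graph(d2, marg, leaf_cut = 0.6)
    lab <- stats::setNames(as.integer(term_ids(d2) %in% pr5$kept),
                           term_ids(d2))
    expect_equal(nrow(check_consistency(d2, lab)), 0)
    expect_true(all(marg[pr5$kept] > 0.5 | pr5$kept == d2$root))
  }
})
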