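# Per-term AUC, hierarchical precision/recall/F, cross-validation, rank-sum
# method comparison, and leaf-confidence pruning of predicted graphs.

#' Area under the ROC curve for one term
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' outscores a randomly chosen negative, ties counted one half. Invariant
#' under strictly monotone transformations of the scores.
#'
#' @param scores Real-valued scores, one per gene.
#' @param labels Binary labels, same length; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
term_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("AUC undefined: one class is empty")
  r <- rank(scores)            # average ranks handle ties as 0.5
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Hierarchical precision, recall and F-score
#'
#' Ancestor-based hierarchical metrics over closed label sets: per sample,
#' with predicted set P and true set T (both ancestor-closed, root excluded),
#' HP = |P n T| / |P| and HR = |P n T| / |T|, with the conventions HP = 1 when
#' both sets are empty, 0 when only P is empty (and symmetrically for HR);
#' HF is the per-sample harmonic mean. All three are macro-averaged over
#' samples.
#'
#' @param dag A [go_dag()].
#' @param predicted Samples-by-terms binary matrix, ancestor-closed (repair
#'   with [repair_labels()] first if needed).
#' @param truth Samples-by-terms binary matrix, ancestor-closed.
#' @return List with scalars `HP`, `HR`, `HF` and a per-sample data frame
#'   `per_sample`.
#' @export
hierarchical_prf <- function(dag, predicted, truth) {
  ids <- setdiff(term_ids(dag), dag$root)
  for (nm in c("predicted", "truth")) {
    m <- get(nm)
    bad <- apply(m, 1, function(l) nrow(check_consistency(dag, l[term_ids(dag)])) > 0)
    if (any(bad)) {
      stop(nm, " labels are not ancestor-closed for sample(s) ",
           paste(utils::head(rownames(m)[bad], 3), collapse = ", "),
           "; apply repair_labels() first")
    }
  }
  P <- predicted[, ids, drop = FALSE]
  T_ <- truth[, ids, drop = FALSE]
  inter <- rowSums(P == 1 & T_ == 1)
  np <- rowSums(P); nt <- rowSums(T_)
  hp <- ifelse(np > 0, inter / np, ifelse(nt == 0, 1, 0))
  hr <- ifelse(nt > 0, inter / nt, ifelse(np == 0, 1, 0))
  hf <- ifelse(hp + hr > 0, 2 * hp * hr / (hp + hr), 0)
  list(HP = mean(hp), HR = mean(hr), HF = mean(hf),
       per_sample = data.frame(sample = rownames(predicted),
                               HP = hp, HR = hr, HF = hf))
}

#' Compare two per-term metric samples with the Wilcoxon rank-sum test
#'
#' Two-sided test; the exact null distribution is used for combined sample
#' sizes up to 20 without ties, the normal approximation with tie correction
#' otherwise. A winner is declared only when `p < alpha`.
#'
#' @param metric_a,metric_b Per-term metric values for the two methods.
#' @param alpha Significance level (default 0.01).
#' @param names Length-2 labels used for the winner (default `c("a", "b")`).
#' @return List with `statistic`, `p_value` and `winner` (`names[1]`,
#'   `names[2]`, or `"tie"`).
#' @export
ranksum_compare <- function(metric_a, metric_b, alpha = 0.01,
                            names = c("a", "b")) {
  if (length(metric_a) == 0 || length(metric_b) == 0) {
    stop("both metric samples must be non-empty")
  }
  n <- length(metric_a) + length(metric_b)
  ties <- anyDuplicated(c(metric_a, metric_b)) > 0
  wt <- suppressWarnings(
    stats::wilcox.test(metric_a, metric_b, exact = (n <= 20 && !ties),
                       correct = FALSE))
  winner <- if (wt$p.value < alpha) {
    if (stats::median(metric_a) >= stats::median(metric_b)) names[1] else names[2]
  } else "tie"
  list(statistic = unname(wt$statistic), p_value = wt$p.value, winner = winner)
}

#' Stratified fold assignment for cross-validation
#'
#' Iterative balancing: terms are visited in order of increasing positive
#' count (rarest first) and each term's still-unassigned positive genes are
#' dealt round-robin across folds, so rare deep terms stay represented in
#' every training split whenever possible; remaining genes are dealt evenly.
#'
#' @param matrix Closed binary annotation matrix.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed controlling the dealing order.
#' @return Named integer vector: fold id (1..k) per gene.
#' @export
make_folds <- function(matrix, k, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  genes <- rownames(matrix)
  fold <- stats::setNames(rep(NA_integer_, length(genes)), genes)
  .with_seed(seed, {
    counts <- sort(colSums(matrix))
    next_fold <- 0L
    for (t in names(counts)) {
      g <- genes[matrix[, t] == 1 & is.na(fold)]
      if (length(g) == 0) next
      g <- sample(g)
      fold[g] <- (next_fold + seq_along(g) - 1L) %% k + 1L
      next_fold <- (next_fold + length(g)) %% k
    }
    g <- genes[is.na(fold)]
    if (length(g) > 0) {
      g <- sample(g)
      fold[g] <- (next_fold + seq_along(g) - 1L) %% k + 1L
    }
  })
  fold
}

#' Cross-validated comparison of flat, TPR-DAG and factor-graph annotation
#'
#' For each fold: per-term scorers are trained on the remaining genes, margins
#' are produced for the held-out genes, channel variances are estimated from
#' the training positives' margins, Platt calibration is fitted on the
#' training margins. Held-out genes are then annotated three ways — flat
#' (calibrated probabilities thresholded at 0.5, repaired to consistency),
#' TPR-DAG on the calibrated probabilities, and factor-graph inference on the
#' raw margins — and scored with hierarchical metrics and per-term AUC.
#' Terms with no positives or no negatives in a training split are excluded
#' from that fold's scorer training with a warning.
#'
#' @param matrix Closed binary annotation matrix (truth).
#' @param features Genes-by-features numeric matrix (same genes).
#' @param dag A [go_dag()] over the matrix terms.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for folds and subsampling.
#' @param scorer Pluggable scorer (default [svm_margin_scorer()]).
#' @param max_neg_ratio Negative subsampling ratio for training sets.
#' @param xi,i_max,damping Sum-product controls, see [sum_product()].
#' @return List with `folds`, per-fold `scores`, a `metrics` data frame
#'   (method by fold HP/HR/HF), per-term AUC data frame `auc`, and the
#'   rank-sum verdict `fgga_vs_tpr` on per-term AUC.
#' @export
cross_validate <- function(matrix, features, dag, k = 5, seed = 1L,
                           scorer = svm_margin_scorer(), max_neg_ratio = 2,
                           xi = 1e-3, i_max = 50, damping = 0) {
  ids <- term_ids(dag)
  matrix <- matrix[, ids, drop = FALSE]
  fold <- make_folds(matrix, k, seed)
  metrics <- NULL; auc_rows <- NULL; fold_scores <- list()

  for (f in seq_len(k)) {
    test_g <- names(fold)[fold == f]
    train_g <- names(fold)[fold != f]
    train_m <- matrix[train_g, , drop = FALSE]

    usable <- ids[colSums(train_m) > 0 &
                    colSums(train_m) < nrow(train_m) & ids != dag$root]
    dropped <- setdiff(setdiff(ids, dag$root), usable)
    if (length(dropped) > 0) {
      warning("fold ", f, ": term(s) without both classes in training, ",
              "excluded: ", paste(dropped, collapse = ", "))
    }
    datasets <- lapply(usable, function(t)
      build_binary_dataset(t, train_m, dag, max_neg_ratio, seed + f))
    margins <- score_terms(scorer, datasets, features)

    # channel variances from training positives' margins; calibration on the
    # full training margins
    eta <- stats::setNames(rep(1, length(ids)), ids)
    flat_all <- matrix(0.5, nrow(margins), length(ids),
                       dimnames = list(rownames(margins), ids))
    for (t in usable) {
      pos_tr <- intersect(rownames(train_m)[train_m[, t] == 1],
                          rownames(margins))
      eta[t] <- if (length(pos_tr) >= 2) {
        estimate_variance(margins[pos_tr, t], term = t)
      } else 1
      cal <- fit_sigmoid(margins[train_g, t], train_m[, t])
      flat_all[, t] <- cal$predict(margins[, t])
    }
    # root and dropped terms: uninformative score/probability
    y_test <- matrix(0, length(test_g), length(ids),
                     dimnames = list(test_g, ids))
    y_test[, usable] <- margins[test_g, usable]
    y_test[, dag$root] <- max(abs(y_test)) + 1   # root is always annotated
    flat_test <- flat_all[test_g, , drop = FALSE]
    flat_test[, dag$root] <- 1

    truth <- matrix[test_g, , drop = FALSE]
    flat_lab <- t(apply(1L * (flat_test >= 0.5), 1,
                        function(l) repair_labels(dag, l)))
    tpr <- tpr_dag_predict_matrix(dag, flat_test)
    fgga <- fgga_annotate_matrix(dag, y_test, eta, xi, i_max, damping)

    h_flat <- hierarchical_prf(dag, flat_lab, truth)
    h_tpr <- hierarchical_prf(dag, tpr$labels, truth)
    h_fgga <- hierarchical_prf(dag, fgga$map_repaired, truth)
    metrics <- rbind(metrics, data.frame(
      fold = f, method = c("flat", "tpr_dag", "fgga"),
      HP = c(h_flat$HP, h_tpr$HP, h_fgga$HP),
      HR = c(h_flat$HR, h_tpr$HR, h_fgga$HR),
      HF = c(h_flat$HF, h_tpr$HF, h_fgga$HF)))

    for (t in usable) {
      if (length(unique(truth[, t])) < 2) next
      auc_rows <- rbind(auc_rows, data.frame(
        fold = f, term = t,
        flat = term_auc(y_test[, t], truth[, t]),
        tpr_dag = term_auc(tpr$probs[, t], truth[, t]),
        fgga = term_auc(fgga$marginals[, t], truth[, t])))
    }
    fold_scores[[f]] <- list(margins = y_test, flat = flat_test,
                             eta = eta, fgga = fgga, tpr = tpr)
  }

  auc_term <- NULL; verdict <- NULL
  if (!is.null(auc_rows)) {
    auc_term <- stats::aggregate(cbind(flat, tpr_dag, fgga) ~ term,
                                 data = auc_rows, FUN = mean)
    verdict <- ranksum_compare(auc_term$fgga, auc_term$tpr_dag,
                               names = c("fgga", "tpr_dag"))
  }
  list(folds = fold, scores = fold_scores, metrics = metrics,
       auc = auc_term, fgga_vs_tpr = verdict)
}

#' Prune a predicted annotation graph by leaf confidence
#'
#' Starts from the consistent positive set (marginals thresholded at 0.5 and
#' repaired), then iteratively removes leaf terms of the current kept
#' subgraph whose marginal falls below `leaf_cut`; removing a leaf can expose
#' its parent as a new leaf, which is then tested too. The default cut of
#' 0.95 targets high-confidence annotation of uncharacterised proteins.
#'
#' @param dag A [go_dag()].
#' @param marginals Named per-term posterior probabilities.
#' @param leaf_cut Minimum marginal for a kept leaf (default 0.95).
#' @param top_k How many top-scoring kept leaves to report (default 5).
#' @return List with `kept` (ancestor-closed term set), `leaves` (data frame
#'   of kept-subgraph leaves and marginals, best first), and `top`
#'   (the first `top_k` rows).
#' @export
prune_predicted_graph <- function(dag, marginals, leaf_cut = 0.95, top_k = 5) {
  if (leaf_cut < 0 || leaf_cut > 1) stop("leaf_cut must lie in [0, 1]")
  ids <- term_ids(dag)
  labels <- repair_labels(dag, stats::setNames(
    as.integer(marginals[ids] > 0.5), ids))
  kept <- names(labels)[labels == 1]
  repeat {
    if (length(kept) == 0) break
    is_leaf <- vapply(kept, function(t)
      !any(dag$children[[t]] %in% kept), TRUE)
    drop <- kept[is_leaf & marginals[kept] < leaf_cut]
    drop <- setdiff(drop, dag$root)
    if (length(drop) == 0) break
    kept <- setdiff(kept, drop)
  }
  leaves <- kept[vapply(kept, function(t)
    !any(dag$children[[t]] %in% kept), TRUE)]
  lv <- data.frame(term = leaves, marginal = as.numeric(marginals[leaves]))
  lv <- lv[order(-lv$marginal), , drop = FALSE]
  list(kept = kept, leaves = lv, top = utils::head(lv, top_k))
}
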