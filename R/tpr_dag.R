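# TPR-DAG leveraging heuristic: bottom-up averaging with positive children,
# then top-down weakest-parent correction.

#' Maximum distance of every term from the root
#'
#' Longest-path depths computed by dynamic programming in topological order.
#' For every edge, `depth(child) > depth(parent)`, so processing terms in
#' decreasing depth visits all children of a term before the term itself.
#'
#' @param dag A [go_dag()].
#' @return Named integer vector of depths; the root has depth 0.
#' @export
max_depths <- function(dag) {
  ids <- term_ids(dag)
  depth <- stats::setNames(rep(0L, length(ids)), ids)
  for (t in topo_order(dag)) {
    ps <- dag$parents[[t]]
    if (length(ps) > 0) depth[t] <- max(depth[ps]) + 1L
  }
  depth
}

# decreasing-depth order with identifier tie-break, for bit-reproducible runs
.by_depth <- function(dag, decreasing) {
  depth <- max_depths(dag)
  ids <- term_ids(dag)
  ord <- order(depth[ids], ids, decreasing = c(decreasing, FALSE),
               method = "radix")
  ids[ord]
}

#' Bottom-up consensus of flat predictions
#'
#' Processes terms from the deepest level up to the root; each term's
#' consensus is the mean of its own flat value and the consensus values of
#' those children whose consensus meets the positivity threshold. Children are
#' deeper than their parents, so their consensus is already final when the
#' parent is visited; terms with no positive children (in particular leaves)
#' keep their flat value.
#'
#' @param dag A [go_dag()].
#' @param flat Named vector of flat per-term probabilities in `[0, 1]`.
#' @param threshold Positivity threshold for a child to join the average
#'   (default 0.5).
#' @return Named consensus probability vector.
#' @export
bottom_up_consensus <- function(dag, flat, threshold = 0.5) {
  ids <- term_ids(dag)
  if (!all(ids %in% names(flat))) stop("flat must cover every dag term")
  flat <- flat[ids]
  if (any(flat < 0 | flat > 1)) stop("flat probabilities must lie in [0, 1]")
  cons <- flat
  for (t in .by_depth(dag, decreasing = TRUE)) {
    ch <- dag$children[[t]]
    pos <- ch[cons[ch] >= threshold]
    if (length(pos) > 0) cons[t] <- mean(c(flat[t], cons[pos]))
  }
  cons
}

#' Top-down weakest-parent correction
#'
#' Processes terms from the root downward; a child whose value exceeds any
#' parent's corrected value is forced down to its weakest (smallest) parent.
#' Thresholding the output at any level therefore yields a consistent label
#' set. Values are never increased.
#'
#' @param dag A [go_dag()].
#' @param consensus Named probability vector in `[0, 1]`.
#' @return Named corrected probability vector.
#' @export
top_down_correction <- function(dag, consensus) {
  ids <- term_ids(dag)
  if (!all(ids %in% names(consensus))) stop("consensus must cover every dag term")
  out <- consensus[ids]
  for (t in .by_depth(dag, decreasing = FALSE)) {
    ps <- dag$parents[[t]]
    if (length(ps) > 0) out[t] <- min(out[t], min(out[ps]))
  }
  out
}

#' TPR-DAG prediction from flat probabilities
#'
#' Composition of [max_depths()], [bottom_up_consensus()] and
#' [top_down_correction()], with final labels thresholded at `threshold`.
#' Output labels are always consistent with the true-path constraint.
#'
#' @param dag A [go_dag()].
#' @param flat Named flat probability vector covering all dag terms.
#' @param threshold Positive-label threshold (default 0.5).
#' @return List with `probs` (corrected probabilities) and `labels` (named
#'   binary vector).
#' @export
tpr_dag_predict <- function(dag, flat, threshold = 0.5) {
  probs <- top_down_correction(dag, bottom_up_consensus(dag, flat, threshold))
  list(probs = probs,
       labels = stats::setNames(as.integer(probs >= threshold), names(probs)))
}

#' TPR-DAG prediction for a matrix of flat probabilities
#'
#' @param dag A [go_dag()].
#' @param flat Samples-by-terms probability matrix with term colnames.
#' @param threshold Positive-label threshold (default 0.5).
#' @return List with `probs` and `labels` matrices.
#' @export
tpr_dag_predict_matrix <- function(dag, flat, threshold = 0.5) {
  ids <- term_ids(dag)
  probs <- t(apply(flat[, ids, drop = FALSE], 1, function(p)
    tpr_dag_predict(dag, p, threshold)$probs))
  colnames(probs) <- ids
  rownames(probs) <- rownames(flat)
  list(probs = probs, labels = 1L * (probs >= threshold))
}
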