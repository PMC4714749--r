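# Per-term binary training sets (inclusive negative policy), a pluggable
# margin-producing scorer, and Platt sigmoid calibration.

# run expr with a locally seeded RNG, restoring global state afterwards
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Assemble a per-term binary training set
#'
#' Positives are the genes positive for the term in the closed annotation
#' matrix. Candidate negatives follow the inclusive policy: any gene with at
#' least one positive annotation in the sub-DAG but negative for the term —
#' closure semantics already guarantee such a gene is negative for all of the
#' term's descendants. Negatives are subsampled (seeded) to at most
#' `max_neg_ratio` times the positive count to keep classes balanced.
#'
#' @param term A term id present in `dag`.
#' @param matrix Closed binary annotation matrix from [ancestor_closure()].
#' @param dag A [go_dag()].
#' @param max_neg_ratio Maximum negatives-to-positives ratio (default 2).
#' @param seed Integer seed for the negative subsample.
#' @return List with `term`, `positives`, `negatives` (gene id vectors).
#' @export
build_binary_dataset <- function(term, matrix, dag, max_neg_ratio = 2,
                                 seed = 1L) {
  if (!term %in% term_ids(dag)) stop("term not in dag: ", term)
  pos <- rownames(matrix)[matrix[, term] == 1]
  if (length(pos) == 0) stop("no positive genes for term ", term)
  annotated <- rownames(matrix)[rowSums(matrix) > 0]
  cand <- setdiff(annotated, pos)
  if (length(cand) == 0) stop("no candidate negatives for term ", term)
  n_keep <- min(length(cand), ceiling(max_neg_ratio * length(pos)))
  neg <- if (n_keep < length(cand)) {
    .with_seed(seed, sort(sample(cand, n_keep)))
  } else {
    sort(cand)
  }
  list(term = term, positives = pos, negatives = neg)
}

#' Fit a Platt sigmoid calibration to classifier margins
#'
#' Maximises the Bernoulli likelihood of `p = 1 / (1 + exp(A * m + B))` with
#' Platt's smoothed targets `(N+ + 1) / (N+ + 2)` for positives and
#' `1 / (N- + 2)` for negatives, which regularise the fit away from hard 0/1
#' probabilities. For informative margins the fitted `A` is negative, so
#' larger margins map to larger probabilities.
#'
#' @param margins Real-valued classifier margins.
#' @param labels Binary labels (1 positive, 0 negative), same length.
#' @return Object of class `platt_sigmoid`: list with `A`, `B` and `predict`
#'   (a function mapping margins to probabilities in `(0, 1)`).
#' @export
fit_sigmoid <- function(margins, labels) {
  stopifnot(length(margins) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("sigmoid calibration needs both classes present")
  }
  t <- ifelse(labels == 1, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  nll <- function(par) {
    z <- par[1] * margins + par[2]
    # -sum(t*log p + (1-t)*log(1-p)) with p = 1/(1+exp(z)), overflow-safe
    sum(log1p(exp(-abs(z))) + t * pmax(z, 0) + (1 - t) * pmax(-z, 0))
  }
  fit <- stats::optim(c(A = -1, B = 0), nll, method = "BFGS")
  A <- fit$par[["A"]]; B <- fit$par[["B"]]
  structure(list(A = A, B = B,
                 predict = function(m) stats::plogis(-(A * m + B))),
            class = "platt_sigmoid")
}

#' Reference margin scorer: soft-margin linear SVM
#'
#' Returns a scorer obeying the pluggable contract of [score_terms()]: called
#' with a feature matrix and binary labels it fits a linear support-vector
#' machine (complexity constant `cost`, default 1) and returns a function
#' mapping new feature rows to signed decision-boundary margins, oriented so
#' positives score high.
#'
#' @param cost SVM complexity constant C (default 1).
#' @return A function `(features, labels) -> function(new_features) -> margins`.
#' @export
svm_margin_scorer <- function(cost = 1) {
  function(features, labels) {
    fit <- e1071::svm(features, factor(labels, levels = c(0, 1)),
                      kernel = "linear", cost = cost, scale = FALSE)
    function(new_features) {
      dv <- attr(stats::predict(fit, new_features, decision.values = TRUE),
                 "decision.values")
      # e1071 orients decision values by class order of appearance in the
      # training data; flip so the positive class always gets the high margin
      if (startsWith(colnames(dv)[1], "0/")) -dv[, 1] else dv[, 1]
    }
  }
}

#' Score every term of a sub-DAG with a pluggable binary scorer
#'
#' For each per-term dataset the scorer is fitted on that term's positives
#' and negatives and then applied to all genes (including those outside the
#' training set), yielding one margin column per term.
#'
#' @param scorer A function `(features, labels) -> predict function`, e.g.
#'   [svm_margin_scorer()].
#' @param datasets List of per-term datasets from [build_binary_dataset()].
#' @param features Numeric genes-by-features matrix with gene rownames.
#' @return Genes-by-terms margin matrix.
#' @export
score_terms <- function(scorer, datasets, features) {
  genes <- rownames(features)
  out <- matrix(NA_real_, nrow = length(genes), ncol = length(datasets),
                dimnames = list(genes, vapply(datasets, `[[`, "", "term")))
  for (d in datasets) {
    tr <- c(d$positives, d$negatives)
    lab <- c(rep(1L, length(d$positives)), rep(0L, length(d$negatives)))
    pred <- tryCatch(scorer(features[tr, , drop = FALSE], lab),
                     error = function(e)
                       stop("scorer failed for term ", d$term, ": ",
                            conditionMessage(e)))
    out[, d$term] <- pred(features)
  }
  out
}
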