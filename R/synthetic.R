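# Synthetic fixtures: rooted random DAGs, consistent annotation matrices and
# Gaussian-corrupted score matrices. The generative conditional is AND over
# parents, matching the support of the logical TPG factors, so generated data
# never violates the model.

#' Generate a rooted random layered DAG
#'
#' Terms are spread over `n_levels` levels with a single root at level 0;
#' every non-root term draws between 1 and `max_parents` parents uniformly
#' from strictly shallower levels, which guarantees acyclicity and
#' root-reachability by construction.
#'
#' @param n_terms Total number of terms (>= 1).
#' @param n_levels Number of levels, at most `n_terms`.
#' @param max_parents Upper bound on parents per term.
#' @param seed Integer seed; the same seed reproduces the same DAG.
#' @return A [go_dag()] with synthetic term ids `GO:S0000001`, ...
#' @export
random_godag <- function(n_terms, n_levels = min(4L, n_terms),
                         max_parents = 2L, seed = 1L) {
  if (n_terms < 1) stop("n_terms must be >= 1")
  if (n_levels < 1 || n_levels > n_terms) {
    stop("n_levels must lie between 1 and n_terms")
  }
  if (n_terms > 1 && n_levels < 2) stop("multi-term DAGs need n_levels >= 2")
  ids <- sprintf("GO:S%07d", seq_len(n_terms))
  .with_seed(seed, {
    level <- integer(n_terms)
    if (n_terms > 1) {
      # one term per level guaranteed, the rest spread uniformly
      level[2:n_levels] <- 1:(n_levels - 1)
      extra <- n_terms - n_levels
      if (extra > 0) {
        level[(n_levels + 1):n_terms] <-
          sample(1:(n_levels - 1), extra, replace = TRUE)
      }
    }
    ec <- character(0); ep <- character(0)
    for (i in seq_len(n_terms)[-1]) {
      shallower <- ids[level < level[i]]
      np <- sample(seq_len(min(max_parents, length(shallower))), 1)
      ps <- if (length(shallower) == 1) shallower else sample(shallower, np)
      ec <- c(ec, rep(ids[i], length(ps)))
      ep <- c(ep, ps)
    }
    go_dag(data.frame(id = ids, name = paste("synthetic term", seq_len(n_terms)),
                      namespace = "synthetic", stringsAsFactors = FALSE),
           data.frame(child = ec, parent = ep, stringsAsFactors = FALSE))
  })
}

#' Sample consistent annotation matrices from a DAG
#'
#' Per sample the root is positive; every other term, visited in topological
#' order, is positive with probability `theta` when all of its parents are
#' positive and negative otherwise. Every generated row is therefore
#' ancestor-closed by construction.
#'
#' @param dag A [go_dag()].
#' @param theta Conditional positive probability given all-positive parents.
#' @param n_samples Number of samples (rows).
#' @param seed Integer seed.
#' @return Binary samples-by-terms matrix with term colnames and sample
#'   rownames `s1`, `s2`, ...
#' @export
sample_annotations <- function(dag, theta, n_samples, seed = 1L) {
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  ids <- term_ids(dag)
  ord <- topo_order(dag)
  m <- matrix(0L, n_samples, length(ids),
              dimnames = list(paste0("s", seq_len(n_samples)), ids))
  .with_seed(seed, {
    m[, dag$root] <- 1L
    for (t in ord) {
      ps <- dag$parents[[t]]
      if (length(ps) == 0) next
      eligible <- rowSums(m[, ps, drop = FALSE] == 1L) == length(ps)
      m[eligible, t] <- 1L * (stats::runif(sum(eligible)) < theta)
    }
  })
  m
}

#' Corrupt annotations into real-valued scores through the Gaussian channel
#'
#' Maps labels `{1, 0}` to signals `{+1, -1}` and adds zero-mean Gaussian
#' noise of per-term variance `eta`: `y = x + N(0, eta)`.
#'
#' @param matrix Binary annotation matrix.
#' @param eta Noise variance, scalar or named per-term vector, at least
#'   [eta_floor].
#' @param seed Integer seed.
#' @return Real-valued score matrix of the same shape.
#' @export
corrupt_scores <- function(matrix, eta, seed = 1L) {
  ids <- colnames(matrix)
  if (length(eta) == 1) eta <- stats::setNames(rep(eta, length(ids)), ids)
  if (any(eta < eta_floor)) stop("eta below eta_floor")
  x <- 2 * matrix - 1
  .with_seed(seed, {
    noise <- matrix(stats::rnorm(length(x), sd = rep(sqrt(eta[ids]),
                                                     each = nrow(matrix))),
                    nrow = nrow(matrix))
    y <- x + noise
  })
  dimnames(y) <- dimnames(matrix)
  y
}

#' The four-term diamond DAG used in worked examples
#'
#' One root with two children that share a common child: the multiple
#' inheritance configuration whose logical factor spans two parents.
#'
#' @return A [go_dag()] with terms `GO:0000001` (root), `GO:0000002`,
#'   `GO:0000003` and their shared child `GO:0000004`.
#' @export
diamond_dag <- function() {
  go_dag(sprintf("GO:%07d", 1:4),
         data.frame(child = sprintf("GO:%07d", c(2, 3, 4, 4)),
                    parent = sprintf("GO:%07d", c(1, 1, 2, 3))))
}
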