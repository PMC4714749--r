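# Core factor graph: logical factors encoding the true-path-graph (TPG)
# constraint, consistency checking and label repair.
#
# Variable nodes carry binary annotations; one logical factor per non-root
# term links that term (the child) to all of its is_a parents. The factor is
# violated exactly when the child is positive while some parent is negative.
# Externally labels are {1, 0}; the noise channel maps them to {+1, -1}.

#' Build the core factor graph of a GO DAG
#'
#' Matches a DAG to a bipartite factor graph by breadth-first traversal from
#' the root: the first time a child term is visited a logical factor is
#' created for it, and each further parent encountered for the same child is
#' attached to that already-created factor. The resulting factor set depends
#' only on the edge set: one logical factor per non-root term, spanning the
#' term and all of its parents.
#'
#' @param dag A [go_dag()].
#' @return An object of class `factor_graph`: list with `variables` (term
#'   ids), `factors` (named list, one per non-root child; each has `child` and
#'   `parents`), and empty slots `y` (observations) and `eta` (per-term channel
#'   variances) filled later by [fgga_annotate()].
#' @export
build_core_fg <- function(dag) {
  factors <- list()
  visited <- dag$root
  frontier <- dag$root
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (p in frontier) {
      for (ch in dag$children[[p]]) {
        if (is.null(factors[[ch]])) {
          factors[[ch]] <- list(child = ch, parents = p)
        } else {
          # revisited child: attach this parent to the early created factor
          factors[[ch]]$parents <- c(factors[[ch]]$parents, p)
        }
        if (!ch %in% visited) {
          visited <- c(visited, ch)
          nxt <- c(nxt, ch)
        }
      }
    }
    frontier <- unique(nxt)
  }
  factors <- lapply(factors, function(f) {
    f$parents <- sort(unique(f$parents))
    class(f) <- "logical_factor"
    f
  })
  structure(list(variables = term_ids(dag), factors = factors,
                 y = NULL, eta = NULL),
            class = "factor_graph")
}

#' @export
print.factor_graph <- function(x, ...) {
  cat(sprintf("factor_graph: %d variables, %d logical factors%s\n",
              length(x$variables), length(x$factors),
              if (is.null(x$y)) "" else ", observed"))
  invisible(x)
}

#' Evaluate a TPG logical factor at a binary assignment
#'
#' The factor is satisfied (value 1) unless the child is positive while at
#' least one parent is negative; equivalently it enforces the two implication
#' rules "positive child implies positive parents" and "negative parent
#' implies negative children".
#'
#' @param factor A `logical_factor` (element of `build_core_fg(dag)$factors`).
#' @param assignment Named binary (0/1) vector covering exactly the factor's
#'   child and parents.
#' @return 0 or 1.
#' @export
evaluate_logical_factor <- function(factor, assignment) {
  vars <- c(factor$child, factor$parents)
  if (!setequal(names(assignment), vars)) {
    stop("assignment must cover exactly: ", paste(vars, collapse = ", "))
  }
  a <- assignment[vars]
  if (!all(a %in% c(0, 1))) stop("assignment values must be 0 or 1")
  as.integer(!(a[[1]] == 1 && any(a[-1] == 0)))
}

#' Enumerate the truth table of a TPG logical factor
#'
#' Materialises all `2^(1+n_parents)` rows with parent columns first and the
#' child column last, matching the conventional layout for a multi-parent
#' term. Factors of more than 12 linked variables are refused: closed-form
#' evaluation via [evaluate_logical_factor()] covers those.
#'
#' @param factor A `logical_factor`.
#' @return Data frame: one binary column per parent, one for the child, and a
#'   `value` column with the factor output.
#' @export
logical_factor_table <- function(factor) {
  vars <- c(factor$parents, factor$child)
  if (length(vars) > 12) {
    stop("truth table would have 2^", length(vars),
         " rows; use evaluate_logical_factor() for high-degree factors")
  }
  grid <- expand.grid(rep(list(0:1), length(vars)))[, length(vars):1, drop = FALSE]
  names(grid) <- vars
  child <- grid[[factor$child]]
  par <- as.matrix(grid[, factor$parents, drop = FALSE])
  grid$value <- as.integer(!(child == 1 & rowSums(par == 0) > 0))
  grid
}

#' Find TPG violations of a binary label vector
#'
#' @param dag A [go_dag()].
#' @param labels Named binary vector covering all dag terms.
#' @return Data frame of violated edges (`child`, `parent`): rows where the
#'   child label is 1 and the parent label is 0. Zero rows iff consistent.
#' @export
check_consistency <- function(dag, labels) {
  miss <- setdiff(term_ids(dag), names(labels))
  if (length(miss) > 0) {
    stop("labels missing term(s): ", paste(miss, collapse = ", "))
  }
  e <- dag$edges
  bad <- labels[e$child] == 1 & labels[e$parent] == 0
  e[bad, , drop = FALSE]
}

#' Repair a label vector to TPG consistency
#'
#' Top-down pass in topological order: a child is forced to 0 whenever any of
#' its parents is 0 (negative-parent propagation). This never invents
#' positives, so the repaired positives are a subset of the input positives,
#' and the output always passes [check_consistency()].
#'
#' @param dag A [go_dag()].
#' @param labels Named binary vector covering all dag terms.
#' @return Repaired named binary vector in the same term order as the input.
#' @export
repair_labels <- function(dag, labels) {
  miss <- setdiff(term_ids(dag), names(labels))
  if (length(miss) > 0) {
    stop("labels missing term(s): ", paste(miss, collapse = ", "))
  }
  out <- labels
  for (t in topo_order(dag)) {
    ps <- dag$parents[[t]]
    if (length(ps) > 0 && out[t] == 1 && any(out[ps] == 0)) out[t] <- 0
  }
  out
}

#' Export a factor graph in DOT format for inspection
#'
#' Variable nodes are drawn as circles and logical factors as boxes, the usual
#' bipartite factor-graph layout.
#'
#' @param fg A `factor_graph`.
#' @param path Output path for the DOT text.
#' @return Invisibly, `path`.
#' @export
write_fg_dot <- function(fg, path) {
  q <- function(x) paste0('"', x, '"')
  lines <- c("graph factor_graph {")
  lines <- c(lines, paste0("  ", q(fg$variables), " [shape=circle];"))
  for (f in fg$factors) {
    fid <- paste0("f_", f$child)
    lines <- c(lines, paste0("  ", q(fid), " [shape=box,label=", q(fid), "];"),
               paste0("  ", q(fid), " -- ", q(c(f$child, f$parents)), ";"))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
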