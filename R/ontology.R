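# GO DAG container, OBO/GAF input, evidence policies, ancestor closure and
# sub-DAG selection.

#' Construct and validate a GO DAG
#'
#' A `go_dag` is a rooted directed acyclic graph of ontology terms whose edges
#' are child-to-parent `is_a` relationships. Every non-root term must reach the
#' single root by directed child-to-parent paths.
#'
#' @param terms Character vector of term identifiers, or a data frame with
#'   columns `id`, `name`, `namespace` (missing columns are filled).
#' @param edges Data frame with character columns `child` and `parent`, one row
#'   per `is_a` edge. May have zero rows for a single-term ontology.
#' @return An object of class `go_dag`: a list with elements `terms` (data
#'   frame), `edges` (data frame), `root` (term id), `parents` and `children`
#'   (named lists of character vectors, keyed by term id).
#' @examples
#' d <- go_dag(c("GO:1", "GO:2"), data.frame(child = "GO:2", parent = "GO:1"))
#' d$root
#' @export
go_dag <- function(terms, edges = data.frame(child = character(), parent = character())) {
  if (is.character(terms)) {
    terms <- data.frame(id = terms, name = terms, namespace = "synthetic",
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(terms), "id" %in% names(terms))
  if (is.null(terms$name)) terms$name <- terms$id
  if (is.null(terms$namespace)) terms$namespace <- "synthetic"
  if (anyDuplicated(terms$id)) {
    stop("duplicate term identifiers: ",
         paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "))
  }
  edges <- data.frame(child = as.character(edges$child),
                      parent = as.character(edges$parent),
                      stringsAsFactors = FALSE)
  missing <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(missing) > 0) {
    stop("edge references unknown term(s): ", paste(missing, collapse = ", "))
  }
  edges <- unique(edges)
  if (any(edges$child == edges$parent)) {
    stop("self-loop edge on term ", edges$child[edges$child == edges$parent][1])
  }

  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = terms$id)
    if (!igraph::is_dag(g)) {
      cyc <- igraph::feedback_arc_set(g)
      e1 <- igraph::ends(g, cyc[[1]])
      stop("cycle detected involving is_a edge ", e1[1], " -> ", e1[2])
    }
  }

  parents <- split(edges$parent, factor(edges$child, levels = terms$id))
  children <- split(edges$child, factor(edges$parent, levels = terms$id))
  roots <- terms$id[lengths(parents) == 0L]
  if (length(roots) == 0L) stop("no root found: every term has a parent")
  if (length(roots) > 1L) {
    stop("multiple roots found: ", paste(roots, collapse = ", "),
         "; a go_dag must have exactly one root")
  }

  dag <- structure(list(terms = terms, edges = edges, root = roots,
                        parents = parents, children = children),
                   class = "go_dag")
  # every term must reach the root
  unreachable <- setdiff(terms$id, c(dag_ancestors_all(dag), roots))
  if (length(unreachable) > 0) {
    stop("term(s) cannot reach the root: ", paste(unreachable, collapse = ", "))
  }
  dag
}

# ids of all terms with a directed path to the root (excludes disconnected ones)
dag_ancestors_all <- function(dag) {
  reached <- character(0)
  frontier <- dag$root
  while (length(frontier) > 0) {
    kids <- unique(unlist(dag$children[frontier], use.names = FALSE))
    kids <- setdiff(kids, reached)
    reached <- c(reached, frontier)
    frontier <- kids
  }
  reached
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms, %d is_a edges, root %s\n",
              nrow(x$terms), nrow(x$edges), x$root))
  invisible(x)
}

#' Number of terms in a GO DAG
#' @param dag A `go_dag`.
#' @return Integer term count.
#' @export
n_terms <- function(dag) nrow(dag$terms)

#' Term identifiers of a GO DAG
#' @param dag A `go_dag`.
#' @return Character vector of term ids (root first is not guaranteed; use
#'   [topo_order()] for a parent-before-child ordering).
#' @export
term_ids <- function(dag) dag$terms$id

#' Topological ordering of terms (parents before children)
#' @param dag A `go_dag`.
#' @return Character vector of term ids; the root is first.
#' @export
topo_order <- function(dag) {
  if (nrow(dag$edges) == 0) return(dag$terms$id)
  g <- igraph::graph_from_data_frame(dag$edges, directed = TRUE,
                                     vertices = dag$terms$id)
  # edges point child -> parent, so reverse order puts parents first
  rev(names(igraph::topo_sort(g, mode = "out")))
}

#' Leaf terms of a GO DAG
#' @param dag A `go_dag`.
#' @return Character vector of terms with no children.
#' @export
dag_leaves <- function(dag) {
  dag$terms$id[lengths(dag$children[dag$terms$id]) == 0L]
}

#' All ancestors of a term (excluding the term itself)
#' @param dag A `go_dag`.
#' @param term A term id.
#' @return Character vector of ancestor ids, unordered.
#' @export
dag_ancestors <- function(dag, term) {
  seen <- character(0)
  frontier <- dag$parents[[term]]
  while (length(frontier) > 0) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(dag$parents[frontier], use.names = FALSE))
  }
  seen
}

#' Parse an OBO ontology document into a GO DAG
#'
#' Reads `[Term]` stanzas and interprets only the `id`, `name`, `namespace`,
#' `is_a` and `is_obsolete` tags; all other tags, including non-`is_a`
#' relationships such as `part_of`, are ignored. Obsolete terms are dropped,
#' together with any edges touching them. The result is restricted to a single
#' namespace.
#'
#' @param x Path to an OBO file, or a character vector of OBO lines.
#' @param namespace Namespace to keep. `NULL` (default) selects the namespace
#'   with the most terms.
#' @return A [go_dag()].
#' @export
parse_obo <- function(x, namespace = NULL) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x, warn = FALSE) else x
  lines <- trimws(lines)

  term_starts <- which(lines == "[Term]")
  stanza_starts <- grep("^\\[.*\\]$", lines)
  if (length(term_starts) == 0) stop("no [Term] stanzas found in OBO input")

  ids <- character(0); nms <- character(0); nss <- character(0)
  edges_c <- character(0); edges_p <- character(0)
  for (s in term_starts) {
    nxt <- stanza_starts[stanza_starts > s]
    e <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[(s + 1L):e]
    tagval <- function(tag) {
      v <- block[startsWith(block, paste0(tag, ":"))]
      sub("!.*$", "", sub(paste0("^", tag, ":\\s*"), "", v))
    }
    id <- trimws(tagval("id"))[1]
    if (is.na(id) || !nzchar(id)) next
    obs <- trimws(tagval("is_obsolete"))
    if (length(obs) && any(obs == "true")) next
    nm <- trimws(tagval("name"))[1]
    ns <- trimws(tagval("namespace"))[1]
    isa <- trimws(sub("\\s.*$", "", trimws(tagval("is_a"))))
    ids <- c(ids, id)
    nms <- c(nms, if (is.na(nm)) id else nm)
    nss <- c(nss, if (is.na(ns)) "unspecified" else ns)
    if (length(isa)) {
      edges_c <- c(edges_c, rep(id, length(isa)))
      edges_p <- c(edges_p, isa)
    }
  }

  if (is.null(namespace)) {
    namespace <- names(sort(table(nss), decreasing = TRUE))[1]
  }
  keep <- nss == namespace
  ids <- ids[keep]; nms <- nms[keep]; nss <- nss[keep]
  ek <- edges_c %in% ids & edges_p %in% ids
  go_dag(data.frame(id = ids, name = nms, namespace = nss,
                    stringsAsFactors = FALSE),
         data.frame(child = edges_c[ek], parent = edges_p[ek],
                    stringsAsFactors = FALSE))
}

#' Read gene-to-term annotation records from a GAF 2.x file
#'
#' Expects tab-separated GAF 2.x column order; comment lines starting with `!`
#' are skipped and rows whose qualifier contains `NOT` are dropped, since
#' negated annotations are not positive evidence.
#'
#' @param path Path to an (uncompressed) GAF file.
#' @return Data frame with columns `gene`, `term`, `evidence`.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(gene = character(), term = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  too_short <- vapply(f, length, 1L) < 7L
  if (any(too_short)) stop("GAF rows with fewer than 7 columns at line(s) ",
                           paste(utils::head(which(too_short), 3), collapse = ", "))
  gene <- vapply(f, `[[`, "", 2L)      # DB object ID
  qual <- vapply(f, `[[`, "", 4L)
  term <- vapply(f, `[[`, "", 5L)
  evid <- vapply(f, `[[`, "", 7L)
  keep <- !grepl("(^|\\|)NOT(\\||$)", qual)
  data.frame(gene = gene[keep], term = term[keep], evidence = evid[keep],
             stringsAsFactors = FALSE)
}

# evidence-code sets for the two training policies
.evidence_robust <- c("IMP", "IGI", "IPI", "IEP", "IDA")
.evidence_loose  <- c(.evidence_robust, "TAS", "IEA")

#' Filter annotation records by evidence-code policy
#'
#' The `robust` policy keeps only experimental evidence codes (IMP, IGI, IPI,
#' IEP, IDA); the `loose` policy additionally keeps TAS and IEA. Record order
#' is preserved.
#'
#' @param records Data frame with columns `gene`, `term`, `evidence`.
#' @param policy `"robust"` or `"loose"`.
#' @return The filtered data frame.
#' @export
apply_evidence_policy <- function(records, policy = c("robust", "loose")) {
  if (!is.character(policy) || !policy[1] %in% c("robust", "loose")) {
    stop("unknown evidence policy: ", policy[1])
  }
  policy <- policy[1]
  keep <- switch(policy, robust = .evidence_robust, loose = .evidence_loose)
  records[records$evidence %in% keep, , drop = FALSE]
}

#' Propagate annotations to ancestors (true-path closure)
#'
#' Builds a binary genes-by-terms matrix in which a gene is positive for a term
#' iff it is directly annotated to the term or to any of its descendants. The
#' output therefore satisfies the true-path-graph constraint: a positive child
#' implies positive parents.
#'
#' @param dag A `go_dag`.
#' @param records Data frame with columns `gene` and `term`. Annotations on
#'   terms absent from `dag` raise an error.
#' @return Binary matrix with gene rownames and term colnames (all dag terms,
#'   in `term_ids(dag)` order).
#' @export
ancestor_closure <- function(dag, records) {
  ids <- term_ids(dag)
  bad <- setdiff(unique(records$term), ids)
  if (length(bad) > 0) {
    stop("annotation term(s) absent from dag: ", paste(bad, collapse = ", "))
  }
  genes <- sort(unique(records$gene))
  m <- matrix(0L, nrow = length(genes), ncol = length(ids),
              dimnames = list(genes, ids))
  if (nrow(records) > 0) {
    m[cbind(records$gene, records$term)] <- 1L
    # children before parents: reverse topological order
    for (t in rev(topo_order(dag))) {
      ps <- dag$parents[[t]]
      if (length(ps) > 0) {
        pos <- m[, t] == 1L
        if (any(pos)) m[pos, ps] <- 1L
      }
    }
  }
  m
}

#' Select an ancestor-closed sub-DAG with sufficient positive support
#'
#' Keeps terms whose closed positive count is at least `min_pos`, then adds all
#' ancestors of kept terms so the result is ancestor-closed; the root is always
#' kept. Because closure makes positive counts monotone non-decreasing from
#' child to parent, ancestors of a kept term always meet the threshold too.
#'
#' @param dag A `go_dag`.
#' @param matrix Closed binary annotation matrix from [ancestor_closure()].
#' @param min_pos Minimum number of positive genes per kept term (>= 1).
#'   Published settings use 50 for robust and 10 for loose annotation data.
#' @return The induced `go_dag` on the kept terms.
#' @export
select_subdag <- function(dag, matrix, min_pos) {
  if (!is.numeric(min_pos) || min_pos < 1) stop("min_pos must be >= 1")
  extra <- setdiff(colnames(matrix), term_ids(dag))
  if (length(extra) > 0) {
    stop("matrix term(s) absent from dag: ", paste(extra, collapse = ", "))
  }
  counts <- colSums(matrix)
  keep <- names(counts)[counts >= min_pos]
  keep <- unique(c(dag$root, keep,
                   unlist(lapply(keep, dag_ancestors, dag = dag),
                          use.names = FALSE)))
  keep <- intersect(term_ids(dag), keep)  # original order
  e <- dag$edges
  e <- e[e$child %in% keep & e$parent %in% keep, , drop = FALSE]
  go_dag(dag$terms[dag$terms$id %in% keep, , drop = FALSE], e)
}

#' Write an annotation or score matrix as tab-separated text
#' @param m Matrix with gene rownames and term colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_term_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_term_matrix()]
#' @param path Input path.
#' @return Matrix with gene rownames and term colnames.
#' @export
read_term_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
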