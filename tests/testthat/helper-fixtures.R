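# Shared fixtures built in code.

# single-edge ontology: B is_a A
edge_dag <- function() {
  go_dag(c("A", "B"), data.frame(child = "B", parent = "A"))
}

# three-level chain A <- B <- C
chain_dag <- function(k = 3) {
  ids <- LETTERS[seq_len(k)]
  go_dag(ids, data.frame(child = ids[-1], parent = ids[-k]))
}

# random scores/variances for a dag, reproducible
random_observation <- function(dag, seed, y_sd = 1.5) {
  set.seed(seed)
  ids <- term_ids(dag)
  list(y = stats::setNames(rnorm(length(ids), 0, y_sd), ids),
       eta = stats::setNames(runif(length(ids), 0.2, 2), ids))
}

obo_path <- function(name) system.file("extdata", name, package = "fgannot")
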