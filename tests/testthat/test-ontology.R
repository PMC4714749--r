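test_that("go_dag validates structure", {
  d <- edge_dag()
  expect_s3_class(d, "go_dag")
  expect_equal(d$root, "A")
  # cycle
  expect_error(go_dag(c("A", "B"),
                      data.frame(child = c("A", "B"), parent = c("B", "A"))),
               "cycle|root")
  # two roots (B unreachable)
  expect_error(go_dag(c("A", "B", "C"),
                      data.frame(child = "C", parent = "A")),
               "multiple roots")
  expect_error(go_dag(c("A", "A")), "duplicate")
})

test_that("parse_obo keeps only is_a structure in one namespace", {
  min_doc <- c("[Term]", "id: GO:A", "name: a", "namespace: mf", "",
               "[Term]", "id: GO:B", "name: b", "namespace: mf",
               "is_a: GO:A ! a")
  d <- parse_obo(min_doc)
  expect_equal(n_terms(d), 2)
  expect_equal(nrow(d$edges), 1)
  expect_equal(d$root, "GO:A")

  # part_of relationships are dropped
  doc <- c(min_doc, "relationship: part_of GO:A")
  expect_equal(nrow(parse_obo(doc)$edges), 1)

  # is_a cycle is a structural error
  cyc <- c("[Term]", "id: GO:A", "namespace: mf", "is_a: GO:B", "",
           "[Term]", "id: GO:B", "namespace: mf", "is_a: GO:A")
  expect_error(parse_obo(cyc), "cycle|root")
})

test_that("parse_obo drops obsolete and out-of-namespace terms", {
  d <- parse_obo(obo_path("toy7.obo"))
  expect_equal(n_terms(d), 7)                      # 9 stanzas in the file
  expect_false("GO:0100008" %in% term_ids(d))      # obsolete
  expect_false("GO:0200001" %in% term_ids(d))      # other namespace
  expect_equal(d$root, "GO:0100001")
  expect_equal(unname(max_depths(d)[["GO:0100007"]]), 3)
})

test_that("evidence policies keep the documented code sets", {
  rec <- data.frame(gene = c("g1", "g1", "g2", "g3"),
                    term = c("t1", "t2", "t1", "t3"),
                    evidence = c("IDA", "IEA", "TAS", "IMP"))
  robust <- apply_evidence_policy(rec, "robust")
  expect_equal(robust$evidence, c("IDA", "IMP"))
  loose <- apply_evidence_policy(rec, "loose")
  expect_equal(nrow(loose), 4)
  expect_equal(loose$gene, rec$gene)               # order preserved
  expect_equal(nrow(apply_evidence_policy(rec[0, ], "robust")), 0)
  expect_error(apply_evidence_policy(rec, "strictest"), "unknown")
})

test_that("GAF reader drops NOT-qualified rows", {
  rec <- read_gaf(system.file("extdata", "toy7.gaf", package = "fgannot"))
  expect_equal(sum(rec$gene == "g6"), 1)           # NOT row removed
  expect_equal(rec$evidence[rec$gene == "g6"], "IPI")
  expect_equal(nrow(rec), 7)
})

test_that("ancestor closure propagates to the root and is idempotent", {
  d <- chain_dag(3)                                # A <- B <- C
  rec <- data.frame(gene = "g1", term = "C")
  m <- ancestor_closure(d, rec)
  expect_equal(as.vector(m["g1", c("A", "B", "C")]), c(1, 1, 1))

  rec2 <- data.frame(gene = "g2", term = "A")
  m2 <- ancestor_closure(d, rec2)
  expect_equal(as.vector(m2["g2", ]), c(1, 0, 0))

  expect_error(ancestor_closure(d, data.frame(gene = "g", term = "Z")), "Z")

  # idempotence: re-closing direct records equal to the closed matrix
  long <- data.frame(gene = rep("g1", 3), term = c("A", "B", "C"))
  expect_equal(ancestor_closure(d, long), m)
})

test_that("closed matrices are always consistent with monotone counts", {
  for (seed in 1:5) {
    d <- random_godag(12, n_levels = 4, max_parents = 3, seed = seed)
    set.seed(seed)
    rec <- data.frame(gene = sample(paste0("g", 1:6), 15, replace = TRUE),
                      term = sample(term_ids(d), 15, replace = TRUE))
    m <- ancestor_closure(d, rec)
    for (g in rownames(m)) {
      expect_equal(nrow(check_consistency(d, m[g, ])), 0)
    }
    counts <- colSums(m)
    e <- d$edges
    expect_true(all(counts[e$parent] >= counts[e$child]))
  }
})

test_that("select_subdag keeps supported terms and their ancestors", {
  d <- chain_dag(3)
  m <- ancestor_closure(d, data.frame(gene = c("g1", "g2"),
                                      term = c("C", "B")))
  # counts: A=2, B=2, C=1
  expect_setequal(term_ids(select_subdag(d, m, 2)), c("A", "B"))
  expect_setequal(term_ids(select_subdag(d, m, 1)), c("A", "B", "C"))
  expect_equal(term_ids(select_subdag(d, m, 99)), "A")   # root always kept
  expect_error(select_subdag(d, m, 0), "min_pos")
  sub <- select_subdag(d, m, 2)
  expect_s3_class(sub, "go_dag")
})
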