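test_that("a single unconstrained term reproduces the channel posterior", {
  d <- go_dag("A")
  r <- fgga_annotate(d, c(A = 0.8), c(A = 0.5))
  expect_equal(unname(r$marginals[["A"]]),
               channel_posterior(0.8, +1, 0.5), tolerance = 1e-12)
  expect_equal(r$iterations, 1)
  expect_true(r$converged)
})

test_that("single-edge graph with uninformative scores gives (2/3, 1/3)", {
  d <- edge_dag()
  y <- c(A = 0, B = 0)
  bf <- brute_force_marginals(d, y, 1)
  expect_equal(unname(bf), c(2 / 3, 1 / 3), tolerance = 1e-12)
  r <- fgga_annotate(d, y, c(A = 1, B = 1), xi = 1e-10, i_max = 100)
  expect_equal(unname(r$marginals), c(2 / 3, 1 / 3), tolerance = 1e-9)
})

test_that("tree-shaped graphs reproduce exact marginals", {
  for (seed in 1:25) {
    nt <- sample(3:10, 1)
    d <- random_godag(nt, n_levels = min(4, nt), max_parents = 1, seed = seed)
    obs <- random_observation(d, seed + 100)
    bf <- brute_force_marginals(d, obs$y, obs$eta)
    r <- fgga_annotate(d, obs$y, obs$eta, xi = 1e-10, i_max = 100)
    expect_equal(unname(r$marginals), unname(bf), tolerance = 1e-6)
    expect_true(r$converged)
  }
})

test_that("well-separated loopy diamonds recover the exact MAP", {
  for (seed in 1:40) {
    d <- diamond_dag(); ids <- term_ids(d)
    set.seed(seed)
    eta <- stats::setNames(runif(4, 0.1, 0.5), ids)
    lab <- sample_annotations(d, 0.7, 1, seed = seed)[1, ]
    y <- stats::setNames((2 * lab - 1) *
                           pmax(2 * eta, abs(rnorm(4, 2, 0.5)) * eta), ids)
    r <- fgga_annotate(d, y, eta, xi = 1e-8, i_max = 200)
    expect_equal(unname(r$map_repaired), unname(brute_force_map(d, y, eta)))
  }
})

test_that("inconsistent evidence is resolved consistently", {
  d <- edge_dag()
  # strong positive child, strong negative parent
  r <- fgga_annotate(d, c(A = -3, B = 3), c(A = 0.5, B = 0.5))
  expect_equal(nrow(check_consistency(d, r$map_repaired)), 0)
  bf <- brute_force_marginals(d, c(A = -3, B = 3), 0.5)
  expect_gte(bf[["A"]], bf[["B"]])         # exact posterior is monotone
})

test_that("exact posterior marginals are monotone along edges", {
  for (seed in 1:100) {
    d <- random_godag(sample(3:8, 1), n_levels = 3, max_parents = 3,
                      seed = seed)
    obs <- random_observation(d, seed + 500, y_sd = 2)
    bf <- brute_force_marginals(d, obs$y, obs$eta)
    e <- d$edges
    expect_true(all(bf[e$parent] >= bf[e$child] - 1e-12))
  }
})

test_that("increasing a score never decreases that term's exact marginal", {
  d <- diamond_dag(); ids <- term_ids(d)
  obs <- random_observation(d, 9)
  for (t in ids) {
    y2 <- obs$y; y2[t] <- y2[t] + 1.5
    expect_gte(brute_force_marginals(d, y2, obs$eta)[[t]],
               brute_force_marginals(d, obs$y, obs$eta)[[t]])
  }
})

test_that("closed-form factor messages equal truth-table summation", {
  set.seed(31)
  for (np in c(1, 2, 3, 5, 8, 11)) {
    child_in <- runif(1)
    parent_in <- runif(np)
    cf <- fgannot:::.factor_out(child_in, matrix(parent_in, nrow = 1))
    en <- fgannot:::.factor_out_enum(child_in, parent_in)
    expect_equal(cf$child, en$child, tolerance = 1e-12)
    expect_equal(as.numeric(cf$parents), en$parents, tolerance = 1e-12)
  }
})

test_that("matrix annotation agrees with per-sample annotation", {
  d <- random_godag(10, n_levels = 3, max_parents = 2, seed = 5)
  ann <- sample_annotations(d, 0.7, 6, seed = 6)
  sc <- corrupt_scores(ann, 0.3, seed = 7)
  eta <- stats::setNames(rep(0.3, 10), term_ids(d))
  rm_ <- fgga_annotate_matrix(d, sc, eta, xi = 1e-8, i_max = 100)
  for (s in rownames(sc)) {
    r1 <- fgga_annotate(d, sc[s, ], eta, xi = 1e-8, i_max = 100)
    expect_equal(unname(rm_$marginals[s, ]), unname(r1$marginals),
                 tolerance = 1e-6)
  }
  expect_true(all(apply(rm_$map_repaired, 1, function(l)
    nrow(check_consistency(d, l)) == 0)))
})

test_that("non-convergence is reported rather than raised", {
  d <- diamond_dag()
  obs <- random_observation(d, 17)
  r <- fgga_annotate(d, obs$y, obs$eta, xi = 1e-15, i_max = 2)
  expect_false(r$converged)
  expect_equal(r$iterations, 2)
  expect_true(is.finite(r$residual))
})

test_that("damped runs are deterministic and still converge", {
  d <- diamond_dag()
  obs <- random_observation(d, 23)
  r1 <- fgga_annotate(d, obs$y, obs$eta, damping = 0.4)
  r2 <- fgga_annotate(d, obs$y, obs$eta, damping = 0.4)
  expect_identical(r1$marginals, r2$marginals)
  expect_true(r1$converged)
})

test_that("brute force refuses oversized graphs and normalises", {
  d <- random_godag(21, n_levels = 4, seed = 1)
  obs <- random_observation(d, 2)
  expect_error(brute_force_marginals(d, obs$y, obs$eta), "20")
  d2 <- chain_dag(4)
  obs2 <- random_observation(d2, 3)
  bf <- brute_force_marginals(d2, obs2$y, obs2$eta)
  expect_true(all(bf >= 0 & bf <= 1))
})
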