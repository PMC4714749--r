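# fgannot

Ontology-aware annotation of gene products over the Gene Ontology (GO) by
factor-graph inference.

Per-term binary classifiers predict GO terms independently, so their outputs
are noisy and routinely violate the true-path-graph (TPG) constraint of the
ontology: annotation to a term must imply annotation to every `is_a`
ancestor. `fgannot` reconciles such predictions in a single probabilistic
model. It is aimed at computational biologists building hierarchical
multi-label protein-function predictors, and at anyone who needs consistent,
confidence-scored GO annotations from per-term classifier scores.

## The model

Each term contributes a binary variable node $x_i$; each non-root term
contributes a logical factor over the term and its parents that is violated
exactly when the child is positive while some parent is negative. Observed
classifier scores enter through a Gaussian channel: $y_i = x_i + z_i$ with
$x_i \in \{+1,-1\}$ and $z_i \sim N(0, \eta_i)$, giving the channel posterior

$$p(x_i \mid y_i) = \frac{1}{1 + e^{-2 y_i x_i / \eta_i}},
\qquad
\hat\eta_i = \frac{1}{L^+ - 1}\sum_{l=1}^{L^+} (y_{il} - 1)^2 .$$

Iterative sum-product message passing (synchronous flooding, tolerance
$\xi = 10^{-3}$, at most 50 iterations by default) approximates the per-term
posterior marginals $p(x_i = 1 \mid Y)$; thresholding at 0.5 and a top-down
repair pass yield consistent MAP annotations. An exhaustive-enumeration
oracle validates the loopy approximation on graphs of up to 20 terms. The
TPR-DAG heuristic (bottom-up averaging with positive children, top-down
weakest-parent correction) and flat thresholding are included as baselines,
with per-term AUC, hierarchical precision/recall/F, k-fold cross-validation
and Wilcoxon rank-sum comparison for evaluation.

## Worked example

Simulate consistent annotations on the bundled 7-term ontology, corrupt them
through the channel, estimate variances, and annotate:

```r
library(fgannot)

dag <- parse_obo(system.file("extdata", "toy7.obo", package = "fgannot"))
dag
#> go_dag: 7 terms, 7 is_a edges, root GO:0100001

ann    <- sample_annotations(dag, theta = 0.8, n_samples = 200, seed = 42)
scores <- corrupt_scores(ann, eta = 0.25, seed = 43)
eta_hat <- vapply(term_ids(dag), function(t)
  estimate_variance(scores[ann[, t] == 1, t]), 0)
round(eta_hat, 3)
#> GO:0100001 GO:0100002 GO:0100003 GO:0100004 GO:0100005 GO:0100006 GO:0100007
#>      0.236      0.265      0.228      0.250      0.263      0.193      0.323

res <- fgga_annotate(dag, scores[1, ], eta_hat)
res
#> fgga_result: 7 terms, 1 positive (repaired); 3 iterations, converged (residual 2.85e-06)
round(res$marginals, 3)
#> GO:0100001 GO:0100002 GO:0100003 GO:0100004 GO:0100005 GO:0100006 GO:0100007
#>      1.000      0.000      0.012      0.000      0.000      0.000      0.000
```

The variance estimates recover the generating value 0.25 per term; for the
first sample (truly annotated only to the root) inference drives every
non-root marginal to near zero and returns the root-only annotation. On all
200 samples, factor-graph annotation improves the hierarchical F-score over
flat thresholding:

```r
resm <- fgga_annotate_matrix(dag, scores, eta_hat)
flat <- t(apply(1L * (scores > 0), 1, function(l) repair_labels(dag, l)))
hierarchical_prf(dag, flat,              ann)$HF  #> 0.967
hierarchical_prf(dag, resm$map_repaired, ann)$HF  #> 0.992
```

A command-line wrapper is installed under `exec/fgannot` with subcommands
`build-graph`, `simulate`, `estimate-noise`, `annotate`, `tpr-dag`,
`evaluate` and `compare`; every run writes a JSON manifest sufficient to
reproduce it bit-exactly.

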