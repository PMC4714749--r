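---
title: "Consistent GO annotation by factor-graph inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consistent GO annotation by factor-graph inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgannot)
```

## The problem

Automated Gene Ontology (GO) annotation assigns each gene product a set of
terms from a rooted DAG in which edges are `is_a` relationships from more
specific (child) to more general (parent) terms. Valid annotation sets obey
the true-path-graph (TPG) constraint: annotation to a term implies annotation
to every ancestor, or equivalently a negative parent forces negative
children. Per-term binary classifiers ignore this structure, so their raw
predictions are both noisy and mutually inconsistent. `fgannot` reconciles
them by exact probabilistic reasoning on small graphs and loopy belief
propagation on larger ones.

## The model

**Core factor graph.** Each term contributes a binary variable node $x_i$.
Each non-root term contributes one logical factor linking the term (as child)
to all of its parents; the factor evaluates to 0 exactly when the child is
positive while some parent is negative, and to 1 otherwise. For a child with
two parents the factor's truth table has $2^3$ rows, of which the three
child-positive rows with a negative parent are unsatisfied:

```{r truth-table}
fg <- build_core_fg(diamond_dag())
logical_factor_table(fg$factors[["GO:0000004"]])
```

The graph is matched from the DAG by breadth-first traversal from the root: a
factor is created the first time a child is visited, and later-encountered
parents of the same child are attached to that factor. The resulting factor
set depends only on the edge set, so the traversal order is irrelevant
(unit-tested).

**Gaussian noise channel.** A classifier's real-valued score $y_i$ (a
soft-margin SVM margin, in the reference scorer) is modelled as
$y_i = x_i + z_i$ with latent signal $x_i \in \{+1, -1\}$ and zero-mean
Gaussian noise of per-term variance $\eta_i$. Under equal priors the channel
posterior is logistic,
$p(x_i \mid y_i) = 1 / (1 + e^{-2 y_i x_i / \eta_i})$,
and $\eta_i$ is estimated from the $L^+$ positively annotated validation
scores as $\hat\eta_i = \sum_l (y_{il} - 1)^2 / (L^+ - 1)$
(`estimate_variance()`; an optional pooled mode also uses negatives at
signal $-1$ under the symmetric-channel assumption, off by default).

**Inference.** `sum_product()` runs synchronous-flooding message passing:
every factor-to-variable message is recomputed from the previous iteration's
variable-to-factor messages, then vice versa, until the largest change in any
marginal falls below $\xi$ (default $10^{-3}$) or `i_max` (default 50)
iterations. Marginals are thresholded at 0.5 (ties negative) for the raw MAP
labels; a top-down pass that zeroes any positive child under a negative
parent yields the repaired labels, which are the default consistent output.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `xi` | 1e-3 | convergence tolerance on marginals (probability units) |
| `i_max` | 50 | iteration cap; non-convergence is reported, not an error |
| `damping` | 0 | mixes old messages into updates; useful on oscillating loopy graphs |
| `eta_floor` | 1e-6 | lower clamp on channel variances |
| `min_pos` | 50 robust / 10 loose | minimum closed positives for a term to be modelled |
| `max_neg_ratio` | 2 | negatives-to-positives cap in per-term training sets |
| `threshold` | 0.5 | positive-label threshold (MAP and TPR-DAG) |
| `leaf_cut` | 0.95 | minimum marginal for kept leaves when pruning predictions |

`eta_floor` exists because a zero variance makes the channel posterior a hard
0/1 and can annihilate entire message products; $10^{-6}$ keeps inference
finite while remaining effectively deterministic. Scores are used as-is
(unthresholded margins); no rescaling is applied.

## Numerical choices

Messages are Bernoulli pairs stored as their "+1" component and clamped to
$[10^{-12}, 1 - 10^{-12}]$. Logical factors use closed-form messages —
$O(\#\text{parents})$ per factor — that are unit-tested for equality against
explicit truth-table summation for degrees 2–12; truth tables themselves are
materialised only up to degree 12. An all-zero message product (a logical
contradiction, possible only at extreme variances) is reset to uniform and
counted in the diagnostics rather than raised. Variable-to-factor messages
start uniform. The convergence test aggregates per-term changes by max. A
marginal of exactly 0.5 maps to a negative label (conservative annotation).

Two design points were genuinely open and are resolved as follows. Positive
counts for sub-DAG selection use closure-propagated annotations (TPG
positives include inherited ones), computed before the threshold. Both
`map_raw` and `map_repaired` are exposed, since loopy marginals can violate
the TPG constraint even though exact marginals cannot: the exact posterior
satisfies $p(x_\text{parent}) \ge p(x_\text{child})$ on every edge
(property-tested on 1000 random instances), so thresholding exact marginals
is automatically consistent, but the loopy approximation carries no such
guarantee and the repaired labels are the default public output.

## The TPR-DAG baseline

`tpr_dag_predict()` implements the leveraging heuristic used for comparison:
compute each term's maximum distance to the root, then from the deepest terms
upward replace each term's value by the mean of its own flat probability and
the consensus values of children at or above the 0.5 threshold, then from the
root downward force each term down to its weakest parent. Terms are processed
once, in decreasing-depth order with identifier tie-breaks, which makes runs
bit-reproducible; the per-level updates are order-independent given the level
discipline. The thresholded output is always consistent.

## Evaluation

`hierarchical_prf()` computes ancestor-based hierarchical precision/recall/F
over closed label sets with the root excluded: per sample
$HP = |P \cap T| / |P|$, $HR = |P \cap T| / |T|$ (an empty prediction scores
precision 1 against an empty truth set and 0 otherwise, and symmetrically for
recall), HF the per-sample harmonic mean, all macro-averaged. This is the
ancestor-based member of the hierarchical P/R family; reports label it as
such. `cross_validate()` runs the k-fold protocol with rarest-first
stratification so deep terms stay in every training split when possible;
within each fold, channel variances are estimated from the training
positives' margins and Platt calibration is fitted on training margins.
`ranksum_compare()` applies the two-sided Wilcoxon rank-sum test (exact for
combined $n \le 20$ without ties) and declares a winner only below the 0.01
level. `prune_predicted_graph()` iteratively removes predicted leaves with
marginals under 0.95, re-testing parents that removal exposes, to shortlist
high-confidence annotations for uncharacterised proteins.

## What the synthetic generator emulates — and what it does not

`random_godag()` draws layered rooted DAGs (each non-root term picks 1 to
`max_parents` parents from strictly shallower levels, guaranteeing
acyclicity and root-reachability); `sample_annotations()` makes each term
positive with probability $\theta$ when all parents are positive, so every
generated row is ancestor-closed and model-matched; `corrupt_scores()` adds
$N(0, \eta)$ noise to $\pm 1$ signals. Defaults used by the end-to-end
recovery test — 30 terms, 5 levels, $\theta = 0.8$, $\eta = 0.25$,
$n = 500$ — put the margin-to-noise ratio in the regime of a robust training
policy with well-trained classifiers (observed base-classifier variances on
real data sit around 0.27–0.41).

The generator is deliberately model-matched: its conditional is AND over
parents, exactly the support of the logical factors, and its noise is exactly
Gaussian. Passing tests therefore demonstrate correct inference and parameter
recovery under the model's own assumptions; they do not show robustness to
real-data features such as non-Gaussian or skewed classifier scores,
class-dependent noise asymmetry, annotation incompleteness (missing true
positives in curated data), or correlated errors across related terms. Real
protein feature vectors are also not simulated — scores are generated
directly at the channel level.

## Problem sizes

The test suite and the worked examples run on graphs of up to 30 terms with
up to 500 samples, where loopy BP typically converges in well under ten
flooding iterations; the exact enumeration oracle is capped at 20 terms by
design. The matrix interface `fgga_annotate_matrix()` propagates messages for
all samples simultaneously and is the intended entry point for genome-scale
runs.

## Known limitations

Only `is_a` edges are modelled; `part_of`/`regulates` are dropped at parse
time. Variances are per-term, not per-sample. Loopy BP carries no general
convergence guarantee — non-convergence at `i_max` returns the last marginals
with `converged = FALSE`, and damping is available when diamonds oscillate.
The exact oracle's monotonicity guarantee applies to exact marginals only.
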