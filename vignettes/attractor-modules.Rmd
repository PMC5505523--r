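---
title: "Finding attractor modules in condition-specific interaction networks"
author: "attracmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding attractor modules in condition-specific interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attracmod)
```

## The problem

Case/control expression studies are usually analysed gene by gene, but many
disease processes act through *modules*: groups of interacting proteins
whose expression is coordinated. `attracmod` implements a module-centric
analysis for a two-phenotype design (for example tumour versus adjacent
normal tissue): it carves condition-specific co-expression modules out of a
protein–protein interaction (PPI) network and then asks, per module,
whether its genes' expression separates the two phenotypes more strongly
than the background gene population. Modules that do are called
**attractor modules**.

The pipeline has five stages, each exposed as an exported function and
composed by `attracmod()`:

1. **Base network** (`build_base_network`). Interactions come as a scored
   edge list (STRING-style `gene_a`, `gene_b`, `combined_score` in
   $[0,1]$). Edges with score $\ge 0.8$ whose both endpoints are profiled
   in the expression data are kept.
2. **Re-weighting and edge filtering** (`reweight_network`,
   `significance_filter`). Within each condition, every edge $(a,b)$ is
   re-weighted by $K(a,b) = |r_{ab}|$, the absolute Pearson correlation of
   the two genes' expression across that condition's samples. The
   correlation is tested with the one-sided t transform
   $t = |r|\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ degrees of freedom, and only
   edges with $p < 0.05$ enter the condition's *destination network*. The
   two conditions are filtered independently, each producing its own
   destination network, which is what yields differing case and control
   edge counts on real data.
3. **Modules** (`maximal_cliques`, `wid`, `interconnectivity`,
   `merge_cliques`). Maximal cliques with 4–20 nodes are enumerated
   (pivoted Bron–Kerbosch via igraph). Each clique $K$ is scored by its
   weighted interaction density
   $\mathrm{WID}(K) = \sum_{a \ne b \in K} K(a,b) / (|K|(|K|-1))$, the
   mean edge weight. Overlapping cliques are merged when their weighted
   inter-connectivity reaches 0.5, agglomerating to a fixed point;
   a module's genes are the union of its member cliques.
4. **Pairing** (`jaccard`, `pair_modules`). Case modules are matched to
   control modules by Jaccard similarity of gene composition
   ($J \ge 0.7$); both members must have at least 5 genes. Matching is
   one-to-one and greedy in decreasing $J$.
5. **GSEA-ANOVA attractor statistic** (`gene_f_statistics`,
   `attract_test`, `bh_adjust`, `call_attractors`). Every gene gets a
   one-way ANOVA F-statistic across the two phenotypes. For a module pair
   with gene set $A$ (union of its two modules) and background $V$ (all
   other genes with a finite F), the Welch statistic
   $$T_M = \frac{\bar F_A - \bar F_V}{\sqrt{S_A^2/A + S_V^2/V}}$$
   is referred to a t distribution with Welch–Satterthwaite degrees of
   freedom. P-values are Benjamini–Hochberg adjusted **across the module
   pairs** (not across genes), and pairs with adjusted $p < 0.05$ are the
   attractor modules.

## Tunable parameters

| argument | default | meaning |
|---|---|---|
| `score_threshold` | 0.8 | minimum interaction confidence (inclusive) |
| `edge_alpha` | 0.05 | per-edge correlation p cut (strict) |
| `clique_min`, `clique_max` | 4, 20 | clique-size window |
| `merge_threshold` | 0.5 | minimum inter-connectivity to merge cliques |
| `interconnect` | `"geometric"` | inter-score convention (see below) |
| `jaccard_threshold` | 0.7 | minimum gene-composition similarity of a pair |
| `min_module_size` | 5 | minimum genes on both sides of a pair |
| `attract_alpha` | 0.05 | FDR threshold for attractor calls |
| `tail` | `"two"` | sidedness of the module Welch test |

All thresholds are on dimensionless quantities (confidences, correlations,
probabilities, gene counts); expression values are assumed normalized,
log-scale intensities, but every statistic used (correlation, F, Welch t)
is location/scale-free per gene.

## Design choices

Several points of the procedure admit more than one reading; the package
fixes them as follows.

* **Inter-connectivity scale.** With non-overlapping parts $K_1 - K_2$ and
  $K_2 - K_1$, the cross densities
  $m_1 = \sum_{a \in K_1-K_2}\sum_{b \in K_2} K(a,b)/(|K_1-K_2||K_2|)$ and
  $m_2$ (symmetric) are combined as $\sqrt{m_1 m_2}$ by default. A bare
  product of two mean edge weights in $[0,1]$ almost never reaches a 0.5
  merge threshold, so the geometric mean — which keeps the statistic on
  the same scale as the edge weights and reduces to $w$ when every cross
  pair has weight $w$ — is the default; `interconnect = "product"` gives
  the literal product. Cliques nested under the set difference convention
  (either difference empty) get inter-score 1 and always merge. Missing
  cross edges contribute weight 0: the sums run over all gene pairs, not
  only network edges.
* **Merge semantics.** Agglomeration runs to a fixed point, which equals
  the connected components of the "inter-score $\ge$ threshold" relation
  on cliques; the result is therefore independent of processing order
  (verified empirically in the suite), and modules come out few and
  large rather than pairwise-merged fragments.
* **Residual mean square.** The per-gene F uses the standard one-way ANOVA
  decomposition: between-group mean square
  $\mathrm{MSS} = \frac{1}{G-1}\sum_g p_g(\bar y_{\cdot g} - \bar
  y_{\cdot\cdot})^2$ over residual mean square
  $\mathrm{RSS} = \frac{1}{S-G}\sum_g\sum_r (y_{rg}-\bar y_{\cdot g})^2$.
  With two balanced groups this makes $F$ exactly the squared
  pooled-variance t statistic, the identity the suite asserts at 1e-10.
  The grand mean is the unweighted mean of the group means; for a
  balanced design it coincides with the pooled mean, and the behaviour is
  documented (not re-weighted) for unbalanced input.
* **Module gene set and background.** The tested set of a pair is the
  union of its case and control modules' genes (at $J \ge 0.7$ the two
  nearly coincide); the background is every gene with a computed finite F
  outside that set, which keeps the reference population reproducible
  without an external annotation resource.
* **Sidedness.** The module test is two-sided by default: a module whose
  genes are *less* phenotype-discriminating than background is also a
  deviation worth flagging; `tail = "greater"` restricts to enrichment.
* **Boundary conventions.** Score $\ge$ threshold retains; p $<$ alpha
  retains. Zero-variance genes get edge weight 0 and p 1 instead of NA so
  graph code never sees missing weights. Ties anywhere are broken by
  (score descending, lexicographically smallest gene id), making every
  stage deterministic.

## The synthetic generator

`simulate_ppi_expression()` emulates the statistical structure the
pipeline assumes, not microarray physics. Planted modules are complete
subgraphs at score 0.95 inside a background Erdős–Rényi edge list with
uniform scores; module genes follow the equicorrelated factor construction
$y_i = \sqrt{\rho}\,z_m + \sqrt{1-\rho}\,\varepsilon_i$ (one factor
$z_m$ per sample), giving exact target pairwise correlation in
expectation; attractor modules additionally receive a case-condition mean
shift in units of the expression SD. Background genes are independent
noise, so their F-statistics are null $F(1, S-2)$ — a distributional
check in the suite. Defaults mirror the motivating study design: 18 + 18
samples and 6-gene modules, with correlation 0.9 (case) versus 0.3
(control) and a 1-sd shift.

What the generator does **not** emulate: probe-level noise, batch
effects, unbalanced designs, scale-dependent variance, many-to-one
protein–gene mapping, or realistic degree distributions. Passing tests on
synthetic data therefore validate the algorithmic contract, not
performance on any particular real platform.

The packaged demonstration configuration (used by the examples and the
acceptance script) sets `rho_control = 0.8` instead of 0.3, with the
differential signal carried by the mean shift: under per-condition edge
filtering a module whose control-condition correlation is only 0.3 rarely
survives into the control destination network at $n = 18$ (each of its
edges passes the filter with probability about one third), so a
recoverable demonstration needs modules that stay co-expressed in both
conditions while differing in phenotype response — biologically, a
module that keeps its wiring but changes its activity level.

## Known limitations

* **Inter-gene correlation inflates the module test.** The Welch
  statistic treats module genes' F values as independent, but
  co-expressed genes share their random between-group mean difference
  (in the factor construction, the group-mean difference of $z_m$ is
  common to the whole module), so under a no-effect null the module mean
  F is far more variable than $S_A^2/A$ suggests and the test rejects
  well above its nominal level. The suite's calibration check runs 200
  null studies and measures this directly; it fails by a wide margin,
  and that failure is a property of the independence-assuming GSEA-ANOVA
  statistic itself, shared with other such gene-set tests (the reason
  methods like camera estimate inter-gene correlation explicitly).
  Attractor p-values should therefore be read as a ranking device, not
  as calibrated error rates.
* **Weakly co-expressed modules are invisible.** Per-condition edge
  filtering at $n = 18$ needs $|r| \gtrsim 0.4$; modules with true
  within-condition correlation near 0.3 fragment before clique mining,
  so a case/control correlation *contrast* of 0.9 versus 0.3 is detected
  essentially never — the corresponding recovery check in the suite
  documents this. Larger sample sizes or a joint (both-condition) edge
  filter would be required.
* Clique enumeration is exact, hence exponential in the worst case; it is
  intended for desk-scale destination networks (thousands of nodes after
  significance filtering), not dense graphs.
* With two conditions the per-gene ANOVA is exactly a two-sample test;
  the implementation fixes $G = 2$ and does not generalize to more
  phenotypes.

## Problem sizes in the validation suite

The suite exercises the pipeline at deliberately small scale: random
graphs of up to 14 nodes against an exhaustive subset-enumeration clique
oracle (200 graphs), 1,000 genes for the $F = t^2$ identity and the
Benjamini–Hochberg oracle, 200 simulated null studies of 150 genes for
calibration, and 20 seeded studies of 200 genes for planted-module
recovery. These sizes make every oracle exactly computable while keeping
the default test run fast.
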