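---
title: "Prioritizing disease genes with a weighted hypergraph of annotated gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing disease genes with a weighted hypergraph of annotated gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperprio)
```

## The model

Annotated gene sets — pathways, biological-process terms, phenotype terms —
group genes by shared function, and disease genes concentrate inside a
subset of them. A pairwise network discards exactly this group structure:
a pathway of 30 genes becomes 435 indistinguishable edges. `hyperprio`
keeps the group as a single object by building a hypergraph in which the
$n$ universe genes are nodes and the $m$ sets are hyperedges, encoded in
the binary incidence matrix $H \in \{0,1\}^{n\times m}$.

**Disease-specific hyperedge weighting.** Not all sets are equally
informative about one disease. Given the known disease genes $V_d$, each
hyperedge receives the weight

$$ w_e \;=\; \frac{|\,\mathrm{members}(e) \cap V_d\,|}{|\,\mathrm{members}(e)\,|}, $$

the fraction of its members already known to be disease genes. A set with
no known disease gene gets weight 0 and is kept: it then contributes
nothing to propagation, which is the faithful reading of the weighting
rule (no pseudocount smoothing). During any benchmark the weights are
recomputed per fold from the training positives only; `cross_validate()`
enforces this, and a dedicated test plants a hyperedge whose only positive
gene sits in the test fold and asserts its weight is exactly 0 there.

**Residual hypergraph convolution.** With node degrees
$d(v)=\sum_e w_e H(v,e)$, edge degrees $\delta(e)=\sum_v H(v,e)$ and their
diagonal matrices $D_v, D_e$, one layer computes

$$ X^{(l+1)} = \sigma\!\left( D_v^{-1/2} H W D_e^{-1} H^{\top} D_v^{-1/2}
   \, X^{(l)} \Theta^{(l)} + X^{(l)} \right). $$

The normalized operator is two-stage message passing — genes send their
features to the sets they belong to, sets average and send back — and the
added $X^{(l)}$ is an identity skip connection. Its purpose is
anti-oversmoothing: where multi-hop neighbourhood information does not
help, training can drive $\Theta^{(l)} \to 0$ and the layer becomes an
identity map, so stacking layers cannot collapse gene representations.
With ReLU and nonnegative input this identity-map limit is exact, and the
test suite asserts it bit-for-bit.

**Head and training.** Initial features are the $n \times n$ identity, so
the first fully connected layer is a per-gene embedding lookup; the model
therefore uses only the gene-set structure, no external per-gene features.
After the input transform, dropout, and three residual layers, a softmax
head $Z = \mathrm{softmax}(X\Theta + b)$ yields two-class probabilities;
column 2 is the risk score. Training is transductive and full batch:
every gene is scored, but only labeled genes (positives and curated
negatives) enter the cross-entropy loss, optimized with ADAM.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hidden_dim` | 128 | width of the embedding and residual layers |
| `n_residual_layers` | 3 | depth of the convolution stack |
| `learning_rate` | 0.005 | ADAM step size |
| `epochs` | 300 | full-batch epochs; convergence is typically well before this |
| `activation` | relu | relu makes the identity-map limit exact; elu available |
| `dropout` | 0.5 | applied after the input transform, training mode only |
| `class_weighting` | none | optional inverse-frequency loss weights for imbalanced labels |
| `min_size` filter | 2 | singleton sets carry no gene–gene association and are dropped |

Learning rate, epoch count, layer count and the two-fully-connected-layer
architecture follow the published training protocol for this model
family; width, dropout and activation are standard graph-network practice
and fully exposed. Sets directly annotated with the disease of interest
should be removed before fitting (`exclude_patterns` of
`filter_gene_sets()`), since they encode the labels and make evaluation
circular; the pattern list is user-supplied because no fixed vocabulary
fits every collection.

## Numerical choices

* **Degenerate degrees.** Genes with zero weighted degree (members only of
  zero-weight sets) use the pseudo-inverse convention $0^{-1/2} := 0$:
  their operator rows are zero, they receive no propagated signal, and
  they keep their transformed self-features through the skip connection.
  They are flagged in the operator's `isolated` mask rather than patched
  with an $\varepsilon$.
* **Exact factorized propagation.** The operator is assembled as
  $A = BB^{\top}$ with $B = D_v^{-1/2} H (W D_e^{-1})^{1/2}$, and training
  applies $A$ through $B$ (genes→sets→genes). This is algebraically the
  same product, exactly symmetric by construction, and roughly an order of
  magnitude faster than materializing the $n \times n$ matrix; the tests
  verify sparse-vs-dense agreement to $10^{-6}$ and better.
* **Two engines, one RNG stream.** The training loop exists twice: a
  compiled core (RcppArmadillo) used by default and a pure-R reference
  implementation. Both draw Glorot initialization and dropout masks from
  the same seeded R RNG stream, and a test asserts their loss traces and
  parameters agree to machine precision — the compiled path is therefore
  verified against readable R code rather than trusted.
* **Ties.** AUROC uses the rank (Mann–Whitney) formulation with half
  credit for ties. AUPRC is average precision without interpolation; a
  tie block contributes its block-averaged precision, so an all-tied
  ranking scores exactly the prevalence. Ranked output breaks score ties
  by universe index, and the universe is ordered by first occurrence
  across the input collections, so every index and ranking is
  reproducible.
* **Fisher enrichment** computes the one-sided p-value directly as the
  hypergeometric upper tail and reports the sample odds ratio $ad/bc$
  (`Inf` allowed, `NaN` for 0/0); `fisher.test` is used in the tests as an
  independent cross-check of the p-value only, since it reports the
  conditional-MLE odds ratio.
* **Decile enrichment** splits a ranking into 10 contiguous blocks, the
  remainder genes (when $n \bmod 10 \neq 0$) assigned one per decile from
  the top, and adjusts the 10 hypergeometric p-values with
  Benjamini–Hochberg.
* **Permutation test** p-values use the add-one estimator
  $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{\mathrm{perm}})$, which
  is never zero and is calibrated under the null (verified by
  simulation). Null sets are drawn uniformly from the network's nodes
  excluding the reference set; degree-preserving draws are deliberately
  not the default, matching the plain "randomly selected genes" null.

## The synthetic benchmark

Because the real inputs are large curated databases, every stage is
testable against a generated benchmark with planted structure
(`generate_fixture()`): 1000 genes of which 100 are positives and 300
negatives, 40 "disease" sets drawing 60% of members from the positives,
160 background sets drawing them at the 10% prevalence rate, set sizes
uniform on 10–50. These defaults are the package's study conditions: the
signal strength (0.6 vs 0.1) mirrors the premise that disease genes
concentrate in a minority of sets, and the sizes keep a full repeated-CV
benchmark to a few minutes on one CPU. A matched null generator sets the
disease-set rate equal to the background rate, and CV on it stays at
chance (mean AUROC within [0.4, 0.6]) — the pipeline finds signal only
where signal was planted. Gene symbols are `G000000`-style so a fixture
can never be confused with a real gene list.

What the fixture does *not* emulate: realistic set-size and overlap
distributions (real collections are heavy-tailed and nested), gene-degree
heterogeneity, correlated set membership, label noise in the curated
negatives, and literature bias in the catalogues used for external
validation. Passing the planted benchmark shows the machinery recovers a
known membership signal; it does not certify real-data performance.

The independent-test protocol in `scripts/acceptance.R` holds out 20% of
the positives, trains without them, and evaluates where they fall in the
ranking — `independent_test_auprc()` treats them as the only true
positives among all non-training genes, so its values are far below
within-CV AUPRC by construction (prevalence ~2%).

## Design choices on open ground

* **Gene identity** is uppercase-symbol string equality; no alias
  resolution, keeping the package dataset-agnostic.
* **Negatives** are required as an explicit curated list; unlabeled genes
  are scored but never enter the loss or the CV metrics.
* **No early stopping by default** (fixed 300 epochs); a patience option
  exists but defaults off, so runs are comparable and deterministic.
* **Class imbalance**: an optional balanced loss weighting exists and
  defaults off.
* **Repeated CV** defaults to 5 repeats with seeds 0–4, reported as mean
  with a normal-theory 95% CI.

## Limitations

Scores are transductive: adding a gene or a set requires refitting. The
method uses no per-gene molecular features; integrating them is possible
(replace the identity features) but out of scope here. Hyperedge weights
are in-sample statistics of the training labels; very small sets can get
extreme weights (a 2-member set with one positive gets 0.5), a known
trade-off of the unsmoothed weighting rule. And on real collections the
exclusion of disease-annotated sets is pattern-based, so an incomplete
pattern list leaves circularity in place — that responsibility stays with
the analyst.
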