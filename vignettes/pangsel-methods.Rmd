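---
title: "Stability-based selection of discriminative gene families: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-based selection of discriminative gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A pangenome analysis of a bacterial genome collection yields a sparse binary
matrix: one row per genome, one column per gene family (homologous genes
clustered at fixed identity/coverage thresholds), cells recording presence or
absence. When the genomes carry a two-level group label — for instance, taxa
frequently investigated as probiotics versus reference gut commensals —
a natural question is which gene families discriminate the groups.
`pangsel` extracts such families with three complementary supervised
learners, combines their selections into a consensus, quantifies how well
the matrix separates the groups, and summarises the functional (COG) makeup
of the selected families. A synthetic pangenome generator with planted
ground truth makes every stage testable end to end without any external
data.

The selected families are discriminative variables, not causal determinants:
they reflect taxonomic and ecological structure in the genome collection as
much as any biology of the phenotype behind the labels.

## The three selection routes

All three learners consume the raw 0/1 matrix (genomes × families) and a
two-level label.

**Logistic regression (`lr`).** One L2-penalised logistic regression is
fitted to the full matrix by L-BFGS with a hard cap of 300 solver
iterations; hitting the cap keeps the current coefficients and warns. Each
family's *contribution share* is |coefficient| divided by the sum of
|coefficients|. Retention applies a 0.3% share threshold under one of two
readings:

* `individual_share` (default): keep every family whose own share exceeds
  0.003. Shares sum to one, so at most ⌊1/0.003⌋ = 333 families can ever
  qualify.
* `cumulative_prefix`: rank families by |coefficient| and keep the shortest
  prefix whose summed share exceeds 0.003 — typically very few families.

The two readings differ by orders of magnitude in how many families they
retain; because a "cumulative contribution exceeds 0.3%" rule is ambiguous
between them, both are implemented and the choice is recorded in the
configuration echo of every result.

**Random forest (`rf`) and linear SVM (`svm`): stability selection.** These
two methods refit their model on `external_iterations = 100` stratified
random subsamples of 90% of the genomes. Within each refit a per-iteration
rule nominates families:

* `rf`: 100 trees per refit, Gini impurity; a family is nominated when its
  impurity-reduction importance strictly exceeds the refit's mean importance
  (a share of the forest's total importance above 1/p). Bare positivity is
  not usable here: a forest spreads small positive importances over hundreds
  of uninformative families per refit, and because consecutive 90%
  subsamples overlap heavily, the same lucky families recur and would pass
  any appearance threshold.
* `svm`: a linear hinge-loss SVM trained by stochastic gradient descent
  with an L2 penalty; a family is nominated when its |weight| lies more than
  3 standard deviations above the mean of the refit's |weight| distribution.
  L2-penalised linear weights are dense, so a distributional cutoff is
  needed where the forest importance is naturally sparse.

A family is *retained* when it was nominated in at least
`appearance_threshold = 40%` of the external iterations (inclusive
comparison: 40 of 100 qualifies, 39 does not).

### The permutation signal gate

Stability selection as described above has a failure mode on group labels
that carry no signal. A fixed random labeling of a wide matrix (p ≫ n)
exhibits *persistent* chance associations — of 2,550 families, a handful
correlate with any fixed labeling at |r| ≈ 0.25 — and since 90% subsamples
share most of their genomes, those same families stay on top of every
refit's importance ranking. Measured on label-permuted data, the plain
z-score rule retains 18–34 chance families; no within-fit cutoff can help,
because the ranking itself is stable.

Each external iteration therefore also refits the model on
`null_gate_permutations = 3` label-permuted copies of the same subsample
and compares signal strength:

* `rf`: the maximum Gini importance. A permuted forest can only exploit
  chance splits, so its maximum importance estimates the chance-importance
  scale. The real refit must beat the strongest permuted refit by a factor
  of `null_gate_factor = 2`, otherwise the iteration nominates nothing; in
  addition, nominated families must individually exceed the permuted
  maximum.
* `svm`: the inverse mean |weight|. Hinge fits to label noise in a wide
  binary matrix need much larger weights to reach the same margins, so the
  overall weight scale (not any single weight, whose scale is confounded
  across fits) separates signal from noise fits. The factor-2 comparison is
  applied to the inverse scale; no per-family cap is applied, because
  weight magnitudes are not comparable across fits.

With the gate, label-permuted runs retain zero families in 10/10 replicates
while the planted-marker scenario below is unaffected (gate ratios 3–7
versus ~1 under permutation). The gate is a per-iteration permutation test
and can be switched off (`null_gate_permutations = 0`). One consequence to
know about: when random labels are linearly separable at low weight norm —
very small n against large p — the SVM gate deliberately refuses to nominate,
because in that regime the weight scale genuinely carries no evidence of
signal.

## Model implementations and numerics

* The logistic objective is `0.5·||w||² + Σ log(1 + exp(−margin))` with an
  unpenalised intercept, minimised by `optim(method = "L-BFGS-B")` over a
  fused C++ objective/gradient. Cross-validation refits warm-start from the
  full-training optimum, which shortens the optimisation path without
  changing the optimum.
* The SVM is trained with the Pegasos-style schedule η_t = 1/(α(t₀+t)) with
  t₀ = 1/(α·√(1/√α)), which keeps early steps at a typical-weight scale
  (the unshifted 1/(αt) schedule starts with steps of size 1/α and at small
  sample sizes never recovers). Iterates from the second half of the
  updates are tail-averaged. Defaults α = 1e-2 and 80 epochs were chosen so
  that on a perfectly separable matrix of the scenario size the fit is
  reliably exact; α is a free parameter here because only "SGD with an L2
  penalty" is prescribed by the pipeline this package implements.
* The random forest is `ranger` with 100 trees, impurity importance, one
  thread, and an explicit seed, making every refit reproducible.
* ROC AUC uses the model's continuous score (class probability for lr/rf,
  margin for svm) via `pROC`; hard labels would collapse AUC to balanced
  accuracy. F1 takes the second label level (alphabetically later group) as
  positive.
* Ties and degenerate inputs: all-zero importances nominate nothing; a
  zero-spread |weight| distribution nominates nothing; k-means tie-breaks
  go to the smallest k; dedup representatives are the lexicographically
  smallest family ID in the C locale.

## Consensus and annotation stages

`build_consensus()` computes all seven Venn regions of the three retained
sets by set algebra over the shared family universe and deduplicates the
union. Deduplication is exact protein-sequence identity (when sequences are
supplied): the input families are already cluster representatives built at
80%/80% identity/coverage, so a second similarity clustering would be
redundant; without sequences the union is already non-redundant by ID.

`cog_distribution()` tallies COG category letters over eggNOG-mapper
annotation records parsed at a maximum e-value of 6e-5 (records at exactly
the threshold are kept — a *maximum* threshold reads as inclusive). A record
annotated "JL" contributes ½ to J and ½ to L, so percentages sum to 100 and
total mass equals the number of annotated records; a whole-count mode is
available since either convention appears in published COG summaries.

## Evaluation

`evaluate_method()` reports the average over 100 random stratified 90/10
partitions of: test ROC AUC, test F1, test accuracy, and 10-fold
cross-validated accuracy computed within the training portion. k = 10 is a
convention choice — the protocol this mirrors does not state k — and is
configurable. On a perfectly separable synthetic matrix every per-iteration
metric equals 1.0 exactly for all three methods, which is the package's
strongest self-check of the whole fit/score path.

## The synthetic pangenome generator

`generate_pangenome()` draws each cell from a Bernoulli distribution with a
family-role-specific presence probability and then inverts each cell
independently with probability `flip_noise`:

| role    | default count | presence probability           |
|---------|---------------|--------------------------------|
| core    | 500           | 0.99 in both groups            |
| marker  | 50            | `p_marker_a` / `p_marker_b`    |
| cloud   | 2000          | 0.10, group-independent        |

The default study scenario used by the acceptance checks is 100+100
genomes with marker probabilities 0.95/0.05 and 1% flip noise — strong but
imperfect markers over a realistic sparse background. The counts are
plumbing choices giving a matrix shape typical of a few-hundred-genome
pangenome at desk scale; real pangenomes from 10⁴ genomes have far more
families and, crucially, phylogenetic correlation between genomes, gene
linkage, and lineage-specific cloud structure that the generator does not
emulate (genomes are exchangeable within a group). Passing the planted-
marker recovery checks therefore demonstrates the machinery is correct, not
that real-data selections carry the same precision.

Family IDs encode their role (`marker_0003`) so tests can assert recovery
directly; `write_synthetic_pangenome()` exports the matrix under opaque
aliases plus a truth sidecar so the on-disk pipeline never sees the roles.
One global seed drives a single RNG stream; the same spec is bit-identical
across runs.

## Problem sizes used by the automated checks

The test suite and the acceptance script run entirely on synthetic data:
marker recovery and the permutation null at 200 × 2,550 with 100 (recovery)
or 20 (null) external iterations; evaluation at 100 partitions with 10-fold
CV; the null at 10 replicate label permutations with 10 partitions each.
These sizes keep a full run in the minutes range on a single core while
leaving all thresholds at their defaults.

## Known limitations

* Only two-group labels are supported; the consensus stage assumes exactly
  the three methods lr/svm/rf.
* The permutation gate triples the cost of an external iteration and is
  conservative for weak signals: families whose effect size is near the
  chance-association scale of the dataset will not be retained.
* LR retention under `individual_share` dilutes as the number of truly
  discriminative families grows (shares sum to one); for hundreds of real
  markers the `cumulative_prefix` reading or a lower threshold is more
  appropriate.
* The exploratory module (PCA, elbow, k-means) is deliberately descriptive
  and feeds nothing downstream.
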