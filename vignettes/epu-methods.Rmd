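---
title: "Ensemble positive-unlabeled learning for disease gene prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble positive-unlabeled learning for disease gene prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epulearn)
```

## The problem

Confirmed disease genes are scarce and hard-won; the genes *not* yet linked
to a disease are not clean negatives, because an unknown fraction of them
are simply undiscovered disease genes. Training an ordinary binary
classifier with "unknown" as "negative" therefore poisons the negative
class. Positive-unlabeled (PU) learning works from a positive set `P` and
an unlabeled set `U` only, and this package implements an ensemble PU
pipeline for disease gene prioritization built on two ideas:

1. **Multiple biological evidence layers.** Disease genes for a common
   phenotype tend to interact physically, co-express across tissues, and
   share function. The pipeline builds three gene similarity networks —
   protein–protein interaction (PPI), co-expression (GE) and Gene Ontology
   similarity (GO) — and propagates label information over each.
2. **Multiple learners.** Three weighted PU classifiers (k-nearest
   neighbour, naive Bayes, multi-level SVM) see the same weighted training
   data, and a learned linear combination of their outputs makes the final
   call.

## Stage 1: networks

**Co-expression.** Gene similarity is the Pearson correlation of
expression profiles across tissues. For each gene the top `k = 5` most
similar partners become edges (ties broken by ascending gene id); the
matrix is then symmetrized *by union*: an edge survives if it is in either
endpoint's top-k list. Union symmetrization is required because the random
walk consumes a symmetric weight matrix, while per-gene top-k lists are
inherently directed. Edge weights are the raw signed correlations; a gene
with a constant profile is defined to have similarity 0 to everything and
is flagged.

**GO similarity.** Genes are compared by Euclidean distance `Dis` on the
GO block of their feature vectors (below), converted to a weight
`w = 1 / (1 + Dis)`, which is 1 at distance 0, monotone decreasing, and
bounded in (0, 1]. The same top-5 / union-symmetrization rule applies.
Other bounded monotone transforms (e.g. `exp(-Dis)`) would serve equally;
`1/(1+Dis)` was chosen for having no extra scale parameter.

**PPI.** Binary symmetric adjacency; interaction data is already sparse,
so no sparsification is applied.

**Phenotype similarity filter.** Phenotype–phenotype similarities in
[0, 1] are passed through the logistic `L(s) = 1 / (1 + exp(c s + d))`
with `c = -15`, `d = log(9999)` (the parameterization established for
propagation-based prioritization on the van Driel similarity matrix), and
entries with `L(s) < 0.5` are zeroed. With these constants `L(0) = 1e-4`
and the retain threshold `L(s) >= 0.5` corresponds to `s >= ~0.61`, so
only confidently similar phenotype pairs survive. Both constants are
config keys (`network$logistic`).

## Stage 2: gene feature vectors

Each gene is a vector with five ordered blocks:

* **MF, BP, CC** — for each selected GO feature term, the maximum Wang
  semantic similarity between that term and any of the gene's annotated
  terms in the namespace (0 for unannotated genes). Wang similarity
  propagates per-term S-values up the DAG, discounted by 0.8 across
  `is_a` edges and 0.6 across `part_of` edges (the published constants of
  the measure), and compares two terms through their shared ancestors.
* **DOMAIN** — binary protein-domain indicators.
* **TOPO** — degree, mean neighbour degree, local clustering coefficient
  and an isolation flag on the PPI graph, min–max scaled to [0, 1] per
  column over the gene universe.

GO feature terms are selected per namespace by the absolute difference of
class means, `|mean_P val(g, t) - mean_U val(g, t)|`, keeping the top
`n_go_features` (default 1000; in the synthetic studies every candidate
term is kept because the generated ontologies are small). Selection uses
only training-fold genes, so held-out genes cannot influence the feature
space. All blocks are in [0, 1], which the naive Bayes model requires.

The **positive representative** `pr` is the *mean* of the positive genes'
feature vectors. A unit-normalized sum was the other candidate reading;
the mean was chosen because `pr` is compared with unnormalized gene
vectors through Euclidean distances, and a unit-norm vector would sit at a
different scale than the vectors it is compared against.

## Stage 3: seeding and propagation

* **Candidate positives (CP).** Genes of the known-disease universe
  (outside the query positives) whose phenotypes survive the logistic
  filter against the query phenotypes; their seed score is the maximal
  filtered similarity. Survival of the filter *is* the similarity
  threshold — no second cutoff is introduced. CP genes act only as
  propagation seeds: they never enter a classifier training pool, and the
  extraction excludes the full declared positive set and the current test
  fold so no held-out label can leak through a seed.
* **Reliable negatives (RN).** Unlabeled genes whose distance to `pr`
  strictly exceeds the unlabeled-set average. The strict inequality makes
  the all-equidistant edge case yield an empty RN rather than an arbitrary
  one.
* **Seed scores.** Positives get +1, CP genes their similarity score, and
  each RN gene `-(|P| + sum of CP scores) / |RN|`, so the seed vector sums
  to zero and positive and negative flow are balanced. Reading the
  balanced "positive mass" as `|P|` only (excluding CP) is available as
  `seed$balance_include_cp = FALSE`.

**Random walk with restart.** On each network,
`R_t = (1 - alpha) * W' R_(t-1) + alpha * R_0` with restart probability
`alpha = 0.7`, stopping when the L1 change drops below `1e-6` (cap 1000
iterations, flagged if hit; the cap is a safety net — the iteration is a
contraction for `alpha` in (0, 1]). `W'` is the row-normalized weight
matrix transposed, i.e. column-oriented, so each gene distributes its
out-flow across its neighbours. Because a probability flow with mixed
signs is ill-defined, co-expression networks propagate absolute
correlations (`network$use_abs_weights`, default on); top-k selection by
descending similarity has already removed most negative edges.

The three converged score vectors combine into one **integrated score**
per gene: the arithmetic mean, counting absence from a network as 0 and
always dividing by 3. Since every summand is one of three symmetric
network scores, a sum would only rescale the result; the mean keeps the
score on the seed scale. Dividing by the per-gene network count instead is
available (`propagation$mean_over_present`).

## Stage 4: the three PU base classifiers

All three emit a posterior pair `(p_pos, p_neg)` summing to 1.

**Weighted kNN (k = 3).** The k nearest training genes (Euclidean
distance on the feature matrix, ties by ascending id, self excluded) are
split by the sign of their integrated score (ties at zero side with the
positives, where they carry no mass anyway); `p_pos` is the positive
score mass over the total absolute mass, and an all-zero neighbourhood
returns (0.5, 0.5). The training pool is `P ∪ RN ∪ U'`, every member
carrying its converged score.

**Weighted naive Bayes.** Multinomial naive Bayes with fractional
confidence-weighted counts: the positive pool is `P` (weight 1) plus
positively-scored unlabeled genes (weighted by their score), the negative
pool `RN` (weight 1) plus negatively-scored unlabeled genes (weight
|score|). Feature likelihoods use Laplace smoothing `lambda = 1`; class
priors are fixed at 0.5; the posterior is computed in log space and
normalized through log-sum-exp. Being multinomial, the model responds to
feature *composition*, not overall magnitude — a deliberate match to the
nonnegative, bounded feature blocks.

**Multi-level SVM.** The remaining unlabeled genes `U'` are partitioned
by the class-conditional means of the integrated score: likely positives
`LP` (score at or above the mean positive score), likely negatives `LN`
(at or below the mean negative score), weak negatives `WN` (the rest).
The partition is invariant under positive rescaling of the scores. The
SVM trains on five strata — labels +1 for `P ∪ LP`, −1 for
`RN ∪ LN ∪ WN` — with per-stratum misclassification costs
`base_C × multiplier`, multipliers (P, RN) = 1, (LP, LN) = 0.5,
WN = 0.25, and `base_C` chosen from {0.1, 1, 10} by stratified 3-fold
internal cross-validation on F-measure. The solver is a primal
L2-regularized weighted squared-hinge SVM (linear kernel by default, RBF
available), optimized by BFGS with analytic gradients; the squared hinge
is smooth, the objective strictly convex in the weights, and per-sample
costs fall out of the formulation naturally — duplicating a point is
exactly equivalent to doubling its cost, and a zero-cost point drops out
of the fit, both of which are asserted in the test suite. Posteriors come
from a Platt-style sigmoid on the decision values, fitted with Platt's
smoothed targets so separable fits stay finite.

## Stage 5: the ensemble

For training gene *i* and model *j*, the margin
`m_ij = P_j(+|g_i) - P_j(-|g_i)` fills a |D| × 3 matrix. The ensemble
score is `s_i = sum_j a_j m_ij` and the final call is +1 when `s_i > 0`,
−1 otherwise — an exact zero maps to the non-disease class, the
conservative choice for prioritization.

The weights minimize `E = 1/2 sum_i (y_i - s_i)^2` by the batch delta
rule: `a_j += eta_t sum_i (y_i - s_i) m_ij`. A hard-threshold output
inside `E` would make the objective non-differentiable, so the gradient
uses the continuous score (the classical LMS treatment); the fitted
object additionally reports the hard-label training error. The learning
rate starts at `eta0 = 0.001` and decays as `eta_t = eta0 / (1 + t/100)`
— small enough that the recorded error history is non-increasing on
margin matrices of the sizes used here (hundreds of rows), which the test
suite asserts over random instances. Weights initialize uniformly on
[0, 1) under a mandatory seed, are not constrained to be nonnegative, and
are not renormalized after training (neither constraint changes the sign
of `s`, and leaving them free preserves the least-squares optimum).

## Evaluation protocol

For a query disease with positives `P`: draw 10 (default; 3 in the
bundled study) unlabeled groups `U` with `|U| = |P|` from the genes not
known to be disease-associated, each group seeded deterministically. Per
group, 3-fold stratified cross-validation: two folds train, one tests.
Within a training fold, soft labels for ensemble training come from
holding out each training gene (leave-one-out by default;
`eval$inner_folds = 5` trades a little fidelity for speed and is used in
the bundled study), refitting the three base models without it, and
recording its margins. Metrics treat unlabeled test genes as negatives;
reported values are the means of per-fold precision, recall and F over
all group × fold runs (macro averaging — which is why an averaged F need
not equal the harmonic mean of the averaged precision and recall). Every
fold asserts that no test gene appears among the positive seeds, CP, RN,
the unlabeled training pool, or the ensemble rows; a violation aborts the
run.

A genome-wide ranking is also produced: per group the full `P ∪ U` set
trains the pipeline, every gene outside `P` is scored by the ensemble,
and scores are averaged over groups.

## The synthetic study

The generator plants exactly the structure the method exploits, in a
600-gene universe with a 60-gene disease module (defaults):

* PPI: planted-partition graph, within-module edge probability 0.2,
  background 0.01;
* expression: 16 tissues; module genes share a latent tissue factor giving
  within-module Pearson correlation ≈ 0.7 (verified by Monte Carlo in the
  tests), background genes are independent noise;
* GO: three random DAG namespaces (depth 3, branching 3, ~10% extra
  `part_of` edges); module genes annotate from one clade under the root,
  background genes uniformly; 10% annotation noise;
* domains: module genes draw from a 6-domain pool, background from all 30;
* phenotypes: 100 phenotypes in 5 groups, within-group similarity
  U(0.7, 1), between-group U(0, 0.3) — so the logistic filter keeps
  exactly the within-group pairs; declared positives link to group-1
  phenotypes, and 100 decoy background genes link to the other groups
  (five of them also touch group 1, so candidate-positive extraction pulls
  in some genuinely wrong seeds).

Half of the module (`hidden_frac = 0.5`) is withheld from the positive
list. These *hidden positives* have no phenotype associations — they sit
in the unlabeled universe exactly like undiscovered disease genes, which
is the premise PU learning addresses — and they are the currency of the
evaluation: the signal-strength contract asserts that propagation alone
ranks them above background with AUC ≥ 0.8, and the full protocol checks
their enrichment in the top 20% of the genome-wide ranking.

What the generator does **not** emulate: real PPI degree distributions
(planted-partition graphs are much more homogeneous than HPRD-scale
interactomes), GO's true depth and shared-ancestor structure, expression
baselines and library-size effects, or incomplete/biased annotation.
Passing tests on this bundle demonstrate that the implementation recovers
planted structure of the kind the method assumes — not that the method
attains any particular accuracy on real OMIM-scale data.

## Problem sizes and numerics

The bundled study runs 3 unlabeled groups × 3 outer folds with 5 inner
folds on the 600-gene default bundle — sizes chosen so the whole protocol,
including the internal SVM cost search, completes in well under a minute
on one core while keeping ≥ 2000 genuinely unlabeled genes in the ranking
universe. Convergence tolerances: 1e-6 (L1) for the random walk, 1e-6
(L1 on the update) for the ensemble; the walk's iteration cap (1000) and
the ensemble's (10000) are flagged, not silent. Degenerate inputs have
defined behaviour throughout: zero-variance expression profiles (similarity
0, flagged), zero-degree network nodes (zero transition columns), empty RN
(warning, unbalanced seeds), all-zero kNN neighbourhoods ((0.5, 0.5)),
single-class SVM training (error), ensemble score ties (class −1). All
tie-breaks are descending score then ascending identifier, making every
stage deterministic given its seeds.

## Known limitations

* The co-expression network propagates absolute correlations; strong
  negative co-expression is treated as evidence of association, not
  dissociation.
* The multinomial naive Bayes is blind to uniform magnitude shifts across
  features by construction.
* Platt calibration on training decision values is optimistic for the
  SVM's probabilities; ranks are unaffected.
* With very small positive sets (< 3 per fold) the stratified internal
  cost search degenerates to a fixed mid-grid cost.
* The ensemble is a linear combiner; it cannot repair three base models
  that are all wrong in the same direction.
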