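---
title: "Methods: interpretable chemical grouping with chemgroup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interpretable chemical grouping with chemgroup}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chemical grouping organizes compounds into clusters of structurally or
mechanistically similar molecules. In toxicology it underpins
read-across (inferring a data-poor chemical's property from data-rich
analogs in the same group), screening prioritization, and
structure-activity analysis. `chemgroup` implements a complete,
scriptable grouping pipeline: structure input and curation, molecular
descriptors, dimensionality reduction, supervised feature selection,
silhouette-tuned clustering on 2-D projections, and SHAP-based
interpretation of the resulting groups — with every option, seed and
result captured in a replayable JSON manifest.

## Structure standardization

Descriptors are only comparable across a dataset if the structures are
drawn consistently, so standardization runs before any descriptor
calculation (on by default, switchable off in the configuration). The
rule chain is fixed, in order: largest-organic-fragment selection
(salt/counterion removal), charge neutralization where chemically valid
(balanced zwitterions such as nitro groups are preserved),
functional-group normalization of nitro groups to the charge-separated
form, canonical-tautomer selection, stereochemistry removal, a valence
check, and canonical SMILES generation. Exact duplicates are collapsed
to one record; when labels are present, duplicates with *conflicting*
labels are removed entirely — a deliberately conservative choice for
supervised runs, since either label could be the wrong one.

Tautomer canonicalization has no single universally agreed scheme. We
use the RDKit MolStandardize canonical tautomer and record the scheme
name and backend version in the manifest, because descriptor- and
bit-level counts downstream (e.g. how many fingerprint bits survive a
variance filter) can shift slightly with the scheme.

## Descriptors

Three binary fingerprints are available: Morgan (circular, default
radius 3, 2048 bits), FeatMorgan (the same circular construction with
pharmacophoric feature invariants instead of atom types), and MACCS
(the fixed 166 informative keys; the implementation's placeholder bit 0
is stripped). Two continuous 2-D sets are available: a pinned
119-descriptor *compact* set and the complete RDKit 2-D collection as
the *extended* set (~210 descriptors). Columns with any non-finite
value across the dataset are dropped and the drop list recorded; the
backend version is pinned in the manifest because descriptor counts are
version-sensitive.

Scaling offers min–max (to [0, 1]), z-score (mean 0, sd 1), and decimal
scaling (divide by the smallest power of ten bounding the column's
absolute maximum by 1). Constant columns map to zero under
min–max/z-score: they carry no information, the alternative is a
division by zero, and the variance filter removes them anyway. Binary
fingerprints are left unscaled by default; continuous descriptors
default to min–max *before* variance filtering, because a variance
grid expressed on a 0–0.1 scale is only meaningful when all columns
share a common range. Scaling parameters are stored with the matrix so
the identical transform can be replayed on new data.

## Dimensionality reduction and feature selection

The low-variance filter removes columns whose *population* variance is
at or below the threshold (so threshold 0 removes exactly the constant
columns). The correlation filter makes a greedy pass in column order,
removing the later column of any still-kept pair with |Pearson r|
above the threshold; the pass is order-dependent by construction, and
fixing "later column loses" makes it deterministic.

For labeled data an automated threshold search scores each grid value
by a supervised model (accuracy for classification, R² for
regression) on a stratified 80/20 holdout or 5-fold cross-validation,
and applies the best threshold to the full matrix with the entire
search trace kept. The default grid is 0 to 0.1 in steps of 0.01 for
both filters. For the correlation filter this published grid is almost
certainly too low in practice — |r| > 0.01 removes nearly everything —
so the grid is configurable and the documentation flags it; a
high-correlation grid such as `seq(0.8, 0.99, 0.01)` is the usual
choice.

Three wrapper selectors are implemented over cross-validated AUC
(classification) or R² (regression):

* **RFE** refits the learner each iteration, ranks columns by
  model-native importance (impurity for forests, gain for boosting,
  absolute coefficients for logistic regression, permutation importance
  for SVM/kNN/naive Bayes, which expose no native ranking) and drops
  the `max(1, floor(0.2 p))` least important; the best subset along the
  path wins. The ranking is refreshed every iteration.
* **GA** evolves bit-mask populations with tournament selection,
  uniform crossover (probability `crossover_proba`), per-bit mutation
  (`mutation_prob`), and elitist best-ever bookkeeping. Defaults
  (population 50, crossover 0.5, mutation 0.2, 40 generations,
  tournament 3) are conventional mid-size settings.
* **SA** starts from a random half of the columns, proposes one
  add/replace/remove move per iteration, always accepts improvements,
  accepts deteriorations with Metropolis probability
  `exp((s_new − s_cur)/T)`, cools geometrically by 0.95, and stops at
  50 iterations or T < 0.01. With the default T₀ = 1, 0.95⁵⁰ ≈ 0.077,
  so the iteration cap binds, never the floor. The Metropolis form is
  the standard choice where only "an acceptance probability" is
  specified.

## Grouping and tuning

Five clusterers are available: k-means, k-medoids (PAM; medoids are
dataset points), hierarchical (single/complete/average linkage over
euclidean or manhattan distances, cut to a requested cluster count so
k is tunable like the other algorithms), DBSCAN and HDBSCAN (both may
emit noise labels, coded −1). DBSCAN's ε is searched on the quantile
scale of the pairwise distances so a single range fits any embedding
scale. DBSCAN and HDBSCAN are implemented in the package (mutual
reachability, minimum spanning tree, condensed tree and
excess-of-mass extraction for HDBSCAN), as no R implementation is
available among the package's dependencies.

Quality is measured by the silhouette score: per point,
`(b − a)/max(a, b)` with `a` the mean intra-cluster distance (0 for
singletons, the standard convention) and `b` the smallest mean
distance to another cluster, averaged over points; euclidean metric;
noise points are excluded. Trials that produce fewer than two
clusters or more than 50% noise score −1 — without that rule a
degenerate trial that declares most points noise can post an inflated
silhouette.

Hyperparameters are tuned by a Tree-structured Parzen Estimator: after
a random start-up phase the trials are split into a good top fraction
and the rest, Parzen densities l(x) and g(x) are estimated per
dimension, and the candidate maximizing l/g is proposed. In *projected*
mode (the default) projection and clusterer parameters are sampled
jointly and the objective is the silhouette of the clustered 2-D
embedding. In non-projected mode the clusterer is tuned on the full
descriptor space first, then the projection is tuned with the clusterer
frozen, re-clustering each trial embedding; the returned labels come
from the best stage-2 embedding (the full-space labels are kept in the
result as well, since both readings of "final labels" are defensible
and a user may want either). Default ranges mirror the case-study
settings (k 2–25, min_dist 0.01–0.25, n_neighbors 2–50, 50 trials) and
are configurable. One master seed derives every per-trial seed
deterministically.

UMAP/t-SNE trials are embedded in batches through one Python helper
process per TPE proposal batch; within a batch the proposals come from
the same Parzen densities. This trades a little TPE adaptivity for a
large constant-factor saving on interpreter start-up and JIT
compilation.

## SHAP-based grouping and interpretation

For labeled data the package can group compounds by *endpoint-specific*
similarity: a learner is fitted on all rows (the use here is
explanatory, not predictive, so no holdout is taken), SHAP values are
computed per compound and descriptor, and the SHAP matrix replaces the
raw descriptors as tuning input. Binary tasks use the positive-class
attribution block; multiclass tasks concatenate per-class blocks
(n × p·C).

Gradient-boosted trees get exact tree-path attribution on the margin
scale — each row of SHAP values plus the base value reproduces the
model margin to numerical precision (the practical comparison floor is
the float32 precision of the reference margins, about 1e-7 per unit of
margin). All other families get permutation-sampling Shapley values of
the predicted probability/output against a fixed background sample:
per permutation the features are switched one at a time from a
background row to the explained row, and successive prediction
differences telescope into attributions that sum exactly to
`f(x) − mean f(background)`.

Cluster interpretation fits one multiclass classifier on the cluster
labels (noise excluded) and ranks each cluster's descriptors by mean
|SHAP| within that cluster's one-vs-rest block — fitting once and
attributing per class, rather than refitting per cluster, keeps the
attributions on a common scale. A deterministic template summarizer
turns the rankings into text (top descriptors, direction of
association, optional endpoint phrasing); an external summarizer (e.g.
a language model) can be injected behind the same signature and falls
back to the template when unavailable.

## Manifest and running modes

Every run writes a schema-versioned JSON manifest holding the input
descriptor, all options and hyperparameters, all seeds, and the stage
results (kept columns, selected features, tuned parameters, labels,
embedding, silhouette, interpretation). Three modes consume it: a new
analysis creates it; *rerun* applies all stored options and tuned
values to a new dataset with the stored seeds, skipping every search
stage; *view* re-renders the stored results with zero recomputation
(asserted in the tests via computation counters). The report bundle
(CSVs, SVG figures, Markdown summary, checksummed index) is rendered
from the manifest alone with fixed 6-significant-digit float
formatting, so re-rendering is byte-identical.

## Synthetic data and what the tests show

The generators cover the three data shapes the pipeline consumes:
Gaussian blobs with controllable center separation (recovery and
silhouette checks), labeled tables with 5 informative columns planted
among 45 noise columns at logistic effect size 2.0 and n = 500 (the
selector-recovery conditions), and scaffold-family SMILES sets built by
decorating ring cores with substituent templates (guaranteed-valid
structures with ~10% injected salts and duplicates). Test problem
sizes (n of a few hundred, fingerprints of 512–1024 bits, 6–20 tuning
trials in unit tests) were chosen to exercise every code path at
interactive speed.

These fixtures are idealized: blobs are spherical and equally sized,
planted signals are linear and independent, and scaffold families are
far more separated than a real screening library. Passing tests
therefore demonstrate correctness of the algorithms and determinism of
the pipeline, not that any particular real dataset will yield
well-separated groups. The published case-study numbers (2273-compound
eye irritation/corrosion dataset) are asserted in the acceptance tests,
which run only when that dataset's SDF is placed under `inst/extdata/`;
bit-level counts there are additionally sensitive to the tautomer
scheme and descriptor-backend version pinned in the manifest.

## Numerical and design choices

* Population variance (divide by n) in the variance filter and column
  statistics; removal at `<= threshold`.
* Ties in the automated threshold search go to the lowest threshold.
* Constant columns: moments reported as 0; scaling maps them to 0.
* Binary labels given as two strings map to 0/1 by sorted order, and
  the mapping is stored in the manifest.
* k-means uses 10 restarts under the trial seed; PAM is deterministic.
* PCA signs are fixed (largest-magnitude loading positive) so
  embeddings are reproducible across platforms.
* JSON manifests canonicalize integers to doubles and empty vectors to
  empty lists, making save/load a field-by-field identity.

## Known limitations

* The chemistry backend is an external Python/RDKit helper invoked per
  dataset batch; a missing interpreter fails fast with a clear error.
* HDBSCAN uses dense distance matrices (O(n²) memory), fine for
  datasets up to a few thousand compounds, not for hundreds of
  thousands.
* The extended descriptor set is the RDKit 2-D collection; descriptor
  families from other backends (e.g. 1600-descriptor sets) are out of
  scope, so column counts differ from workflows built on those
  backends.
* The sampling SHAP approximation has Monte-Carlo error; exact
  attribution is guaranteed only for gradient-boosted trees.
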