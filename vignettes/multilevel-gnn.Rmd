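---
title: "Multilevel graph neural networks for multi-omics survival-risk classification"
author: "mlgnn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel graph neural networks for multi-omics survival-risk classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlgnn)
```

## The problem

Tumor cohorts profiled on several omics layers — mRNA expression,
copy-number variation (CNV) and DNA methylation (MT) — are small (a few
hundred patients) and very wide (thousands of genes per layer). Classifying
patients into long-term survivors (LTS; survival beyond a cancer-specific
threshold, e.g. 2 years for glioblastoma) versus non-survivors from such
data invites overfitting unless strong biological structure constrains the
model. This package implements a hierarchical classifier that injects two
kinds of prior knowledge:

* a **gene regulatory network** (TF → target edges with importance scores,
  e.g. SCENIC output) that tells the model which genes inform each other,
  and
* **pathway membership** (KEGG-style GMT gene sets) that tells the model
  which genes act together, giving a natural intermediate representation.

The model has three levels, mirroring that structure.

## The model

### Guidance graph

All (gene, omics) pairs become typed nodes of one *guidance graph*.
Regulatory scores are normalized per TF into [0, 1] (default: division by
the TF's maximum score, which keeps every edge non-zero; min–max is
available because either reading is compatible with "normalized to the
range 0 to 1") and become mRNA–mRNA edge weights. For every gene shared
between layers, the CNV node links to its mRNA node with weight **+1** (copy
number tends to track expression) and the MT node with weight **−1**
(promoter methylation tends to repress expression). CNV and MT nodes are
never linked directly; mRNA is the bridge layer, which is why every omics
combination in the ablation harness must contain mRNA. Regulatory edges are
stored directed but message passing treats them as undirected: the encoder
aggregates neighborhoods symmetrically and nothing in the construction fixes
a direction convention.

### Gene encoding

Each node `v` has a trainable D-dimensional embedding `e_v` (D = 8 by
default). A sample enters the network as `s_v = x_v · e_v`, the embedding
scaled by that sample's value for the node — a node with value 0 contributes
nothing. Two rounds of GraphSAGE-style message passing follow: a signed
weighted mean of neighbor features (rows of the adjacency are normalized by
the *sum of absolute* incident weights, so methylation neighbors contribute
subtractively), concatenated with the self representation and passed
through a learned linear map with ReLU. Two layers give every node an
exactly 2-hop receptive field, which the tests assert on a path graph.

### Pathway aggregation

For every (pathway i, omics j) with at least one selected member gene, a
learnable matrix `W_p^{ij}` (M_dims × genes, M_dims = 2 by default)
contracts the gene axis of the *expression-reweighted* encodings
`x_v · z_v` — multiplying by the input a second time emphasizes aberrant
genes — into pathway features `PF_ij`, which two per-block fully connected
layers map to a D-dimensional pathway embedding `p_ij`.

`W_p^{ij}` is initialized to the PCA loading matrix of the block's training
submatrix, so at initialization the block performs the PCA compression and
training starts from a sensible linear summary. A cosine-independence
penalty keeps the rows of each `W_p` from collapsing onto one direction
during training: we use the sum of |cos| over unordered row pairs. (A bare
sum over all index pairs would include the constant diagonal and would
*reward* anti-parallel rows, contradicting the penalty's purpose, so the
absolute off-diagonal form is used deliberately.) Because PCA loadings are
orthonormal the penalty is exactly 0 at initialization — an invariant the
acceptance tests check. The total training loss is cross-entropy plus
`lambda_ind` (default 0.01) times the mean penalty over blocks.

### Prediction head

The pathway embeddings are arranged into a D × N × M tensor (N pathways, M
omics layers). Pathways are ordered by greedy Pearson-similarity chaining
computed on the initial PCA pathway features of the training samples: the
most similar pair takes positions 1–2, then the unused pathway most similar
to the last placed one is appended (ties break toward the smaller index).
This puts correlated pathways next to each other so that the following 2×2,
stride-2 max pooling over the (pathway × omics) plane summarizes related
features together. Pooling uses ceiling mode (partial windows kept):
with three omics layers, floor mode would silently discard the third
column, which would defeat the omics-combination analysis. The pooled
tensor is flattened, optionally concatenated with the training-fold
z-standardized age, and passed through two linear layers with a softmax
giving P(non-LTS) and P(LTS). The risk score used everywhere is P(non-LTS).

## Preprocessing

**Labels.** Patients surviving past the threshold are LTS regardless of
vital status; patients who died at or before it are non-LTS; censored
patients whose follow-up ends at or before the threshold cannot be labeled
either way and are excluded. Survival times are stored in days (the common
convention of public cohort tables) and converted with 365.25 d/y.

**Feature selection.** Within each training fold, each gene's mutual
information with the label is estimated with the k-nearest-neighbor
estimator for discrete/continuous pairs,
`MI = psi(N) − <psi(N_x)> + psi(k) − <psi(m)>`, where `N_x` is the size of
the point's class, the search radius is the distance to its k-th
same-class neighbor, and `m` counts all points within that radius,
excluding the query point (the estimator family leaves this convention
open; excluding the point is the one under which the disjoint-support
oracle returns exactly the label entropy). We use k = 3 and the Chebyshev
metric, which in one dimension is the absolute difference. Near-discrete
CNV values are jittered with uniform noise of amplitude 1e-10 to break
ties. Negative estimates are clipped to 0, and genes whose MI exceeds the
layer's mean MI are retained — a strict inequality, so a degenerate layer
with all-equal MI values fails loudly rather than keeping everything.

Everything fitted — MI selection, PCA initializers, the pathway order and
age standardization — is computed on training folds only. The fitting
functions record the sample ids they saw, and the cross-validation harness
asserts that these never intersect the held-out fold; an intentionally
leaky negative control in the test suite proves the assertion trips.

## Evaluation protocol

`crossValidate()` runs repeated stratified 5-fold cross-validation.
Within a repeat, the test scores of all five folds are pooled before one
AUC is computed (rank-based, midrank tie handling — exhaustive
pair-counting is the test oracle), and the mean ± sd over repeats is
reported. Stratification is used because realistic cohorts are imbalanced
enough that unstratified folds risk losing a class. The reference protocol
is 30 repeats; the package default is 5 so that the bundled synthetic
experiments run in minutes on one CPU.

Training uses Adam (lr 1e-3; optional decoupled weight decay), mini-batches
of 32 samples, at most 30 epochs, and early stopping (patience 5) on a
stratified 15% validation
split carved from the training fold; the best-validation parameters are
restored. A master seed fans out deterministically to fold assignment,
parameter initialization, batching and the CNV jitter, making entire runs
bit-reproducible.

## Interpretation

**Gene level (node masks).** With the model frozen, a raw mask vector over
graph nodes is optimized (Adam on the raw mask; plain fixed-step gradient
descent stalls once sigmoids saturate) to minimize
`alpha·NLL(predicted class) + beta·||sigma(M)||_1 + gamma·sum H(sigma(M))`
with the sigmoid mask multiplying the node inputs. Two signs in this
objective are implemented opposite to a literal reading of the lineage
formula: the prediction term must be a *negative* log-likelihood (otherwise
optimization destroys the prediction it is meant to preserve), and the
entropy term must be a *penalty* (otherwise it rewards the uninformative
mask 0.5). Defaults are alpha = 1, beta = 0.005, gamma = 0.1, 300 steps,
lr 0.01, masks initialized at sigma = 0.5. Mask values are z-scored across
genes within each omics per sample, averaged over samples, and ranked; a
mean split over samples of a gene's importance yields groups for external
survival analysis.

**Pathway level (Integrated Gradients).** The attributed function is the
non-LTS logit viewed as a function of the compressed pathway features `PF`
(the output of the `W_p` contraction, before the block FC layers; the
alternative attribution point after the FC layers is a one-line change but
the pre-FC features are the direct output of the "compression matrix").
The baseline is the all-zero feature vector (configurable to training-mean
features). The path integral is discretized by a midpoint rule with 128
points by default. Because the network after `PF` is piecewise linear, the
path gradient is piecewise constant, and a plain midpoint rule leaves a
completeness gap of order 1e-3; `pathwayIG()` therefore refines any
interval whose adjacent midpoint gradients differ (which pinpoints a
ReLU/max-pool boundary crossing) on a 16× finer midpoint grid, driving the
gap to ~1e-4 or below. Screening runs over many models can disable the
refinement; pathway rankings are unaffected.

Per (pathway, omics, sample) the importance is the mean |IG| over the
block's feature dimensions; per (pathway, omics) the median over samples is
z-scored within the omics across pathways, and **z > 1.96** flags a key
pathway (one-sided: only unusually high importance is called). A median
split of per-sample scores yields groups for external survival analysis.

One practical caveat the synthetic experiments exposed: when several
pathways carry genuinely independent signal, a single trained network often
settles on a sufficient subset of them (training loss reaches ~0 without
the rest), and the attribution then truthfully reports that the unused
pathway did not matter *to that network*. Which subset is chosen depends on
the initialization seed. `pathwayImportance()` therefore accepts a list of
`pathwayIG()` results from models trained with different seeds and averages
their scores before z-scoring; a two- or three-model ensemble makes the
key-pathway calls stable under retraining and is what the package's own
recovery experiments use.

## The synthetic cohort generator

`generateCohort()` produces cohorts in which every claim above is testable
against a known ground truth. Default conditions (the package's reference
desk-scale analogue of a public tumor cohort): 300 samples, 600 genes of
which 20 are TFs, 30 pathways of 10–40 genes, 30 risk-informative genes and
3 driver pathways. The latent per-sample risk is the normalized sum of one
independent N(0,1) component per driver pathway, `r = Σ r_k / √3`, so the
drivers are mutually non-redundant: a model that ignores one of them caps
its achievable AUC, and a correct explainer must surface all three.
Survival time is log-linear in −r (log-sd 0.4, median at the 2-year
threshold, so classes are near-balanced) with exponential censoring (~10%).
Each informative gene adds `effect_size · r_k` of its driver's component
(default 3.0 — a strong, clearly separable signal chosen so the
architecture reliably learns every component at 300 samples; 0 gives a
pure-noise null cohort) to exactly one omics layer — ten genes per layer —
so omics combinations carry complementary information and the ablation
trend is identifiable. CNV is coupled positively and methylation negatively
to expression for every gene, matching the ±1 guidance-graph semantics; TF
targets co-vary mildly with their TF so the regulatory graph is
informative. Age is `55 + 2·r + N(0, 8)` years whenever signal is planted
(mildly prognostic, AUC ~0.6 on its own) and pure noise in the null cohort,
which therefore carries no predictive signal through any input.
Informative genes appear only inside the driver pathways, and each driver
hosts genes from all three layers, so gene-level and pathway-level
explanations have distinct, checkable ground truths.

What the generator does *not* emulate: real marginal distributions
(expression is Gaussian, not counts), batch effects, missingness,
probe-level methylation structure, or realistic network topology beyond
sparse TF fan-out. Passing the recovery tests therefore demonstrates that
the machinery is correct and sensitive at realistic sizes — not that any
particular AUC will be achieved on real tumors.

## Numerical choices and degenerate inputs

* Signed weighted-mean aggregation divides by the sum of |weights|;
  isolated nodes aggregate to zero and depend only on their own input.
* A pathway-omics block needs `min(M_dims, n_genes, n_train − 1)`
  components; blocks with no surviving genes are skipped, and a pathway
  missing from one omics occupies a zero column of the feature tensor.
* Constant pathway feature vectors get correlation 0 in the ordering;
  zero rows of `W_p` contribute 0 to the cosine penalty (no 0/0).
* All-equal risk scores produce a single low-risk group with a warning;
  the median element of an odd-length score vector goes to the low group
  (strict `>`).
* Explainer masks live strictly inside (0, 1); a sample with zero mask
  variance in an omics contributes zero z-scores with a warning.
* A single pathway (or zero score variance) within an omics makes the
  key-pathway z-score undefined and is an error, not a silent NA.

## Problem sizes used by the bundled experiments

The test suite and `scripts/acceptance.R` run entirely on generated data:
the default 300 × 600 cohort for cross-validation (5-fold with 2-3 repeats
on the planted cohort; 3-fold with 5 repeats for the null calibration and
the per-combination ablation, where the question is a mean trend rather
than a single best estimate), a 60 × 80 cohort for estimator-level checks,
seeded 100-sample subsets for the explainer recovery runs, and two-model
ensembles for the key-pathway calls. These sizes are the package's chosen
reference experiments; all of them exercise every code path of the full
model.

## Known limitations

* The encoder, head and training loop are plain R + Matrix; they are fast
  at the bundled scales (~a thousand graph nodes) but not engineered for
  genome-wide node sets in the tens of thousands.
* Binary LTS classification only — no continuous-time survival head; the
  exported risk groups and importance splits are inputs for external
  survival tooling (e.g. the survival package), which this package does not
  wrap.
* The mutual-information filter is the plain mean threshold of the design
  it follows; no multiple-testing control is attempted.
* Comparator models (CNN-on-pathway-image baselines and the like) are out
  of scope; the package validates against planted ground truth instead.
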