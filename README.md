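# mlgnn

Multilevel graph neural networks for multi-omics tumor survival-risk
classification, in R.

## What it does, and for whom

Given three omics layers over a shared gene set — mRNA expression,
copy-number variation (CNV) and DNA methylation (MT) — plus a TF→target
regulatory network (SCENIC-style edge list) and pathway gene sets (GMT),
`mlgnn` classifies patients into long-term survivors (LTS, survival beyond a
cancer-specific threshold such as 2 years) versus non-LTS, and explains the
classification at the gene and pathway level. It is aimed at computational
biologists working with small (a few hundred patients), wide tumor cohorts
who want network- and pathway-constrained models instead of unstructured
classifiers, with a fully synthetic, ground-truthed cohort generator for
validating every stage without any data download.

The model is hierarchical:

1. **Guidance graph** — nodes are (gene, omics) pairs; mRNA–mRNA edges carry
   per-TF-normalized regulatory weights `w ∈ [0, 1]`; CNV–mRNA edges are
   fixed at `+1` and MT–mRNA edges at `−1`, encoding the usual direction of
   association with expression. CNV and MT never connect directly.
2. **Gene encoder** — per node, a trainable embedding `e_v` scaled by the
   sample's value, `s_v = x_v · e_v`, followed by two GraphSAGE-style layers
   (signed weighted-mean neighborhood aggregation, self-concatenation,
   linear + ReLU), giving encodings `z_v` with a 2-hop receptive field.
3. **Pathway aggregation** — per (pathway i, omics j), a learnable matrix
   `W_p^{ij}` (initialized to the block's PCA loadings) contracts the
   expression-reweighted encodings: `PF_ijm = Σ_v W_p^{ijm}[v] (x_v · z_v)`,
   then two fully connected layers produce a D-dimensional pathway feature.
   A cosine penalty `L_ind = Σ_{m<n} |cos(W_p^m, W_p^n)|` keeps feature
   dimensions independent; total loss is cross-entropy `+ λ_ind · L_ind`.
4. **Prediction head** — pathway features form a D × N × M tensor, ordered
   by greedy Pearson-similarity chaining, max-pooled 2×2 over the
   (pathway × omics) plane, optionally concatenated with standardized age,
   and classified by two linear layers + softmax. The risk score is
   P(non-LTS).

Preprocessing uses k-nearest-neighbor mutual information
(`MI = ψ(N) − ⟨ψ(N_x)⟩ + ψ(k) − ⟨ψ(m)⟩`, k = 3) per training fold, keeping
genes above the per-omics mean MI. Evaluation is repeated stratified 5-fold
cross-validation with fold-pooled AUC. Interpretation uses a node-mask
explainer (GNN-Explainer lineage; per-sample masks on node inputs, z-scored
within omics and averaged) and Integrated Gradients over pathway features
(mean |IG| per block, median across samples, z > 1.96 within omics flags
key pathways).

All forward/backward passes are hand-written in base R + Matrix and are
verified against finite differences in the test suite.

## Worked example

```r
library(mlgnn)

# a synthetic cohort with planted signal and known ground truth
sim <- generateCohort(syntheticSpec(n_samples = 150, n_genes = 200, n_tfs = 10,
                                    n_pathways = 12, pathway_size = c(8, 20),
                                    n_informative = 24, n_drivers = 3, seed = 3))
cohort <- labelCohort(sim$cohort, thresholdYears = 2)
cohort

# mean-MI feature selection on all labeled samples
sel <- selectFeatures(cohort, k = 3)
sel

# guidance graph over the selected genes
graph <- buildGuidanceGraph(normalizeTFWeights(sim$network), sel$kept)
graph

# repeated stratified cross-validation (small settings for the example)
cv <- crossValidate(cohort, sim$network, sim$pathways,
                    nFolds = 3, nRepeats = 2, seed = 1)
cv

# train two models on everything; ensemble their pathway attributions
igs <- lapply(c(5, 6), function(s)
  pathwayIG(trainModel(buildModel(graph, cohort, sim$pathways, sel, seed = s + 2),
                       cohort, seed = s),
            cohort, steps = 128))
imp <- pathwayImportance(igs)
subset(imp, key)
```

Output from this exact script:

```
MultiOmicsCohort: 136 samples
  mRNA: 200 genes
  CNV: 200 genes
  MT: 200 genes
  labels: 71 LTS / 65 non-LTS (threshold 2 y)
  age available
FeatureSelection (k = 3 ):
  mRNA: 66 / 200 genes kept (mean MI threshold 0.0210)
  CNV : 71 / 200 genes kept (mean MI threshold 0.0215)
  MT  : 63 / 200 genes kept (mean MI threshold 0.0200)
GuidanceGraph: 200 nodes ( CNV 71, mRNA 66, MT 63 ), 46 edges ( CM 20, MM 18, mRNA 8 )
CVResult: 2 x 3-fold CV, pooled AUC 0.899 +/- 0.035
   pathway omics      score        z  key
1    PW003   CNV 0.03677330 3.024203 TRUE
13   PW001  mRNA 0.04586070 2.400576 TRUE
25   PW002    MT 0.03906457 2.493468 TRUE
```

Reading it: 136 of 150 samples are labelable at the 2-year threshold (the
rest are censored too early); about a third of the genes pass the mean-MI
filter in each layer; the guidance graph couples the retained genes within
and across omics; pooled AUC 0.90 shows the planted signal is learned; and
the three flagged key pathways are exactly the three planted driver
pathways (`sim$truth$drivers`), each surfacing in one omics layer.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/mlgnn simulate --config cfg.yaml --out run/
Rscript inst/scripts/mlgnn train --config cfg.yaml --out run/
Rscript inst/scripts/mlgnn explain-genes --config cfg.yaml --out run/
Rscript inst/scripts/mlgnn explain-pathways --config cfg.yaml --out run/
Rscript inst/scripts/mlgnn ablate --config cfg.yaml --out run/
```

Configs are YAML/JSON validated against a strict schema (unknown keys are
errors); every run directory carries a manifest (seed, config hash, package
version) and re-running from it reproduces its outputs byte-for-byte.

See the vignette (`vignettes/multilevel-gnn.Rmd`) for the full model
description, parameter meanings, numerical conventions and limitations.
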