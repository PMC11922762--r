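---
title: "Cross-species disease positioning: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species disease positioning: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(humoclust)
```

# The problem

Mouse models of hepatocellular carcinoma (HCC) are only useful to the
extent that they transcriptionally resemble the human disease. Rather
than matching models to patients by driver mutation — which is known to
be a poor proxy for signalling state — this package positions tumours of
both species in a *shared transcriptional space* and asks which human and
mouse samples co-cluster. The joint communities ("HuMo" clusters) define
cross-species subtypes that can then be characterized by pathway
enrichment, histology association and survival.

The pipeline is: per-species variance-stabilizing transformation (VST) of
raw counts; reduction to one-to-one human–mouse orthologs; within-sample
centring; SVD of the human matrix into a rank-r latent space; projection
of the mouse samples into that frozen human frame; an exact kNN graph
over all samples; and Louvain community detection. Everything downstream
(ssGSEA, subclassing, NTP, Fisher panels, survival) consumes these
cluster labels or the per-species VST matrices.

# The model, stage by stage

## Normalization

Size factors use the median-of-ratios estimator: with geometric-mean
reference $r_g = (\prod_j c_{gj})^{1/n}$ over genes positive in every
sample, $s_j = \mathrm{median}_g\, c_{gj}/r_g$. The VST assumes the
negative-binomial variance function $\mathrm{Var} = \mu + \alpha(\mu)
\mu^2$ with the trend $\alpha(\mu) = a_1/\mu + a_0$, and applies the
closed form

$$y = \log_2 \frac{1 + a_1 + 2 a_0 q + 2\sqrt{a_0 q (1 + a_1 + a_0 q)}}
{4 a_0}, \qquad q = c/s,$$

which behaves like $2\sqrt{a_0 q}/\ln 2$ at low counts and approaches
$\log_2 q$ at high counts (a doubling adds one unit). $q = 0$ is in the
domain.

The trend is fitted from gene-wise method-of-moments dispersions
$\hat\varphi_g = (v_g - m_g)/m_g^2$ on normalized counts, by least
squares of $\hat\varphi_g$ on $1/m_g$ over genes with $m_g \ge 1$ and
positive variance, one round of outlier trimming (residuals beyond
2×IQR), and a refit. Two numerical choices matter here:

* **Gene-wise estimates are left unclamped in the fit.** $\hat\varphi_g$
  has sampling noise of roughly $\sqrt{2/n}$ centred on the true
  dispersion; truncating at zero before fitting would discard the
  negative half of that noise and bias the intercept upward by several
  hundredths — enough to swamp a Poisson-like dataset's true $a_0
  \approx 0$. Only the fitted coefficients are clamped
  ($a_0 \ge 10^{-4}$, $a_1 \ge 0$).
* **Zero-variance genes carry no dispersion information** and are
  excluded; a matrix with no usable genes falls back to a constant
  dispersion or, failing that, errors.

Method of moments was preferred to maximum likelihood because it is
closed-form, independently checkable, and adequate for trend fitting at
cohort scale; estimation is "blind" (no design matrix).

## Order of operations

The VST is fitted per species on the *full* gene set (more genes give a
better trend fit), matrices are then subset to the one-to-one orthologs
(ambiguous pairs are dropped entirely, and mouse genes are renamed to
their human partner so a single gene namespace flows downstream), and
within-sample centring happens *last*, on the shared axis — this makes
human and mouse sample means comparable on the same genes.

## Latent space and projection

The rank-r space is the span of the top r left singular vectors (gene
loadings) of the centred human genes × samples matrix; r = 100 is the
analysis default (any r exceeding the matrix rank is reduced with a
warning; the recovery analyses in this vignette's test scale use r = 50
or less). Sample coordinates are $E^\top U_r$ — the unwhitened,
singular-value-scaled scores, so projecting the training matrix
reproduces its own SVD scores exactly. Mouse samples are projected with
the human loadings *unchanged*: the human space is a frozen reference
frame, and the per-gene species offset (a constant vector across mouse
samples) is largely annihilated because a random direction in gene space
retains only ~$\sqrt{r/G}$ of its norm after projection. Per-component
signs are fixed by forcing each loading's largest-magnitude entry
positive, making the factorization deterministic across platforms.

Whether scores should be whitened by singular values before neighbour
search was genuinely open; unwhitened scores were chosen because they
preserve the self-consistency identity above and weight components by
explained variance, which is what a Euclidean kNN should see.

## Graph and communities

The sample graph is exact kNN (Euclidean, default k = 20 — a common
choice for cohorts of hundreds; exposed as a parameter) with **union**
symmetrization and unweighted edges; distance ties break by lexicographic
sample id so the graph is reproducible. Louvain maximizes
$Q = \sum_c [e_c/m - \gamma (d_c/2m)^2]$ by seeded-order local moves
(each accepted move strictly increases Q; the per-pass trace is kept and
asserted monotone in the tests) followed by graph aggregation, until no
move helps. γ = 1. Louvain is greedy and path-dependent: on small or
ambiguous graphs single runs can land in local optima, so best-of-n
seeded restarts are supported (`n_restarts`) and used wherever
near-optimality is checked against exhaustive enumeration. Cluster
labels are deterministic given a partition: ordered by decreasing human
sample count, ties by total size, then lexicographic smallest member.
Isolated nodes become flagged singleton clusters.

New cohorts are attributed either by majority vote among the k nearest
reference samples in the frozen space (default; stable, never refits) or
by joint re-clustering with maximal-overlap label transfer. The default
is nearest-reference because joint re-clustering can reshape reference
communities as the new cohort grows.

## Gene-set analytics

ssGSEA uses the weighted running-sum statistic: genes ranked by
expression descending (ties by gene id), in-set cumulative weight
$|x|^\alpha$ versus out-of-set cumulative count, summed over all
positions. α = 0.25 by default (the classical ssGSEA weight; the
original analysis delegates to a package without stating α, so it is
exposed). Scoring consumes the per-species VST matrices — *not* the
centred ones — with mouse ids translated to human so human-symbol gene
sets apply to both species. Raw scores are the default; min-max
per-set normalization is optional and order-preserving. Subclass calls
(Hoshida/Chiang style) are the argmax over the named subclass rows, ties
to the lexicographically smallest name with a flag.

Nearest Template Prediction restricts expression to the union of marker
genes, builds a +1 (optionally signed) template per class, and predicts
the class minimizing cosine distance. Significance is by resampling:
each permutation draws one random marker set *per class* (matching each
class's size) from all genes and takes the minimum distance over
classes. Replicating the argmin selection in the null is what makes the
p-values uniform under no signal — comparing the observed minimum with
single random templates would be anti-conservative by construction,
because the minimum of K distances is stochastically smaller than any
one of them. The +1/(n+1) correction keeps p > 0; FDR is
Benjamini–Hochberg within the cohort.

## Association statistics

Cluster-phenotype panels are one-vs-rest per cluster (the only contrast
giving one dot per cluster per feature), Fisher exact two-sided p by the
probability-mass rule, odds ratio ad/bc with the Haldane–Anscombe +0.5
correction applied to all four cells only when a zero cell occurs — for
the OR and Wald CI but never for the exact p, keeping the exact test
exact while keeping the figure's log-odds finite. Categorical histology
is binarized "any vs none" by default (exposed as `negative_level`). No
multiplicity correction by default (per-test significance at p ≤ 0.05,
the open/closed-circle convention); BH is available. Survival uses the
Kaplan–Meier product-limit estimator and the standard log-rank
chi-square, both via the survival package.

# The synthetic cohort generator

Because the original human/mouse cohorts require controlled-access
downloads, the package ships a generator that emulates their statistical
structure: negative-binomial counts (Var = μ + φμ², φ stated everywhere
to avoid the size/prob ambiguity), k subtypes shared across species with
disjoint marker blocks among the orthologs only (non-ortholog genes are
noise), per-gene mouse baseline offsets drawn once (the shift the
projection must absorb), variable library sizes, and cluster-linked
covariates: Bernoulli mutation flags, exponential survival with
per-subtype hazards, uniform-fraction censoring, and Dirichlet-drawn
subtype-dependent histology categories.

Defaults are the study conditions used throughout the tests and the
acceptance script: 4 subtypes, 200 human + 80 mouse samples, 2500 genes
per species with 2000 orthologs, 15% of orthologs as markers per subtype,
mean |log2 FC| = 1.5 (signed per gene), φ = 0.1, library sizes uniform on
[2×10⁵, 10⁶], species offset s.d. 0.5 log2 units, mutation probabilities
(0.5, 0.15, 0.15, 0.15) echoing the CTNNB1 enrichment in cluster 1,
hazards (0.10, 0.05, 0.15, 0.20) giving cluster 2 the best prognosis, and
30% censoring. Sample and gene counts mirror the scale the method
targets — a few hundred human tumours, tens of mouse samples, and a
couple of thousand usable orthologs; effect sizes are not reported for
real cohorts, so the default was chosen once to exhibit both a clean
failure regime (ARI ≈ 0 at zero effect) and a clean success regime
(ARI ≥ 0.9 at 1.5), with the test suite sweeping the transition.

What the generator does *not* emulate: batch effects beyond the species
offset, many-to-many homology, compositional coupling beyond softmax
normalization, read-level noise, copy-number structure, and informative
censoring mechanisms (censoring times are a uniform fraction of the
event time, so censoring probability — though not timing — is
independent of subtype). Passing tests therefore demonstrate correctness
of the machinery under the assumed generative model, not robustness to
every artefact of real cohorts.

# Worked example

```{r example, eval = FALSE}
sim <- simulate_cohort(seed = 1)
fit <- humo_fit(sim$human_counts, sim$mouse_counts, sim$ortholog_map,
                rank = 50, knn_k = 20, seed = 0)
summary(fit)
plot(fit)

# characterize clusters with the generator's own marker sets
sets <- gene_set_collection(setNames(sim$marker_genes, paste0("subtype", 1:4)))
enr <- ssgsea_matrix(fit$expr$human, sets, alpha = 0.25)

# histology and survival associations
panel <- cluster_feature_panel(fit$clusters, sim$metadata, "histology")
lr <- logrank_test(sim$metadata$time, sim$metadata$event,
                   cluster_labels(fit)[sim$metadata$sample_id])
```

# Numerical choices, degenerate inputs, limitations

* Ambiguous ortholog pairs are dropped, not resolved by expression;
  gene ids are opaque strings (no version stripping).
* Counts of 0 are valid VST inputs; a matrix with no all-positive gene
  has undefined size factors and errors (a pseudo-reference fallback is
  deliberately not silent).
* kNN requires k < n; duplicate coordinates are allowed and resolved by
  the id tie-break. Louvain on an edgeless graph returns singletons with
  Q = 0.
* Gene overlap when projecting external cohorts: warn below 100%,
  error below 80% (missing genes contribute zero to scores).
* UMAP layouts are decorative; clustering never consumes them.
* Problem sizes in the tests (e.g. rank 15–50, cohorts of tens to a few
  hundred samples, 50-graph exhaustive Louvain comparisons at ≤ 8 nodes)
  are the package's chosen validation scale; all recoveries quoted above
  are recomputed by the test suite and `scripts/acceptance.R`, and no
  empirical claim is made beyond what those runs compute.
* The Fisher panel treats semi-quantitative histology as binary; ordinal
  trend tests and Cox models are out of scope, as are Leiden refinement,
  weighted/SNN graphs and consensus clustering.
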