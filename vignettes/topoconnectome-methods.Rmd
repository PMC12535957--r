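---
title: "Topological and graph-theoretical featurization of multimodal brain networks"
author: "topoconnectome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological and graph-theoretical featurization of multimodal brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topoconnectome)
```

## The problem

Multimodal MRI yields, for every subject, several weighted networks over one
anatomical parcellation: a morphological gray-matter (GM) similarity network,
an FA-weighted structural connectivity network (DTI), and a resting-state
functional correlation network (fMRI). All edge weights live in $[0,1]$ (raw
functional correlations in $[-1,1]$, rectified by taking absolute values,
because only the strength of co-activation is of interest here). The package
turns such networks — single layers, their concatenation, or a two-layer
multilayer network — into fixed-length feature vectors, and benchmarks how
well those vectors separate a patient group (PwMS) from healthy volunteers
(HV) under repeated stratified cross-validation with AUC-ROC scoring.

Because clinical connectome datasets of this kind are generally not
redistributable, the package ships a synthetic cohort generator that
reproduces the statistical structure the analysis relies on. Every stage is
therefore testable end to end without any external data.

## Weight inversion and the flag filtration

Persistent homology expects *dissimilarities*: tightly connected regions
should be close. Connectivity scores are therefore inverted edgewise,

$$\hat e_{ij} = 1 - e_{ij},$$

and the inverted network is filtered by a threshold $t$ growing from 0 to 1.
At threshold $t$ the complex contains every vertex, every edge with
$\hat e_{ij} \le t$, and every higher clique of such edges (the flag, or
Vietoris–Rips, construction); a $k$-simplex enters at the maximum of its
edges' dissimilarities. Two conventions are deliberate and fixed:

* An absent raw connection ($e_{ij} = 0$) maps to $\hat e_{ij} = 1$: it
  enters the complex only at the final threshold. The matrix is treated as
  dense throughout; there is no sparsity cutoff.
* Intervals are half-open $[b, d)$ and zero-persistence pairs are dropped,
  so Betti curves are well defined at every grid point. Infinite bars are
  retained and counted for all $t \ge b$; in particular $\beta_0(1)$ equals
  the number of connected components of the full graph (1 for dense
  matrices).

Homology is computed over GF(2), the standard choice for persistence (no
torsion is reported). Ties in filtration value are broken by (dimension,
lexicographic vertex tuple); diagrams and Betti curves are invariant to this
choice, which unit tests verify by vertex relabeling.

## Computing persistence

The reduction operates on the *coboundary* matrix, dimension by dimension,
with the clearing optimization: for homology dimension $d$ the columns are
the $d$-simplices in decreasing filtration order and the rows their
$(d+1)$-cofacets. This produces exactly the pairing of classical
boundary-matrix column reduction, but never reduces a column of the top
dimension — decisive for dense clique filtrations, where a 76-region network
filtered for dimensions $\{0,1,2\}$ contains $\binom{76}{4} \approx 1.28$
million tetrahedra whose (almost entirely zero-reducing) boundary columns a
homology-direction reduction would have to process one by one. On one CPU
core the 76-region, dimensions-$\{0,1,2\}$ case completes in a few seconds;
the same computation through the boundary matrix took minutes in our
development measurements.

Correctness is established against two independent routes, never against
the reduction itself:

* a brute-force oracle that rebuilds the complex at a threshold and computes
  $\beta_k = n_k - \operatorname{rank}\partial_k -
  \operatorname{rank}\partial_{k+1}$ by Gaussian elimination over GF(2)
  (`betti_bruteforce_oracle()`), and
* igraph's connected-component counts for $\beta_0$.

The Euler identity $\sum_k (-1)^k \beta_k(t) = \sum_k (-1)^k n_k(t)$ on the
truncated complex is asserted at every breakpoint as an additional internal
consistency check of the oracle route.

The multilayer complex is filtered on the supra-adjacency matrix (below) and
doubles the node count to $2N$; because simplex counts grow steeply, the
supra complex may be capped at dimensions $\{0,1\}$ via `supra_dim_cap`
(with a logged notice). At $N = 76$ the capped supra case runs in about a
second; uncapped it enumerates $\binom{152}{4} \approx 21$ million
tetrahedra and takes several minutes, which is why the cap exists.

## Betti curves

A diagram is vectorized by sampling $\beta_k(t)$ at `grid_size` (default
100) equally spaced thresholds on $[0,1]$, endpoints included, one vector
per homology dimension, concatenated in dimension order (and across the
three modalities for the concatenated single-layer representation).

## The multilayer network

The supra-adjacency matrix is the $2N \times 2N$ block matrix

$$S = \begin{pmatrix} W_{GM} & W_{DTI} \\ W_{DTI}^{\top} & W_{fMRI} \end{pmatrix},$$

GM and fMRI as intralayer blocks and the structural DTI matrix as interlayer
links ("roads" coupling the two views of each region). The coupling between
a region's two replicas is the DTI diagonal — zero — unless
`replica_coupling` overrides it with a constant in $(0,1]$. For homology the
supra matrix is assembled in raw space and inverted as a whole, so an
absent interlayer link becomes dissimilarity 1; a zero DTI matrix therefore
decouples the two layers at every threshold below 1, which is tested via
component counts. This supra-graph treatment — including computing node
metrics on the supra graph and averaging each region's two replica values —
is the package's declared multilayer convention, chosen for transparency
over more elaborate multilayer centrality definitions; results under it are
labeled as such in feature provenance strings.

## Node metrics

Five node-level metrics are computed on raw (non-inverted) weights, since
inversion exists only to orient the filtration: degree (edges above a
threshold, default 0, exposed because dense matrices make degree degenerate
at $N-1$), strength (row sums), local efficiency, betweenness and closeness.
Path-based metrics use edge length $1/w$ — the dominant convention in
connectomics toolkits, where stronger connections are shorter — with
$1 - w$ available as an alternative. Betweenness is normalized by
$(N-1)(N-2)/2$; closeness uses component-size scaling,
$c(v) = \frac{r_v}{N-1} \cdot \frac{r_v}{\sum_u d(v,u)}$ over the $r_v$
reachable nodes, so disconnected graphs degrade gracefully (isolated nodes
score 0); harmonic closeness was rejected to keep a single declared
convention. Local efficiency of a node is the mean inverse shortest-path
length over ordered pairs of its neighbors, computed inside the neighborhood
subgraph; unreachable pairs contribute 0 and nodes with fewer than two
neighbors score 0. Betweenness and closeness are verified against exhaustive
simple-path enumeration on all-random graphs with $N \le 7$.

## Preprocessing

The fixed pipeline order is: absolute value on fMRI correlations, then
edge-wise covariate residualization, then (only for homology) inversion.
Residualization fits, per modality and per edge independently, ordinary
least squares of edge weight on (intercept, age, sex indicator) across
subjects and replaces each value with its residual plus the edge's
cross-subject mean. The design matrix is handled through the pseudoinverse,
so constant covariates degrade to an exact pass-through rather than an
error. Residuals can leave $[0,1]$; they are clamped with a logged count
rather than rescaled, since centering at the mean is the only stated
transformation. Sex is encoded F = 0 / M = 1; because the fit includes an
intercept, the coding does not affect residuals. Whether residualization
should precede or follow the absolute-value transform is not externally
determined; the package declares abs-first as the default order and exposes
both toggles.

## The synthetic cohort generator

The generator defines the study conditions for every test; its defaults are
fixed and are not tuning knobs.

* **Base edge distributions.** Raw DTI weights are drawn from a normal
  distribution truncated to $[0,1]$ with mean 0.40 and sd 0.10, so inverted
  weights concentrate in 0.4–0.8 and look normal; raw GM similarity is
  truncated normal with mean 0.60 and sd 0.05, placing inverted mass in the
  narrower 0.3–0.5 band; fMRI correlation magnitudes follow Beta(1.2, 4.0)
  (mostly weak correlations, so inverted values skew high), with 30% of
  edges given a negative sign to exercise the rectification step. The
  truncated-normal/Beta families are the generator's own concrete choices
  for matching those qualitative histogram shapes; all parameters are
  config-exposed.
* **Covariates.** Ages are uniform on 25–60 years; sex is Bernoulli with
  60% female — plausible ranges for an adult clinical cohort. Edge weights
  are shifted by $s_{\text{age}}(a - 42.5) + s_{\text{sex}}\,\mathbb 1[M]$
  and clamped; default slopes are small (age $-0.002$/yr, sex $0.01$) so
  that clamping is rare and the residualizer has a real but removable
  signal.
* **Group effect.** A fixed, seed-determined subset of edges (default 30%
  of the target modality's edges, default target DTI) is reduced by `delta`
  in patient subjects only. The affected subnetwork is the same for every
  subject — modeling a disease that alters consistent pathways — which is
  what makes the group signal learnable by cross-validated classifiers.
* **Determinism.** Every subject is generated from its own seed derived
  from the master seed, so cohorts are reproducible and individual subjects
  do not change when the cohort grows.

What the generator does *not* emulate: spatial lesion geometry, tractography
biases, realistic fMRI autocorrelation structure, or site effects. Passing
benchmarks on these cohorts demonstrates that the pipeline recovers planted
group structure of realistic magnitude and location — not that any
particular clinical effect size will be reproduced on real data.

## Feature pipelines and the benchmark

Representations: three single layers, their concatenation, and the
multilayer supra network. The Betti pipeline yields
`grid_size × |dims|` columns per complex; the metric pipeline yields $N$
columns per metric (aggregated replica means for the multilayer), $5N$ for
the all-metric configuration ($5 \times 76 = 380$ at the reference
parcellation). The all-metric table can be PCA-reduced to 20 components or
reduced to the top 100 columns by random-forest impurity importance.

PCA and importance selection are fitted inside each training fold and
applied to the held-out fold — the defensible default for leakage control
when nothing else is specified. Columns are z-scored (fit on training
folds) before the network, logistic regression and SVM, but not before the
random forest, which is scale-invariant; unscaled Betti counts would
otherwise dominate metric features in the kernel and gradient-based models.

The four classifier families are fixed: a fully connected network with
hidden layers (200, 100, 10), ReLU activations, trained full-batch with
Adam (learning rate $10^{-3}$, at most 300 epochs, early stopping on a
stratified 20% validation split of the training fold, patience 20 — a fixed
budget chosen once, since only the architecture is externally specified);
ridge-penalized logistic regression (penalty $1/n_{\text{train}}$, matching
the common default of unit inverse-regularization scaled by sample size);
a random forest of 100 fully grown trees; and an RBF SVM with $C = 1$ and
the scale heuristic $\gamma = 1/(p \cdot \operatorname{var}(X))$. All four
emit continuous scores, never hard labels.

Evaluation is stratified 4-fold cross-validation repeated 10 times with
fold assignment re-randomized each repeat from the master seed ("random
initializations of the subjects within each fold" is read as re-randomized
folds; re-initializing only the models would leave the 10 repeats nearly
redundant for the three deterministic families). AUC is computed per
held-out fold from the continuous scores via the trapezoidal ROC sweep,
which the tests verify equals the Mann–Whitney rank statistic exactly,
including ties. Summaries report, per configuration and family, the mean
and standard deviation over the 10 repeat-level means, a cross-family
average, and a flag for average $\ge 0.70$.

A calibration property of the harness itself: with labels permuted
independently of the features, every family's grand mean AUC must sit at
0.5. A single permutation of one dataset does not satisfy this tightly —
whatever spurious dataset-level association that permutation happens to
carry is shared by all folds — so the null check averages over several
fresh permutations, under which the AUC null distribution is symmetric
about 0.5 by construction. The same reasoning applies to benchmarks on
cohorts generated with a zero group effect: the chance level of a
configuration is estimated by averaging its grand mean AUC over several
independently generated null cohorts, since any single cohort's folds all
share whatever spurious association that cohort happens to carry.

## Problem sizes used by the tests and the acceptance script

The shipped checks run on deliberately scaled-down instances chosen to
exercise every code path: oracle comparisons on 50 random networks with
5–10 vertices; metric oracles on 50 graphs with up to 7 vertices (the
exhaustive path enumerator grows factorially); residualization recovery on
200 subjects over 10 regions; the parameter-recovery benchmark on 40
regions with 30 + 30 subjects, homology dimensions $\{0,1\}$ and a
DTI-targeted `delta` of 0.15 (at which DTI-bearing representations must
beat the fMRI-only representation by at least 0.15 mean AUC, while a
`delta` of 0 must leave every representation at chance); and one dense
76-region subject for the dimensions-$\{0,1,2\}$ homology timing. The
end-to-end workflow test uses a 12-region, 12-subject cohort.

## Known limitations

* The multilayer metric convention is a supra-graph computation with
  replica averaging, not a reimplementation of any specific multilayer
  centrality theory; provenance strings record this.
* The generator draws edges independently given the covariate and group
  structure; real connectomes have correlated edges, community structure
  (available optionally via `community_structure`, off by default) and
  heavier tails.
* Homology above dimension 2 is out of scope, as are persistence
  landscapes, images and entropy summaries, and cohomology representatives.
* Degree on dense matrices is degenerate at threshold 0; the threshold is a
  parameter, not a recommendation.

## A minimal session

```{r example, eval = FALSE}
cfg <- synthetic_config(n_hv = 12, n_pwms = 12, parcellation_size = 20,
                        seed = 1)
ch <- preprocess_cohort(generate_cohort(cfg))

# topological features of the structural layer, dims 0 and 1
fm <- betti_features(ch, "SL-DTI", dims = c(0, 1))
res <- repeated_cv(fm, n_folds = 4, n_repeats = 10, seed = 1)
summarize_cv(res)

# or the whole benchmark in one call
out <- run_all(run_config(synthetic = cfg, dims_sets = list(c(0, 1)),
                          n_repeats = 2))
out$betti_summary
```
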