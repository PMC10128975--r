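---
title: "Phenotype-constrained network fusion: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype-constrained network fusion: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonmtf)
```

## The model and its assumptions

`sonmtf` jointly factorizes a binary subject-by-gene variant matrix
$M \in \{0,1\}^{n_s \times n_g}$ and several gene-by-gene interaction
networks $R_i \in \{0,1\}^{n_g \times n_g}$ over one shared, ordered
gene universe:

$$\min_{P,S,G,U_i \ge 0}
\;\lVert M - P S G^\top\rVert_F^2
+ \sum_i \lVert R_i - G U_i G^\top\rVert_F^2
\quad \text{s.t. } P^\top P = I,\; G^\top G = I .$$

The shared gene factor $G$ ($n_g \times k_1$) is the point of the
fusion: the networks and the variant profile must explain the *same*
gene clustering, so sparse genomic evidence from a handful of subjects
is regularized by dense interaction evidence. The orthogonality
constraints push $P$ and $G$ towards cluster-indicator matrices, which
justifies reading hard clusters off their row-wise maxima.

The model assumes (i) a single gene-identifier namespace aligning
networks, variants and annotations — the package treats identifiers as
opaque strings and ships no aliasing service; (ii) binary relations —
variant multiplicity, zygosity and co-expression strength beyond the
thresholding step are discarded; (iii) that phenotype is informative at
the subject level, which is what fixing $P$ encodes.

### The fixed subject factor

With one column per phenotype group and entries $1/\sqrt{|group|}$,
$P^\top P = I$ holds exactly and stays exact because fixed-P mode never
updates $P$. $k_2 = 2$ is forced in this mode (healthy vs diseased);
free-P mode accepts any $k_2 \le n_s$. Both phenotype groups must be
non-empty, which also dictates which subject pairs are eligible in the
stability analysis.

## Optimization

### Update rules

Each sweep updates $S$, every $U_i$, then $G$ (then $P$ when free), in
that fixed order:

* $S \leftarrow S \circ (P^\top M G) \oslash (P^\top P\, S\, G^\top G)$
* $U_i \leftarrow U_i \circ (G^\top R_i G) \oslash (G^\top G\, U_i\, G^\top G)$
* $G \leftarrow G \circ \big[\,\mathrm{num} \oslash (G G^\top \mathrm{num})\,\big]^{1/2}$
  with $\mathrm{num} = M^\top P S + \sum_i R_i G (U_i + U_i^\top)$,

the square-root form being the standard multiplicative rule for
orthogonality-constrained factors. All quantities in the ratios are
nonnegative, so factors stay nonnegative; a guard
$\varepsilon = 10^{-10}$ on denominators prevents division by zero
(entries whose numerator is zero may reach zero, never below). A
non-finite entry aborts with an error, signalling divergence. At an
exact factorization with orthonormal factors every update ratio is 1,
i.e. the truth is a fixed point.

$S$ is stored as $k_2 \times k_1$ so that $P S G^\top$ conforms; note
some presentations write its transpose.

### Initialization

The default start is *spectral*: k-means (10 restarts under the run's
seed) on the leading $k_1$ eigenvectors of the mean network adjacency
gives a near-indicator $G_0$ (indicator plus 0.01, columns normalized),
and $S_0 = P^\top M G_0$, $U_{i,0} = G_0^\top R_i G_0$ are the
nonnegative projections. This choice was made because multiplicative
updates only move *within* the support pattern of their start: from a
dense uniform-random $G$ they reliably descend but often settle in
optima that blend two true clusters, whereas the spectral start is
already near-orthonormal and lets the updates act as a local refinement.
A uniform-random scheme (`init = "random"`: i.i.d. U(0,1), $G$ columns
normalized) remains available and is the automatic fallback when the
embedding cannot support $k_1$ k-means centers (tiny or degenerate
inputs). Restart $r$ seeds the generator with `seed + r − 1`; the best
final objective across restarts wins.

### Convergence and defaults

| parameter | default | meaning |
|---|---|---|
| `k1` | 5 (pipeline) | gene clusters; set to the expected module count |
| `k2` | 2 | subject clusters; fixed-P mode forces 2 |
| `max_iter` | 500 | sweeps per restart |
| `rel_tol` | 1e-6 | relative objective change declaring convergence |
| `n_restarts` | 10 | random restarts (3 suffice with spectral init) |
| `epsilon` | 1e-10 | denominator guard |

Monotone descent of the objective is not a theorem for the square-root
orthogonal rule, but holds empirically from the spectral start on every
instance class the tests exercise (per-step relative tolerance
$10^{-8}$); the constraint residual
$\lVert G^\top G - I\rVert_F/\sqrt{k_1}$ is a reported diagnostic, not
an invariant, since orthogonality is enforced only through the rules.

## Downstream analysis choices

* **Hard clustering.** Row argmax; ties break to the lowest column
  index and all-zero rows go to cluster 1 with a warning — both are
  conventions beyond the max rule itself, chosen for determinism.
  Assignments are invariant to positive row scaling.
* **Subnetworks.** A cluster's subnetwork takes the union of
  intra-cluster edges over all networks, with per-edge provenance.
* **Specificity.** healthy-specific = mutated in ≥ 1 healthy and 0
  diseased subjects; disease-specific = mutated in *all* diseased and 0
  healthy subjects (a `at_least_k` relaxation exists but defaults off).
  Percentages are over all cluster members, mutated or not.
* **Co-expression thresholding.** The top fraction (default 1%) of
  pairs by weight is kept *globally*, not per gene; the retained count
  is $\lceil f\,|E|\rceil$ and ties at the cut break lexicographically.
  A per-gene variant would favor hub genes; the global reading is the
  plain one and is the package's choice.
* **Universe.** Exactly the genes with ≥ 1 PPI edge, PPI being the most
  direct interaction evidence; other networks are restricted to it.
* **Enrichment.** Hypergeometric upper tail via the stable
  distribution-function routine; $N$ and $M_{ann}$ count only genes
  annotated by ≥ 1 set of the collection, per the test's definition.
  Correction is Benjamini–Hochberg over all (cluster, annotation) pairs
  *within one namespace* — a global family across, say, GO and Reactome
  would mix very differently-sized term systems; the namespace is
  recorded in every output row. Significance is $p_{adj} \le 0.05$.
* **Stability.** Re-fits on every healthy–diseased subject pair (all
  pairs in free-P mode) and compares gene partitions with the adjusted
  Rand index (normalized mutual information available via config);
  ARI is the default because its chance correction makes 0 interpretable
  across different $k_1$.

## What the synthetic generator does and does not emulate

`planted_spec()` mirrors the *statistical shape* of a small two-family
carrier cohort design:
1 healthy + 4 diseased subjects; three mutually independent
planted-partition networks over 200 genes in 5 equal clusters
($p_{in} = 0.3$, $p_{out} = 0.02$); mutation rates 0.6 on a phenotype's
disjoint target clusters vs 0.05 background; three 20-gene annotation
sets per cluster, 90% drawn from the cluster. These sizes keep a full
pipeline run around a second while leaving a clear signal-to-noise
margin, and they are the scale at which all package-level checks run.

It does **not** emulate real genetics: no allele frequencies, linkage,
pedigree structure, network degree heterogeneity (real PPI networks are
scale-free; planted-partition graphs are locally Erdős–Rényi), nor
correlated errors between networks. Passing the planted-recovery tests
therefore shows the estimator recovers the structure *its own model
assumes* at realistic sparsity — it does not certify performance on
real cohorts, where cluster sizes are unbalanced, $k_1$ is unknown and
the variant signal is far weaker.

## Known limitations

* $k_1$ must be supplied; no model-selection procedure is included.
* Dense matrix algebra throughout: fine to a few thousand genes, not
  engineered for the ~17k-gene scale of genome-wide runs (a sparse
  backend would be the natural extension).
* Fixed-P mode requires phenotype labels for every subject; the method
  is deliberately not fully unsupervised.
* The multiplicative solver is a local heuristic; different seeds can
  reach different optima, which is why restarts and the stability
  module exist.
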