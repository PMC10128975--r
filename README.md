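# sonmtf

Phenotype-constrained fusion of molecular interaction networks with
germline variant profiles by **S**imultaneous **O**rthogonal
**N**on-negative **M**atrix **T**ri-**F**actorization.

## The problem

Rare hereditary diseases offer too few genomes for association studies:
with a handful of carriers, the genomic signal alone cannot separate
causal from incidental variation. One way out is to support the weak
genomic signal with prior molecular knowledge — protein–protein
interactions (PPI), gene co-expression (COEX) and genetic interactions
(GI) — and with the one strong piece of information that is available:
each subject's phenotype (healthy carrier vs diseased). `sonmtf`
implements such a data-fusion analysis for a small cohort of subjects
whose per-gene variant status is summarized as a binary matrix, and
returns gene clusters whose variant content separates the healthy from
the diseased subjects, together with their interaction subnetworks and
functional enrichments.

## The model

Let `M` (n_s × n_g) be the binary subject-by-gene variant matrix
(`M[s,g] = 1` iff subject `s` carries a non-synonymous coding variant in
gene `g`) and `R_i` (n_g × n_g, i = 1..3) the network adjacency
matrices over a shared, ordered gene universe. All matrices are
factorized simultaneously,

    min_{P,S,G,U_i ≥ 0}  ||M − P S Gᵀ||²_F + Σ_i ||R_i − G U_i Gᵀ||²_F
                         s.t.  PᵀP = I,  GᵀG = I

where `P` (n_s × k₂) and `G` (n_g × k₁) are cluster-membership indicator
factors for subjects and genes, `S` (k₂ × k₁) links subject clusters to
gene clusters, and each `U_i` (k₁ × k₁) compresses one network. `G` is
shared across all data, so every network and the variant profile inform
the same gene clustering. Phenotypes enter as prior knowledge by
*fixing* `P` to the orthonormal healthy/diseased group indicator
(entries `1/√(group size)`), which forces the subject stratification and
lets the gene clusters absorb the healthy-vs-diseased contrast.

The objective is minimized by multiplicative update rules (with the
square-root, orthogonality-projected form for the orthogonal factors),
started from a spectral/k-means initialization. Hard clusters are read
off `G` by row-wise argmax; each gene cluster yields a subnetwork whose
edges are the union of the three networks restricted to the cluster.
Genes are labeled *healthy-specific* (mutated only in healthy subjects)
or *disease-specific* (mutated in all diseased subjects and no healthy
one), clusters are ranked by the percentage of such genes, and each
cluster is tested for annotation enrichment with the hypergeometric
upper-tail probability and Benjamini–Hochberg correction.

## Worked example

Real cohort genomes are private, so the package ships a generator of
desk-scale benchmarks with planted structure: five gene clusters of
40 genes, three planted-partition networks (edge probability 0.3 within
clusters, 0.02 between), one healthy + four diseased subjects whose
mutations hit disjoint target clusters (rate 0.6 vs background 0.05),
and three annotation sets per cluster.

```r
library(sonmtf)

d   <- generate_planted(planted_spec(seed = 42))
cfg <- default_config(solver = list(k1 = 5, seed = 42, n_restarts = 3))
res <- run_pipeline(d$profile, d$networks, d$annotations, config = cfg)

print(res$fit)
#> sonmtf_fit: objective 6829.78 after 41 iterations (restart 1, converged)
round(res$specificity, 1)
#>   cluster_id size pct_healthy_specific pct_disease_specific
#> 1          1   40                  0.0                   20
#> 2          2   40                  0.0                    0
#> 3          3   40                  2.5                    0
#> 4          4   40                  2.5                    0
#> 5          5   40                 52.5                    0
res$quality
#> [1] 100
compare_partitions(res$clustering, d$assignment)
#> [1] 1
```

The factorization recovers the planted partition exactly (adjusted Rand
index 1). One recovered cluster concentrates the healthy-specific
variants (52.5% of its genes are mutated only in the healthy carrier)
and another the disease-specific ones (20%) — the synthetic analogues of
the healthy- and disease-specific subnetworks the method is built to
find. Every cluster has significantly enriched planted annotations
(cluster quality 100%); the enrichment table carries the cluster/
annotation counts and adjusted p-values:

```r
head(subset(res$enrichment, significant), 3)
#>   cluster_id annotation_id namespace  N  X M_ann  K        p_raw       p_adj significant
#> 1          1      ANN:c2:1   planted 31 18   164 20 5.141255e-14 7.713883e-13        TRUE
#> ...
```

A thin command-line driver is installed with the package
(`system.file("cli", "sonmtf.R", package = "sonmtf")`) with
`simulate`, `run` and `stability` subcommands over YAML configs.

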