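---
title: "Methods: from OTU abundances to QTL networks"
author: "micronetgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from OTU abundances to QTL networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its statistical machinery: the
models and conventions at each stage, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the choices made
where the design was genuinely open.

## 1. Behavioral descriptors

Within one host, microbial pairwise interactions are scored from the
log10-transformed abundances `x -> log10(x + 1)`. The pseudocount keeps
zeros at zero and makes the transform total on non-negative data; zero
abundance means "absent in this host" and excludes the OTU from all pairs.
For an ordered pair with `xu > xv > 0`:

| type       | formula                    | reading                                  |
|------------|----------------------------|------------------------------------------|
| mutualism  | `xu*xv/(xu - xv)`          | large when both abundant and near-tied   |
| antagonism | `1/((xu*xv)(xu - xv))`     | large when both rare and near-tied       |
| aggression | `xu/xv`                    | dominance of the more abundant partner   |
| altruism   | `1 - xv/xu`                | sacrifice extent, in (0, 1)              |

Useful identities, enforced as tests: `Z_al = 1 - 1/Z_ag`,
`Z_mu * Z_an = 1/(xu - xv)^2`; `Z_ag` and `Z_al` depend on the pair only
through the ratio `xu/xv`.

**Ties.** `xu == xv` makes two of the denominators vanish. Tied pairs are
excluded rather than epsilon-perturbed: with continuous abundances ties have
probability ~0, and no principled regularization presents itself. The same
exclusion applies to zero-abundance partners.

## 2. Normalization, thresholding, networks

Each host's descriptor matrix is min-max normalized over its defined entries
(`(z - min)/(max - min)`; a degenerate range maps to 0) and entries strictly
above a threshold are kept as edges: 0.95 for mutualism, antagonism and
aggression, 0.99 for altruism. Normalization scope is per host per type by
default; a `scope = "global"` switch normalizes against the min/max pooled
across hosts for cross-host comparability of edge weights. Per-host is the
default because each matrix is an object in its own right and pooling makes
a host's network depend on the rest of the cohort.

Mutualism and antagonism networks are undirected; aggression and altruism
are directed from the more abundant to the less abundant member. All OTUs of
the panel stay in the graph, so isolated nodes count in denominators.

A consequence worth knowing: `Z_mu` and `Z_an` are heavy-tailed in the gap
`xu - xv`, so after min-max normalization the top 5% of the *range* is
typically occupied by very few near-tied pairs, and synthetic mutualism and
antagonism networks come out much sparser than the ratio-based aggression
and altruism networks. This is intrinsic to the formulas plus range
normalization, not a defect of the implementation.

## 3. Centralities and emergent indices

Shortest-path quantities use the unweighted topology (after thresholding,
an edge is present or absent). The conventions, all computed in-package and
cross-checked against igraph and brute-force oracles:

- **degree**: incident edge count; total (in + out) for directed graphs.
- **closeness**: Wasserman–Faust corrected for disconnected graphs — a node
  reaching `r` others with distance sum `d` gets `(r/d) * (r/(N-1))`;
  isolated nodes get 0. Directed graphs use outward distances.
- **betweenness**: Brandes' algorithm, directed paths on directed graphs, no
  pair normalization.
- **eccentricity**: the largest distance to a reachable node, 0 if none.
- **eigencentrality**: leading eigenvector of the adjacency, symmetrized and
  binarized for directed graphs, scaled to max 1.
- **PageRank**: damping 0.85, power iteration to 1e-13, dangling mass spread
  uniformly.

The network-level index vector per host and type is connectivity (edge
density given directedness) plus the mean of each of the five node
centralities — 24 phenotype columns in total. Mean-over-nodes is a declared
convention; exact network-level formulas for these summaries vary across the
literature and the choice is recorded in the run manifest.

**Hub calling** runs on per-type consensus networks (built from across-host
mean log10 abundances through the same normalize/threshold path): hubs are
nodes strictly exceeding both a degree and a closeness cutoff, by default the
0.90 quantile of each metric among non-isolated nodes, with absolute
overrides. For directed types these centralities are computed on the
symmetrized topology (`hub_centralities()`): the strongest nodes of a
directed interaction network are edge *sinks* whose outward closeness is 0,
so a joint rule on directed-path closeness could never fire — hub status is
about embeddedness in the co-occurrence structure, consistent with using
total degree.

## 4. Association mapping

Each index is transformed `log10(index + 1e-6)` — indices can be exactly 0
(empty networks), and the fixed offset is recorded. Each SNP is tested by
OLS of the phenotype on the 0/1 genotype indicator with a two-sided t-test
on the slope; covariates (e.g. subpopulation proportions) are projected out
of both phenotype and genotype first, which reproduces the partial t-test of
the joint model exactly. Missing genotypes are mean-imputed per SNP; SNPs
with more than 10% missing calls are dropped, as are SNPs with
MAF <= 0.05 (strict) and zero post-imputation variance.

Significance is the fixed line `-log10(p) >= 5` (inclusive); no further
multiple-testing correction is applied, though a Bonferroni column is
emitted. Genomic-control lambda is the median observed 1-df chi-square over
its null median. SNP heritability: per-SNP h² is the single-SNP R²; total
SNP-h² is the joint OLS R² over all significant SNPs, switching to ridge
with a small fixed penalty (1e-3·n) and a flag when the hit count
approaches the sample size. Degenerate fits follow fixed conventions: a
constant phenotype gives beta 0 and p 1; a perfect fit reports the smallest
positive double rather than 0, keeping p in (0, 1].

## 5. QTL networks

For each phenotype, hosts are re-coded by the genotype-mean transform: at
each significant SNP a host is assigned the mean phenotype of all hosts
sharing its allele, giving a hosts × SNPs matrix with two distinct values
per column. Over these columns a directed acyclic graph is learned by
maximizing the decomposable Gaussian BIC (per node: Gaussian log-likelihood
of the node on its parents minus `0.5·log(n)` per parameter) with greedy
hill climbing over add/delete/reverse moves, a `max_parents = 3` cap, and
random restarts from sparse random DAGs (edge probability 0.2 over a random
topological order). Acyclicity is enforced at every move; the search is
deterministic given its seed. Edge orientations are reported as statistical
dependency orientations, not biological causality: genotype-mean columns are
deterministic functions of genotype, so orientation is score-driven only.
Hub QTLs are nodes whose total degree strictly exceeds the 0.90 quantile
among non-isolated nodes.

On problems with up to four nodes the hill climber is validated against
exhaustive enumeration of all 543 DAGs; chain-structured data (X→Y→Z) is
used to verify skeleton recovery without the shortcut X–Z edge.

## 6. The synthetic-data generator

The generator emulates the target study design: 179 inbred host accessions,
a panel of the 100 most abundant bacterial and 100 most abundant fungal
OTUs, and biallelic SNPs with allele frequencies drawn uniformly from
(0.02, 0.5] — deliberately spanning both sides of the 5% MAF filter.
Genotypes are single 0/1 calls (homozygous inbred coding). Population
structure, when requested, perturbs per-subpopulation allele frequencies
Balding–Nichols style, `Beta(p(1-F)/F, (1-p)(1-F)/F)` with divergence `F`
(default 0.1), hosts assigned to subpopulations in blocks.

Per-OTU baseline log10 abundances are uniform on [1, 4] and sorted
decreasing within kingdom so that low OTU ids are the abundant taxa,
mirroring a "most abundant" selection. The log10 abundance of OTU j in host
i is `baseline_j + Σ_s effect·x_is + N(0, 0.5)` over the causal SNPs
affecting j, exponentiated back to the raw scale, so everything is strictly
positive. Each `simulate_*` operation seeds its RNG deterministically from
`config$seed` plus a fixed per-operation offset — operations are then
individually reproducible and composable, and `simulate_dataset()` is
bit-reproducible end to end.

Two planting modes exist because the abundance→index map is strongly
nonlinear: **abundance mode** (above) feeds effects through the entire
pipeline, and **index mode** (`plant_index_effect()`) adds `effect·x`
directly to a phenotype column after computation, isolating the
association-mapping stage for power and calibration studies. Measured on
this generator, an abundance-mode effect of 1 on the log10 abundance of the
three most abundant OTUs shifts the most responsive index only at the
~0.05 significance level at 200 hosts — the descriptor/threshold path
attenuates it — while effects of 3 shift indices at p < 0.001, and
index-mode effects explaining 15% of phenotype variance are recovered as
the top-ranked SNP essentially always at n = 179. Power claims about this
pipeline should therefore be read against index-mode plantings; abundance-
mode plantings answer the harder end-to-end question.

What the generator does **not** emulate: linkage disequilibrium beyond
subpopulation structure, compositionality or sequencing-depth artifacts of
real amplicon data, phylogenetic correlation among OTUs, and zero inflation.
Passing tests on this generator therefore validate the computational
pipeline and its statistical calibration, not robustness to those
real-data features.

## 7. Problem sizes and numerical choices

The bundled analyses and checks run at: pipeline fixture 50 hosts × 40 OTUs
× 500 SNPs; full study scripts 179 hosts × 200 OTUs × 2000 SNPs; null
calibration 30–100 cohorts of 200 hosts × 2000 SNPs; BN validation at 2–4
nodes (exhaustive) and n = 500 chains. These sizes were chosen so the whole
validation battery completes in minutes on a laptop while keeping every
statistical check adequately powered.

Numerical details: PageRank iterates to an L1 tolerance of 1e-13 (capped at
10⁴ iterations); eigencentrality takes the absolute value of the leading
eigenvector (Perron sign ambiguity); min-max normalization with a degenerate
range maps to 0; thresholding is strictly `> tau`; ranking ties in top-k OTU
selection break lexicographically by OTU id; the Wilcoxon tests use the
normal approximation with tie and continuity corrections, with an all-tied
degenerate case returning p = 1 explicitly.

## 8. Known limitations

- Emergent indices of very sparse networks are near-constant across hosts;
  their log-transformed distributions can be strongly non-Gaussian, and
  single-marker t-tests on such degenerate phenotypes should be read with
  the reported per-phenotype lambda in hand.
- The total SNP-h² convention (joint R²) is optimistic when hits are many
  relative to hosts; the ridge fallback bounds but does not remove this.
- Hub calling is cutoff-based; no null model backs the hub/non-hub split.
- The BN learner returns one maximum of a multimodal score surface;
  restarts reduce but do not eliminate local-optimum risk for large hit
  sets.
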