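---
title: "Double-target selection from CRISPR screens and expression networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Double-target selection from CRISPR screens and expression networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Genome-wide CRISPR double-knockout screening of gene pairs is combinatorially
infeasible: 100 genes with 4 guides each already give (4×100)²/2 = 80,000
guide-pair constructs, and 10,000 genes with one guide each would need
50,000,000. `dscn` ranks candidate target *pairs* computationally so that
wet-lab double-knockout screening can concentrate on a short list. The
package is aimed at cancer target discovery, where the pair of interest is a
*synthetic-lethal* (SL) combination: losing both genes kills the cell, losing
either alone does not.

The method deliberately couples two biological compartments:

* **tumor tissue**, where differential expression says which genes matter in
  patients, and
* **cancer cell lines**, where CRISPR knockout screens measure *gene
  essentiality* — the log2 fold change of cell count after knockout (more
  negative = more essential).

Both are laid over the same protein–protein interaction (PPI) skeleton so
results transfer between compartments by shared gene names.

# Networks

For a gene universe (the intersection of all inputs with the PPI skeleton) we
build two weighted networks `G = S + D`:

* the **affinity matrix** `S` holds edge weights: Pearson correlations of the
  two endpoint genes across samples, restricted to PPI edges (tumor samples
  for the tissue network, cell-line expression panels for the cell-line
  network);
* the **diagonal** `D` holds node weights `w_i`: tumor-vs-normal log2
  fold change (difference of log2 means) for tissue, mean log2 essentiality
  across the retained cell lines for the cell-line network.

The Laplacian is `L = D − S`. For spectral clustering the tissue Laplacian is
row-normalized: the diagonal keeps the signed node weight `w_i`, and
off-diagonal `(i, j)` becomes `−|w_ij · w_i| / Σ_k |w_ik|`, so every
connected row satisfies `Σ_{j≠i} |L'_ij| = |L'_ii|`. Notes on this operator:

* With signed fold changes the diagonal is *not* always positive; the row
  identity above is the form that remains true in general, and it is asserted
  as a package invariant (to 1e-9).
* `L'` is genuinely asymmetric; the package never symmetrizes the stored
  matrix.
* Zero-variance genes produce undefined correlations; those edges get weight
  0 with a logged warning. Rows with no edges keep zero off-diagonals and are
  exempt from the row identity.

# Spectral clustering and the number of subnetworks

Eigenvectors of `L'` embed genes; K-means on the embedding yields `K' ≤ 10`
exclusive subnetworks ("local" networks). Three numerical decisions deserve
explanation, because the textbook recipe breaks on this operator:

**Which matrix is decomposed.** `L'` is asymmetric. For positive node
weights, `L' = D_w (I − P)` (with `P` the |edge|-normalized transition
kernel) is similar to the symmetric positive-semidefinite matrix
`D_w^{1/2} (I − D_s^{-1/2} |S| D_s^{-1/2}) D_w^{1/2}`, so its spectrum is
real and non-negative — matching the model's assumption that the spectrum
starts at 0. But its leading eigenvector is constant, which carries no
clustering information. The default therefore decomposes the symmetric part
`(L' + L'ᵀ)/2`, whose spectrum is real and whose small eigenvectors are the
cluster indicators; `eigendecompose(..., symmetrize = FALSE)` exposes the raw
decomposition.

**Negative eigenvalues.** Symmetrization perturbs the near-null indicator
eigenvalues, which can dip a few percent below zero when node weights are
heterogeneous. Excluding negative eigenvalues would discard exactly the
informative directions (in simulation it collapses a planted 3-block
structure to one cluster), so by default the k *smallest* eigenvalues are
selected regardless of sign; `drop_negative = TRUE` restores the strict
non-negative rule and errors when fewer than k non-negative eigenvalues
exist.

**Choosing K with Hartigan's number.** For each candidate `K` the embedding
of width `k = K` is K-means clustered (`nstart = 10`, seeded, so repeated
calls are identical) and
`H(K) = (W_K / W_{K+1} − 1)(n − K − 1)` is computed from the total
within-cluster sums of squares; the smallest `K` with `H(K) ≤ 10` wins,
capped at 10. Because `W_K` and `W_{K+1}` live in embeddings of different
widths (each extra eigenvector contributes roughly one unit of total sum of
squares), the raw ratio is meaningless; each `W` is divided by its
embedding's total sum of squares first, i.e. the ratio compares
*unexplained-variance fractions*. Without this normalization the rule
selected `K' = 1` whenever the leading eigenvector happened to be
near-constant. Degenerate embeddings (all rows identical) give `K' = 1`.

Tissue clusters are mapped onto the cell-line network purely by gene name:
cluster *i* of the tissue network induces the cell-line subnetwork on the
same genes, keeping only internal edges.

# Impact scores

The impact score of a target is its own node weight plus its propagated
effect on the rest of the (local or global) network:
`IS(T1) = S(T1) + Σ_i S[N_i | Pa(N_i)]`. More negative = more impactful.
Three propagation schemes are provided:

* **Most-probable path**: only the immediate neighbors count;
  `IS = w_T1 + min_N (w_N · w_{T1,N})`. With no neighbors the propagation
  term is zero.
* **Random walk**: a single seeded walk of `2n` steps from the target under
  the transition kernel `P[j, i] = |w_ji| / Σ_x |w_jx|` (absolute values: a
  Markov kernel must be non-negative; the *sign* of an edge still enters the
  score through the parent edge weight). Each first-visited node contributes
  `w_i · w_{i,Pa(i)}` with `Pa(i)` the node it was first reached from.
  Averaging several walks is possible (`walk_steps`, per-target seeds) but
  the default is one trajectory, as the model prescribes.
* **Diffusion path** (default): deterministic breadth-first tiers from the
  target; each reachable node contributes `w_i ×` (sum of its edges into the
  tier above + sum of its edges within its own tier). "Tier above" means
  exactly `tier(i) − 1`, and same-tier edges are accumulated once per
  endpoint. A `diffusion_ratio` flag provides the alternative reading that
  divides the edge sum by `w_i` instead of multiplying.

The default configuration is **diffusion on local networks**, the combination
that best separates known SL pairs from other pairs in the benchmark the
method was built on.

# Knockdown subsampling and pair scores

Knockdown of the first target T1 is modeled without any new assay: cell-line
expression samples with T1 expression at or above its mean are removed
(strictly below the mean are kept), and independently essentiality lines with
T1 essentiality at or above its mean are removed. Equality at the mean drops
the sample (the stricter reading); each source must retain at least
`min_samples = 3` samples, otherwise the pair is reported degenerate. The
cell-line network is rebuilt on the subsample — correlations from the kept
expression samples, node weights averaged over the kept lines — and T2 is
scored on it through the *same* tissue clustering (the tissue side is never
re-clustered): that score is `IS(T2 | T1)`.

The pair score is additive, `IS(T1,T2) = IS(T1) + IS(T2|T1)`. Both orders are
evaluated and the smaller (more impactful) ordered score is reported, with
both orders retained; ties prefer the lexicographically first gene. A pair is
**synergistic** when `IS(T1,T2) < IS(T1) + IS(T2)` — algebraically,
`IS(T2|T1) < IS(T2)`, strict — which is exactly a conditional-essentiality
criterion. Rankings ascend by pair score with a lexicographic tiebreak, and a
target whose expression is too flat to subsample is skipped with a warning
rather than aborting a long ranking run.

The per-sample variant (**DSCNi**) scores pairs for one cell line or patient:
node weights are that line's own essentiality vector and stay fixed during
conditional scoring; only the background expression panel is subsampled. Its
scores are on the same scale as the cohort method.

# Subnetwork similarity

As a diagnostic (it does not gate scoring), each tissue/cell-line subnetwork
pair is compared: cell-line node weights are scaled by
`Σw_tissue / Σw_cellline` so traces match; each Laplacian's edge weights are
renormalized to `w_jl · |w_j| / Σ_x |w_jx|` keeping the original edge signs;
and the distance is the sum of squared off-diagonal differences (no square
root, diagonal excluded).

# Drug-synergy association

Given observed drug-combination Bliss scores, a combination is synergistic
when its Bliss score strictly exceeds 0.12. Every drug pair maps to the
unordered cross-drug pairs of its targets; each (combination, target-pair)
mapping event adds one count to a 2×2 table of drug synergy × predicted
target synergy — a target pair mapped by several combinations counts once per
combination. Association is tested with the closed-form Pearson chi-square
(no continuity correction); the odds ratio uses `ad/bc`, with an add-one
correction applied to all cells only when some cell is zero. The add-one
rule, rather than the Haldane–Anscombe 0.5, is what reproduces the published
odds ratio 1,599 from the reported table (2594, 7097, 0, 4375), and is
flagged as an inference from that value.

# The synthetic world

`generator_spec()` / `generate_dataset()` plant every structure the pipeline
is supposed to find, so each stage is testable offline:

* **Expression**: gene blocks share a latent factor;
  `x = √ρ·f_block + √(1−ρ)·ε` on a log2-microarray-like scale (mean 7,
  sd 1), giving within-block correlation ρ (default 0.7) and between-block 0.
  Defaults: 100 tumor, 50 normal, 100 cell-line samples.
* **Fold changes**: every gene is mildly up-regulated in tumors, log2FC ~
  U(0.5, 1.5), with per-gene overrides. Positive-only defaults keep the
  normalized-Laplacian diagonal positive — the regime the clustering model
  assumes — while signed weights remain fully supported by the scoring code.
* **Essentiality**: baseline N(−0.2, 0.5) per gene and line over 30 lines,
  with per-gene mean overrides for planted essential genes.
* **PPI**: within-block edge probability 0.3 plus a guaranteed spanning path;
  between-block probability 0.02; STRING-like scores U(400, 999).
* **Planted SL pairs** `(x, y)`: `y`'s essentiality is shifted by `sl_effect`
  (default −2) in the lines where `x`'s essentiality is below its mean, then
  recentred so `y`'s *marginal* stays at baseline. This matters: synthetic
  lethality is a conditional signal. Planting a marginal essentiality shift
  instead mostly rewards the planted gene's *neighbors* (a node's weight
  enters every nearby target's propagation term with an edge-sum multiplier),
  and the planted pair drowns. The conditional, marginal-preserving shift is
  exactly the signal the knockdown subsampling is designed to expose.

What a green test establishes — and what it does not: the generator draws
independent Gaussian samples with block-factor correlation. It does not
emulate microarray probe effects, batch structure, heavy-tailed expression,
dependence between expression and essentiality beyond the planted SL
structure, or hub-dominated PPI degree distributions. Recovery results on
this world certify the algorithmic chain, not performance on real cohorts.

# Numerical choices and edge cases

* Correlations use pairwise-complete observations and require ≥ 3 samples;
  NaN correlations (zero variance) become 0 with a warning.
* Eigenvalues within `1e-8 · max(1, |λ|_max)` of zero are treated as zero.
* Isolated nodes: absorbing in the random walk (self-probability 1),
  excluded from diffusion tiers; an isolated target scores its bare node
  weight.
* K-means ties and empty clusters are handled by `stats::kmeans` with
  `nstart` restarts under a per-K derived seed; cluster ids are relabeled in
  order of first appearance so runs are bit-identical.
* All ranking ties break lexicographically on `(gene1, gene2)`.
* The run configuration is JSON (schema-validated, unknown keys rejected)
  rather than YAML, because no YAML parser is part of the package's
  dependency footprint; every knob above is a key.

# Known limitations

* Diffusion-score monotonicity under edge additions holds when tiers are
  stable; adding an edge that re-tiers a node can reassign a term between
  endpoints and is not monotone in general.
* Hartigan's threshold-10 rule is sample-size sensitive: splitting one tight
  Gaussian cluster removes ~30% of the within sum of squares, so the rule
  accepts the true K only for modest n (tens of points per cluster); on
  larger embeddings it over-splits, which the `k_max = 10` cap bounds.
* Pair rankings are dominated by cluster composition (the propagation term
  sums the whole local network); the conditional synergy *flag* is the
  per-pair signal, and the global ranking should be read within clusters.
* The similarity table is reported, not used for filtering, because no
  downstream decision rule is defined for it.
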