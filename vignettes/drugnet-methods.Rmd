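---
title: "Methods: from competition pulldowns to network-normalized drug-disease scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from competition pulldowns to network-normalized drug-disease scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugnet)
```

# The analysis in one paragraph

Chemical proteomics with immobilized kinase inhibitors recovers, per drug
and cell type, a table of proteins with spectral counts and sequence
coverage, in replicate, with and without excess free drug (competition).
`drugnet` turns those tables into per-drug target profiles, diffuses the
profiles and a disease gene model over a protein-protein interaction (PPI)
network by random walk with restart (RWR), and summarizes the overlap of
the two diffusion limits in a deletion-weighted correlation score.  Because
every drug binds a different number of proteins with different strengths,
raw scores are not comparable across drugs; each drug's score is therefore
normalized into an empirical p-value against the same drug scored on a
catalog of unrelated disease gene sets.  A low p-value means the drug's
network influence concentrates on the disease-influenced part of the
proteome.

# Target deconvolution

**Specificity gate.** For each (drug, cell type, protein) the average
spectral count is computed over all uncompeted replicates and over the
competed run(s); a replicate in which the protein was not detected counts
as 0.  A protein is a specific binder when

* the uncompeted/competed ratio is at least 2.0 **and** the average
  uncompeted count is at least 10.0 (`specific_by_ratio`), or
* it is entirely absent from the competed run and the average uncompeted
  count is at least 1.0 (`specific_by_absence`) — absence after competition
  is itself strong evidence, so the count threshold drops.

Proteins failing both rules can still be `rescued` when they are absent
from the uncompeted pulldowns of at least two other drugs in the same cell
type: a sticky background protein would be recovered by every affinity
matrix, so drug-restricted presence suggests true binding that the soluble
drug competed incompletely.  The rescue rule carries no count threshold;
any detected, drug-restricted protein qualifies.  All three thresholds are
exposed as arguments of `specificity_filter()` /
`rescue_by_cross_drug_absence()`.

**Abundance score.** Each specific protein receives
`A = SC x SeqCov` (average uncompeted spectral count times average percent
sequence coverage), a semi-quantitative abundance proxy in the family of
spectral abundance indices.  Non-kinases are down-weighted by a factor
0.25: in a kinase-inhibitor pulldown they are most plausibly indirect
binders riding along in complexes with the kinase targets.  Cell-type
profiles of the same drug are merged by the per-protein **maximum** of A —
the optimal observed binding potential — which makes the merge
associative, commutative and idempotent.

**Replicate-level specificity statistics.** Claims of the form "this
kinase binds drug X but not the others" are tested by comparing the
per-replicate abundance scores of the protein in the two contrast arms
(absent = 0) with a one-sided two-sample Kolmogorov-Smirnov test.  The
statistic is `D = sup_x [ECDF_b(x) - ECDF_a(x)]`, evaluated at every
pooled sample point (this handles the heavy ties produced by zeros), and
the reported p-value is the asymptotic one-sided tail

```
p = exp(-2 D^2 n m / (n + m)),
```

clipped to (0, 1].  With complete separation (D = 1) this reduces to a
function of the replicate counts alone: for quadruplicates in two cell
lines against three other drugs (n = 8, m = 24) it gives `exp(-12) ~
6.1e-6`; for a patient-pool duplicate against the same drug's eight
cell-line runs (n = 2, m = 8), `exp(-3.2) ~ 0.041`; for 8-vs-8 and 4-vs-4
cell-type contrasts, `exp(-8) ~ 3.4e-4` and `exp(-4) ~ 0.018`.  The
asymptotic tail is deliberately the default — at these tiny sample sizes
it is an approximation, but it is smooth in D and directly reproducible
from the formula; the exact conditional permutation tail (which for
complete 4-vs-4 separation gives `1/C(8,4) ~ 0.014`) is available with
`method = "exact"`.

# Network assembly and diffusion

Edge lists from any number of interaction sources are merged into one
undirected simple graph on canonical accessions (`merge_edge_lists()`);
identifiers are translated through an explicit map and unmappable rows are
dropped and counted, never guessed.  Analyses run on the largest connected
component; node order is fixed lexicographically before any matrix is
built, so every vector and matrix in a session shares one reproducible
index.

The diffusion matrix defaults to the column-stochastic normalization
`P[u, v] = 1/deg(v)`: under the RWR update

```
x_{i+1} = (1 - alpha) P x_i + alpha x_0
```

column stochasticity conserves total probability mass at every iterate, so
"a probability distribution over all proteins" is exact, not approximate.
Row and symmetric (`D^-1/2 A D^-1/2`) normalizations are exposed for
comparison.  The restart weight `alpha` defaults to 0.3; it is the
fraction of walk mass returned to the seeds per step and controls how
local the limit stays.  The iteration stops when the L1 change between
iterates falls below `tol = 1e-10` (the update is a contraction with
Lipschitz constant `1 - alpha`, so the limit is unique, convergence is
geometric, and about 65 iterations suffice at alpha = 0.3); `max_iter =
10000` is a safety cap whose violation is an error, not a silent return.

Seed vectors: drug profiles seed proportionally to A; average-patient
disease models seed proportionally to deletion frequency, with the disease
driver added at frequency 1.0; copy-number (cell-line) models give every
gene deleted below copy number -0.5 equal weight plus the driver.
Amplified genes (> +0.5) receive no seed weight — only the deletion rule
is part of the model.  A driver recorded under a fusion name that is not a
network node is translated through an alias table
(`seed_from_targets(..., alias = )`); when an alias collides with an
accession that already carries weight, the maximum is kept, consistent
with the profile merge.

# Correlation scoring and null normalization

With `d` the disease limit, `t` the drug limit and `c_i` the deletion
coefficients (`c_i = 1` off the deletion list, `1 - frequency` on it; the
driver is not a deletion and keeps 1), the score is

```
score = sum_{i in S} c_i d_i t_i,
```

where S holds the `top_n = 500` largest summands — roughly 5% of the
nodes of an interactome-scale network, enough to capture the overlap
region while excluding the long tail of near-zero products.  The
deletion coefficient encodes that a frequently deleted gene's product is
often absent and thus a poor conduit for drug effect.  By default S is
ranked by the full summand `c_i d_i t_i`; ranking by the bare product
`d_i t_i` is available (`rank_by = "product"`).  With `c = 1` and
`top_n = |V|` the score reduces exactly to the inner product of the two
limits, which the test suite exploits as a closed-form check.

Null normalization scores the same drug model against diffusion limits of
unrelated disease gene sets.  Null sets are plain gene lists; they are
seeded with equal weights and scored with all-ones coefficients, since no
deletion frequencies exist for them.  The default p-value is the add-one
empirical tail `(1 + #{null >= observed}) / (1 + N)` — conservative,
never 0, bounded below by `1/(N+1)` — with a Gaussian-fit upper tail as an
option for short null lists.  Drugs are ranked per disease model by
ascending p-value, ties broken by descending raw score, then name.  No
multiple-testing correction is applied across drugs.

The hypergeometric check `interactor_enrichment()` quantifies the premise
that non-kinase specific binders are complex partners of the kinase
targets: with N network nodes, K distinct non-kinase neighbors of the
kinase set and k of the n non-kinases among them, it reports the upper
tail P(X >= k).  Kinase self-interactions are excluded from the neighbor
set and the universe is the connected component in use.

# What the synthetic generator emulates

The generator exists so the whole pipeline can be exercised, benchmarked
and regression-tested without proprietary mass-spectrometry tables or
database dumps.  Its defaults mirror the experimental design the analysis
was built for:

* **Network**: preferential attachment (3 edges per new node), because
  curated interactomes are heavy-tailed; an Erdos-Renyi variant exists for
  comparison.  A 1000-node benchmark network stands in for the
  ~13,000-node interactome.
* **Design**: 4 drugs x 2 cell types x 4 uncompeted replicates, plus one
  competed run per drug per cell type (competition in singlicate, as is
  standard practice for these experiments).
* **Counts**: negative binomial with dispersion 0.25 (variance `mu +
  0.25 mu^2`), Poisson at dispersion 0.  Spectral counts are
  overdispersed across replicates; the NB is a modeling choice, not a
  measured distribution.
* **Targets**: per-drug affinities uniform in [20, 60] expected counts,
  scaled per cell type by expression factors (1.0, 0.8).  Indirect
  binders are sampled PPI neighbors of planted targets at 0.3 of the
  recruiting target's affinity.  Competition multiplies both by 0.1.
* **Background**: 5% of the proteome, mean count 2, *unchanged by
  competition*, and drawn with a minimum count of 1: background binders
  model the sticky proteins (ribosomes, cytoskeleton, chaperones) that
  every affinity matrix recovers consistently.  Without that floor, a
  background protein would occasionally be missing from the competed
  singlicate by sampling chance alone and masquerade as
  `specific_by_absence` — a pattern real background proteins do not show.
* **Coverage**: `100 SC / (SC + 20)` — monotone, saturating, bounded in
  (0, 100]; 20 is the count at half-saturation.
* **Disease**: 11 deleted genes with frequencies uniform in [0.07, 0.84]
  plus a driver at 1.0, matching the frequency span of recurrent
  deletions in the leukemia setting the score was designed for.
* **Effective drug**: when a disease model is supplied, one drug's targets
  are drawn from the *distance-1 ring* of the disease genes, topping up
  from distance 2 only if the direct neighborhood is too small; the other
  drugs' targets are placed uniformly.  Direct adjacency is the faithful
  emulation of an effective kinase inhibitor, whose targets physically
  complex with the driver and other disease proteins.  Sampling uniformly
  over the whole distance-2 ball would be much weaker: in a scale-free
  graph the 2-hop neighborhood of a dozen seeds reaches a large share of
  the graph through hubs, making "near" placement statistically close to
  random placement.

What it does **not** emulate: peptide-level identification, protein
grouping and FDR control (generation starts at the protein table);
expression-abundance correlation structure between proteins; interaction
false positives/negatives in the network; batch effects between cell
types beyond a scalar expression factor.  Consequently, a passing
benchmark shows the *pipeline logic* recovers planted signal under
realistic counting noise — it does not certify performance on real
eluate tables, where specificity errors and network incompleteness
dominate.

# Benchmarks the test suite runs

Problem sizes were chosen so the full suite exercises realistic structure
while remaining quick to run routinely:

* KS arithmetic at the four reconstructable replicate-count contrasts.
* RWR limits vs. the direct resolvent solve `alpha (I - (1-alpha)P)^-1
  x0` on 50 random connected graphs of up to 100 nodes (L-infinity 1e-8),
  with mass conservation checked at every iterate.
* Correlation score vs. its inner-product closed form, and top-n
  selection vs. an exhaustive sort oracle.
* Hypergeometric tails vs. brute-force subset enumeration on 100 random
  graphs of up to 30 nodes.
* Planted-drug recovery: 50 simulated studies (1000-node network, 4
  drugs, 100 null sets) in which the drug whose targets neighbor the
  disease genes must rank first in at least 90% of runs, with its rank
  stable across `top_n` in {250, 500, 1000}.
* Gate recovery: over 50 simulated studies, precision and recall of the
  specificity gate for planted direct targets of at least 0.9 each
  (indirect binders are genuinely drug-dependent and are not counted as
  false positives).

# Numerical and degenerate-input choices

* Tie-breaks are deterministic everywhere: lexicographic node order for
  matrix indexing and top-n selection, smallest-accession component on
  LCC ties, score-then-name on ranking ties.
* `D <= 0` in the KS test short-circuits to p = 1; the asymptotic tail is
  clipped to (0, 1].
* A drug with no specific proteins yields an empty profile with a
  warning, not an error; an empty seed (nothing maps to the network) is
  an error, because a diffusion limit of nothing is not meaningful.
* Generators restore the caller's RNG state; every stage draws from a
  substream derived from one master seed, so datasets are bit-identical
  under a fixed seed and independent of call order.
* The analysis stage (`analyze_dataset()`, `run_pipeline()`) contains no
  randomness at all; reruns are bit-identical.

# Known limitations

* The asymptotic KS tail is approximate for the tiny replicate counts it
  is applied to; it is used because it is exactly reproducible from
  (D, n, m), with the exact tail one flag away.
* Empirical p-values are bounded below by `1/(N+1)`; with 100 null sets
  the best attainable p is ~0.0099, so ranking resolution, not
  significance depth, is the design goal.
* The deletion-coefficient score treats deletions as the only genomic
  alteration class; amplifications are flagged but unscored.
* Null disease sets are scored with equal seed weights and unit
  coefficients; observed disease models carry deletion-weighted seeds and
  coefficients.  The comparison is therefore slightly conservative for
  the observed model.
```{r session}
sessionInfo()
```
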