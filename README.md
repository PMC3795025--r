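# drugnet

Integrated chemical-proteomics and network-diffusion analysis for kinase
inhibitors: from competition-pulldown spectral-count tables to drug target
profiles, through random walk with restart on a protein–protein
interaction (PPI) network, to a deletion-weighted drug–disease correlation
score normalized against null disease models.

## The problem

Multi-targeted kinase inhibitors bind dozens of cellular proteins, and
which binding events matter depends on the disease context: a drug is
promising for a tumor driven by a fusion kinase and recurrent gene
deletions when its *network influence* lands on the part of the proteome
the disease perturbs.  `drugnet` implements that reasoning end to end for
anyone with (a) replicate drug pulldown tables with competition controls,
(b) a PPI edge list, and (c) a disease gene model (deletion frequencies or
copy numbers).  A synthetic-data module generates all three with realistic
statistical structure, so the pipeline can be exercised and benchmarked
without proprietary inputs.

## The method

1. **Specificity gate.** A protein is a specific binder of a drug when its
   uncompeted/competed average spectral-count ratio is ≥ 2.0 with average
   uncompeted count ≥ 10.0, or when it vanishes from the competition run
   (count threshold lowered to 1.0).  Proteins absent from ≥ 2 other
   drugs' pulldowns are rescued.  Per-protein abundance is scored as
   `A = SC × SeqCov` (× 0.25 for non-kinases); cell-type profiles merge by
   per-protein maximum.  Replicate-level specificity claims get one-sided
   two-sample Kolmogorov–Smirnov p-values `exp(−2D²nm/(n+m))`.
2. **Diffusion.** Drug profiles (seeds ∝ A) and disease models (seeds ∝
   deletion frequency, driver at 1.0) are diffused over the PPI network's
   largest connected component by the random walk with restart
   `x_{i+1} = (1−α)·P·x_i + α·x_0` with a column-stochastic `P` and
   α = 0.3, iterated to an L1 residual below 1e-10.
3. **Scoring.** With `d` and `t` the disease and drug limits and
   `c_i = 1 − deletion frequency` (1 off the deletion list), the score is
   `Σ_{i∈S} c_i·d_i·t_i` over the `top_n = 500` largest summands.  Each
   drug's score is normalized into an empirical p-value against the same
   drug scored on unrelated (null) disease gene sets, and drugs are ranked
   per disease model by ascending p-value.

See `vignettes/drugnet-methods.Rmd` for the full model description,
parameter rationale, and the limits of what the synthetic benchmarks show.

## Worked example

Simulate a 1000-node study — 4 drugs × 2 cell types in quadruplicate with
singlicate competition, one drug's targets planted next to the disease
genes — and run the full analysis:

```r
library(drugnet)
cfg <- sim_config(n_proteins = 1000, seed = 42)
ds  <- simulate_dataset(cfg, n_null_sets = 100)
report <- analyze_dataset(ds$pulldowns, ds$network,
                          list(average_patient = ds$disease), ds$null_sets)
print(report$rankings$average_patient)
#>     drug   disease_model       score n_null    p_value rank
#> 1 drug01 average_patient 0.002352256    100 0.08910891    1
#> 2 drug03 average_patient 0.001154784    100 0.78217822    2
#> 3 drug02 average_patient 0.001068580    100 0.88118812    3
#> 4 drug04 average_patient 0.001010459    100 0.91089109    4
ds$truth$effective_drug
#> [1] "drug01"
```

The drug whose planted targets neighbor the disease genes (`drug01`)
receives the highest correlation score and the lowest null-normalized
p-value: only ~9% of unrelated disease gene sets score as well against
its treatment model, while the three uniformly-targeted drugs are
indistinguishable from their nulls.  Its deconvolved profile:

```r
print(report$profiles$drug01)
#> <target_profile> drug01: 24 specific protein(s)
#> P00585 P00331 P00351 P00600 P00301
#> 5406.6 4359.2 2432.9 2152.0 1810.8
```

A kinase seen in all 8 replicates of one drug (two cell lines) and in none
of the other three drugs' 24 runs gets the specificity tail:

```r
ks <- ks_specificity_pvalue(rep(50, 8), rep(0, 24))
#> D = 1, p = 6.14e-06
```

`run_pipeline("config.yaml")` performs the same analysis from files
(pulldown TSV, edge-list TSV, disease JSON, null-set TSV) and writes every
intermediate table, a run manifest and a markdown report to an output
directory; `simulate_dataset(cfg, dir = ...)` writes a matching input
bundle.

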