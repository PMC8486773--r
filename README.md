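# lopitdyn

Dynamic spatial and temporal proteomics analysis in R.

`lopitdyn` is for experiments that ask not only *how much* of each protein
a cell makes over time, but *where* each protein resides — and how both
change after a stimulus. It pairs two data types:

- **Subcellular fractionation profiles** (hyperLOPIT-style): each protein's
  relative abundance across density-gradient fractions quantified by TMT
  channels, measured in two conditions (e.g. unstimulated vs stimulated).
  Profile shape encodes organelle residency.
- **Whole-proteome time courses**: protein x timepoint x replicate
  abundance matrices.

## What it computes

**Spatial branch.** Proteins are classified into subcellular compartments
with a semi-supervised **T-augmented Gaussian mixture (TAGM)** fitted by
collapsed Gibbs MCMC: one Gaussian component per marker-defined
compartment (11 niches by default) plus a heavy-tailed multivariate-t
outlier component, yielding for every protein a joint posterior
probability per compartment and an outlier probability. Allocation is
conservative (posterior > 0.999 and outlier probability < 1e-6, otherwise
"unknown"). Comparing the pooled posteriors between conditions gives each
protein a normalised L2 posterior distance

  d(x, y) = ||x − y||₂ / √2  ∈ [0, 1],

which equals 1 exactly when all certainty moves from one compartment to
another, and translocation events are typed: organelle→organelle (1),
unknown→organelle (2), organelle→unknown (3), and unassigned-in-both with
a (near-)maximal posterior shift (4).

**Temporal branch.** Paired moderated t-tests (empirical-Bayes variance
shrinkage, BH correction, calls at adjusted p ≤ 0.01 and |log2FC| ≥ 0.6)
per timepoint against 0 h; and Bayesian nonparametric clustering of
standardised profiles with a **Dirichlet-process mixture of Gaussian-
process regressions** (squared-exponential kernels, shared latent curve
per cluster, cluster number inferred), summarised through the posterior
similarity matrix by maximising the posterior expected adjusted Rand
index, with a replicate-consensus extraction step. Fisher's exact and
hypergeometric tests link clusters to compartments and to annotation
terms.

**Preprocessing and simulation.** PSM quality filtering with the standard
TMT thresholds, mechanism-aware imputation (kNN for MAR, left-censored
minima for MNAR), median PSM→protein aggregation, sum normalisation and a
glog-based variance-stabilising transform — plus seeded synthetic-data
generators that emulate the full data structure (compartment profiles on
the simplex, planted movers of all four types, co-regulated time-course
clusters, planted differential abundance, PSM tables with quality
violations and missingness) together with ground truth for validation.

## Worked example

Simulate a two-condition spatial experiment with 110 markers, 120
unlabelled proteins and five planted movers of each type, then run the
full spatial pipeline (classification in both conditions, translocation
typing, ranking):

```r
library(lopitdyn)
cfg <- spatial_sim_config(n_markers_per_class = 10, n_unknown = 120,
                          mover_counts = c("1" = 5, "2" = 5,
                                           "3" = 5, "4" = 5),
                          seed = 42)
sim <- generate_spatial_pair(cfg)
res <- run_spatial(sim$expr_a, sim$expr_b, sim$markers,
                   pipeline_config(tagm_chains = 3, tagm_iter = 1500,
                                   l2_type4_threshold = 0.5, seed = 1))

table(res$allocation_a$label)
#>       chromatin         cytosol              ER Golgi apparatus        lysosome
#>              22              21              18              20              17
#>    mitochondria       nucleolus         nucleus      peroxisome              PM
#>              20              16              22              22              18
#>        ribosome         unknown
#>              14              20

head(res$movers[, c("accession", "label_A", "label_B", "type", "l2")], 5)
#>   accession         label_A         label_B type l2
#> 1    P00127 Golgi apparatus       chromatin    1  1
#> 2    P00133 Golgi apparatus         nucleus    1  1
#> 3    P00151         nucleus      peroxisome    1  1
#> 4    P00157        lysosome Golgi apparatus    1  1
#> 5    P00212    mitochondria         cytosol    1  1

recover_planted_movers(res$records, sim$truth)
#>   type planted detected tp recall precision
#> 1    1       5        5  5      1         1
#> 2    2       5        5  5      1         1
#> 3    3       5        5  5      1         1
#> 4    4       5        5  5      1         1
```

The allocation table shows 230 proteins assigned across the 11 niches and
20 left "unknown" (planted outliers, ambiguous boundary profiles, and the
unassigned side of type-2/3 movers). The mover table ranks candidates by
their normalised L2 distance — the top entries are organelle→organelle
events at the maximal distance of 1 — and the recovery table confirms all
twenty planted translocations are detected with their correct type (the
type-4 screen here uses the softer distance cut of 0.5; see the methods
vignette). The temporal branch is driven the same way through
`generate_timecourse()` and `run_temporal()`.

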