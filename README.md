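# fateflow

Optimal-transport fate mapping for longitudinal single-cell expression
data.

Single-cell RNA-seq destroys the cells it measures, so a time course is a
sequence of unlinked snapshots — while the underlying population (the
motivating case is antigen-specific CD8 T cells responding to acute viral
infection) expands, contracts, differentiates into branching fates and
migrates between anatomical compartments. `fateflow` reconstructs the
links: it fits entropic **unbalanced optimal transport** (UOT) couplings
between adjacent timepoints and derives the downstream fate-level
quantities from them. It is aimed at computational immunologists and
single-cell analysts who need trajectory inference that tolerates
proliferation, death and migration.

Between adjacent timepoints with source/target marginals $a, b$ and local
PCA Euclidean costs $C$, the coupling solves

$$\min_{P\ge 0}\ \langle P, C\rangle - \epsilon H(P)
 + \lambda_a\,\mathrm{KL}(P\mathbf 1\|a)
 + \lambda_b\,\mathrm{KL}(P^\top\mathbf 1\|b),
 \qquad \tau = \tfrac{\lambda}{\lambda+\epsilon},$$

via log-domain Sinkhorn iterations (RcppArmadillo). Source marginals come
from proliferation/apoptosis gene-set scores: clipped differentials
$\delta_i$ give growth factors $g_i = \exp(\delta_i \Delta t/\sigma)$ with
$\sigma$ calibrated so the fastest cell doubles three times per day
($g_{max} = 2^3 = 8$). On top of the couplings the package computes:

- population-size reconstruction $N_t = N_{t-1}\,\overline{g_i(t)}$;
- fate-flow inflow/outflow matrices and Sankey exports;
- barycentric projections and per-gene trajectory (Spearman) correlations
  that separate lineage-stable from transiently expressed genes;
- trajectory kernel mean embeddings (TKME: Nystroem RBF features
  barycentrically projected across timepoints) and Leiden/k-means
  trajectory clustering;
- fate entropy and consistency scores;
- compartment egress probabilities and tissue arrival-time estimates;
- debiased Sinkhorn (earth mover's) distances between cell populations;
- composite-score cell-state annotation with day-window masks, and
  windowed-DTW + k-medoids temporal gene modules;
- a ground-truthed two-compartment birth-death-migration simulator that
  makes every component testable without downloads.

## Worked example

```r
library(fateflow)

sim <- defaultBenchmark(seed = 1)        # ground-truthed benchmark
tc  <- normalizeLog1p(filterGenes(filterCells(sim$tc)))
tc
#> TimeCourse: 970 genes x 3759 cells
#>   timepoints (days): 0, 3, 4, 5, 7, 10, 14, 28
#>   compartments: siIEL, spleen
#>   normalized: TRUE

## growth-calibrated population kinetics (no coupling needed)
pri <- timecourseGrowthPriors(tc, sim$sets$proliferation,
                              sim$sets$apoptosis)
populationSizes(pri, N0 = 1000)$day[which.max(populationSizes(pri)$N)]
#> [1] 7        # reconstructed expansion peak; the simulator's true peak day

## transport maps on the circulating compartment
spl <- tc[, tc$compartment == "spleen"]
hvg <- selectHVG(spl, 300)
maps <- fitTimecourseMaps(spl, priors = timecourseGrowthPriors(
          spl, sim$sets$proliferation, sim$sets$apoptosis),
        config = solverConfig(0.01, 0.95, 0.9995, scaleCost = TRUE),
        hvg = hvg)
maps[["5->7"]]
#> TransportMap 5 -> 7 days: 300 x 300 cells
#>   epsilon=0.01 tauA=0.95 tauB=0.9995 | cost=15.29 | converged (202 iters, ...)

## trajectory embedding and clustering
gb <- fitBasis(spl, "global_pca", nComponents = 30, hvg = hvg)
Z  <- tkmeEmbed(gb@coords, setNames(spl$timepoint, colnames(spl)), maps,
                d = 50, includeDaysAfter = 6, seed = 1)
labels <- clusterTrajectories(Z, "kmeans", k = 4, seed = 1)
table(labels)
#> labels
#>   1   2   3   4
#> 558 567 696 458   # four trajectory clusters tracking the planted fates
```

The numbers above are what the code prints at seed 1: the reconstructed
population series peaks at day 7 (the configured expansion peak), and the
four trajectory clusters recover the planted memory / terminal /
early-effector / intermediate branches with adjusted Rand index ≈ 0.89 on
post-activation cells.

`runPipeline()` orchestrates the full workflow (preprocess → marginals →
transport → trajectories → migration) and writes CSV tables plus a
provenance manifest; `inst/scripts/fateflow` is a thin command-line wrapper
with `simulate` and `run` subcommands.

## Vignette

`vignettes/fate-mapping-methods.Rmd` documents the transport model and its
hyperparameters, the growth-prior calibration, the TKME construction, the
arrival-time estimator, the simulator's generative model, and the design
decisions and known limitations (including which contrasts are not
discriminative at desk scale and why).
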