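# apmswalk

Context-specific AP-MS interactome analysis: high-confidence interactor
calling, GO-term functional analysis, and biased targeted random walks that
attribute functional outputs to individual effector pathways.

## The problem

Affinity-purification mass spectrometry (AP-MS) against a tagged bait —
prototypically KRAS, a hub GTPase whose effectors (RAF1, BRAF, PIK3CA,
AFDN, ...) compete for the same binding surface — yields one label-free
quantification (LFQ) matrix per combination of *genetic context* (bait
variant: WT, G12D, G12V, G12C) and *culture context* (growth stimulus and
concentration). The scientific questions are:

1. Which proteins are high-confidence interactors in each condition,
   given bead-only control runs and heavy, structured missingness?
2. Which biological processes (GO terms) differ between conditions?
3. Through which effector pathways does information flow from the bait to
   the proteins that carry out each process?

`apmswalk` implements the full analysis as a tested, reusable R package,
with seeded synthetic-data generators in place of raw MS deposits so every
stage runs at desk scale.

## The methods

**Interactor calling** is a five-step filter on the LFQ matrix: (i) drop
proteins flagged "only identified by site" / "potential contaminant" /
"reverse"; (ii) treat LFQ = 0 as missing; (iii) remove outlier runs with
abnormally low coverage or intensity; (iv) keep a protein in a condition
group only if observed in >= 60% of its (3 biological x 2 technical) runs;
(v) classify remaining missing values as MNAR (absent in a whole group:
below detection) or MAR, impute them (detection-limit floor / kNN), and
test each condition against the bead control with an empirical-Bayes
moderated t — the posterior variance is
s²_post = (d₀·s₀² + df·s²)/(d₀ + df) with (d₀, s₀²) estimated by method of
moments on log variances — calling interactors at BH-adjusted p < 0.01 and
log₂FC > 1. Technical replicates are merged by the median.

**Functional analysis** runs two routes: gene set enrichment (weighted
KS running-sum statistic, gene-label permutation null) on the moderated
statistics, and a collapse of LFQ intensities onto GO terms (summing all
identified annotated proteins per sample) followed by a per-term factorial
ANOVA (Type-II SS) whose p-values are corrected collectively with Hommel's
procedure, Tukey HSD post-hocs under collective BH, Wang graph-based
semantic similarity, and binary-cut clustering of the significant terms.

**Pathway attribution** builds a network from a confidence-scored edge
list (edges < 0.7 removed; nodes > 4 hops from the nearest effector
removed; the source connects by directed edges to its effectors only) and
runs targeted random walks from the source to each target with the biased
step rule

    P(step to neighbour in AP-MS set) = 20 · P(step to neighbour not in set)

normalized over the neighbourhood, and walk length = shortest path + 2.
Paths below frequency 1e-6 (the scale-free form of 100 per 1e8 walks) are
dropped, the top 10 per target are retained, and retained paths are
decomposed into condition-specific information-flow networks and effector
traversal weights. An exact depth-limited enumeration of path
probabilities serves as the engine's oracle.

## Worked example

```r
library(apmswalk)

grid <- design_grid(genetic = c("WT", "G12D"), stimuli = "DMOG",
                    concentrations = "20")
sim <- simulate_lfq(sim_config(n_proteins = 100, grid = grid, seed = 7))
flt <- run_filter_pipeline(sim$dataset)
flt$report
#>             step n_proteins n_runs n_observations
#> 1          input        100     30           2536
#> 2 remove_flagged        100     30           2536
#> 3      drop_zero        100     30           2536
#> 4   outlier_runs        100     30           2536
#> 5       presence        100     30           2536
head(flt$interactors$G12D.DMOG.20, 4)
#> [1] "P0010" "P0035" "P0043" "P0058"
```

Against the generator's ground truth this run recovers 95% of the planted
condition-specific interactors. The walk module, on a simulated effector
network:

```r
net <- simulate_network(30, 5, 3, seed = 1)
net
#> effector_network: 30 nodes, 75 undirected edges, source KRAS -> 3 effectors
spec <- walk_spec(target = setdiff(net$nodes, net$effectors)[10],
                  n_walks = 1e5,
                  evidence = c(head(setdiff(net$nodes, net$effectors), 4),
                               net$effectors[1]),
                  seed = 2)
head(filter_and_rank_paths(run_walks(net, spec)), 3)
#>                           path count    freq
#> 1             KRAS->N001->N011  3474 0.03474
#> 2 KRAS->N001->N004->N001->N011  1168 0.01168
#> 3 KRAS->N001->N024->N001->N011   134 0.00134
```

The ranked paths show the dominant route entering through the in-evidence
effector `N001`; `effector_traversal()` sums the retained-path frequencies
per effector, and `effector_traversal_matrix()` assembles the
effectors-by-conditions heatmap matrix.

The whole pipeline (simulate -> filter -> GSEA -> collapse/ANOVA ->
semantic clustering -> walks) runs from one config via
`run_pipeline(pipeline_config(out_dir = "run1", seed = 1))`, writing TSV
artifacts and a manifest; `inst/cli/apmswalk.R` is a thin Rscript front
end with `simulate` / `filter` / `walk` / `run-all` subcommands.

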