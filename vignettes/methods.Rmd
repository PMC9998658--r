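---
title: "Methods: from LFQ matrices to effector pathway attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from LFQ matrices to effector pathway attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmswalk)
```

# Scope and data model

`apmswalk` analyses context-specific AP-MS experiments: a bait protein is
pulled down under a grid of *genetic contexts* (bait variants WT, G12D,
G12V, G12C) crossed with *culture contexts* (an unstimulated minimal
medium plus stimuli DMOG, EGF, IL6, PGE2, TNFa at 20 or 200 ng/ml), with
3 biological x 2 technical replicates per condition and a set of
bead-only control runs. With the full grid this is 44 conditions and 264
sample runs (`design_grid()`).

The central carrier is the `lfq_dataset`: a proteins x runs matrix of
label-free quantification (LFQ) intensities with run metadata and protein
identification flags. Missing observations are `NA`; MaxQuant-style
exports encode non-observation as 0, and the distinction is introduced
deliberately by the zero-removal filter, not at load time, so that the
loaded table is a faithful image of the export.

# Interactor calling

The filter runs five steps in a fixed order; the order matters (the test
suite pins it with a fixture that would pass the presence filter if zeros
still counted as observations):

1. **Flag removal** — proteins marked "only identified by site",
   "potential contaminant" or "reverse" are removed.
2. **Zero removal** — LFQ = 0 becomes `NA`.
3. **Outlier runs** — a run is removed if its observed-protein count is
   below `min_proteins` (default: half the cohort's median count) or its
   median log2 intensity is more than `mad_k = 3` MADs below the global
   median of run medians. The published analyses typically do this step by
   visual histogram inspection; an explicit count + MAD rule makes it
   reproducible and testable. If every run is flagged the filter aborts:
   that indicates a broken input, not an outlier.
4. **Presence** — within each condition group (and the control group), a
   protein must be observed in at least 60% of the group's runs *after*
   outlier removal; a removed run carries no evidence, so it is excluded
   from the denominator. A protein is dropped globally only if it
   survives in no group.
5. **Control enrichment** — per condition, missing values are classified
   per (protein, group): missing in *all* runs of a group while observed
   elsewhere is MNAR (below the detection limit), anything else is MAR.
   MAR cells are imputed by kNN over proteins (k = 10, Euclidean distance
   on shared observed runs, inverse-distance-weighted mean; run-median
   fallback with a warning when fewer than k usable neighbours exist).
   MNAR cells are imputed at the dataset's minimum observed log2
   intensity — a detection-limit floor. A literal zero on the log2 scale
   would inject an arbitrary, scale-dependent value far below any
   observed intensity; the floor preserves the "below detection"
   semantics while keeping variances finite. A `floor_value = 0` override
   exists for users who want the literal behaviour.

The test is an empirical-Bayes moderated t: per protein, the pooled
two-group variance s² with df = nA + nB − 2 is shrunk to
s²_post = (d₀·s₀² + df·s²)/(d₀ + df), and t = log₂FC / (s_post·√(1/nA+1/nB))
is referred to t with df + d₀ degrees of freedom. The hyperparameters
(d₀, s₀²) are estimated by method of moments on log variances: with
e_g = log s²_g − ψ(df/2) + log(df/2), the excess of Var[e] over ψ′(df/2)
estimates ψ′(d₀/2) (inverted by Newton iteration), and the mean of e
gives s₀². At d₀ = 0 the statistic is exactly the classical pooled t (a
unit test asserts this limit); the suite also cross-checks the moment
estimates against an independent implementation. Calling uses BH-adjusted
p < 0.01 within each condition and log₂FC > 1.

Technical replicates are merged by the median over observed values; an
all-missing pair stays missing.

# Functional analysis

**Route 1 — GSEA.** The moderated statistics are ranked and scored with
the weighted running-sum statistic: walking down the ranking the sum
gains |score|^p (p = 1 by default; p = 0 gives the classical KS form) at
set members and loses 1/(N − |S|) otherwise; ES is the signed maximum
deviation. The null is *gene-label* permutation — random sets of the same
size — because per-condition sample sizes (6 runs) are far too small for
phenotype permutation. The permutation p is (1 + #{|ES*| ≥ |ES|})/(B + 1),
BH-adjusted across sets. A set spanning the whole ranking is degenerate
and scores 0.

**Route 2 — collapse + ANOVA.** Direct annotations are propagated up the
ontology (true-path rule), then per term and sample all identified
annotated proteins' raw-scale intensities are summed. The per-term scan
fits a factorial ANOVA on log2(1 + sum): term sums are sums of
log-normals, so factor effects are closer to additive on the log scale —
this is the package's choice, as the published description leaves the
scale open. Type-II sums of squares are used because post-filter designs
are unbalanced (Type-II equals sequential SS on balanced designs, which
the suite asserts); interaction terms with no estimable column are
dropped and reported. Terms with fewer than 3 annotated identified
proteins are excluded for stability. All term x effect p-values are
corrected *collectively* with Hommel's closed-testing procedure; terms
significant at adjusted p < 0.05 get Tukey HSD post-hocs
(studentized-range p, Tukey–Kramer SEs for unequal group sizes), whose
p-values are collectively BH-adjusted. Fits with zero residual SS are
flagged degenerate and return no F statistic rather than an infinite one.

**Semantic clustering.** Term–term similarity is Wang's graph-based
measure: S-values propagate multiplicatively along edges (is_a 0.8,
part_of 0.6, maximum over paths), and similarity is the S-mass on common
ancestors over the total S-mass. The package picks the Wang measure as
the canonical companion of binary-cut clustering; the cited methodology
admits information-content variants, which would require an annotation
corpus the desk-scale pipeline does not assume. The published binary-cut
algorithm has several scoring variants; the one implemented here is:
a term set whose mean off-diagonal similarity reaches the
`cut_score_threshold` (default 0.85) becomes one cluster, otherwise it is
split in two by average-linkage clustering on 1 − similarity and both
halves recurse. This reproduces the canonical behaviours (two perfect
blocks give exactly two clusters; an identity matrix gives singletons)
and is deterministic. Note the direction it implies: a *higher* threshold
is a stricter cohesion bar and can only produce *more* clusters — the
property suite asserts cluster counts non-decreasing in the threshold.

**Phenotype comparison.** LS-mean tables are radar-normalized by dividing
each parameter row by its maximum (negative entries are rejected as out
of the defined domain; an all-zero row is returned unchanged), and
parameter-vs-term-sum agreement is summarized by a plain Pearson matrix
over matched groups.

# Biased targeted random walks

The network is built from a scored undirected edge list: edges with
confidence < 0.7 are removed first ("less than" is strict, so a score of
exactly 0.7 survives); nodes farther than 4 hops from the nearest
effector are removed; the source is attached afterwards with *directed*
edges to the effectors only, so the source can never be re-entered.
Duplicate undirected edges keep the maximum score — conservative against
discarding high-confidence evidence.

A walk starts at the source; at each node the next step is drawn with
weight 20 for neighbours in the condition's AP-MS evidence set and 1
otherwise, normalized over the neighbourhood — so the actual
probabilities depend on the number of connecting nodes, but the pairwise
rule P(in) = 20·P(not in) always holds. The walk absorbs at its target
and fails after walklen = shortest path + 2 steps ("iterations exceeded"
is read as one iteration = one step). Walks may revisit nodes: the bias
rule is memoryless and nothing in the procedure forbids revisits; a
no-revisit mode is deliberately *not* the default because it would change
the Markov structure the exact oracle assumes.

`enumerate_paths_exact()` expands every node sequence within the depth
limit with its exact probability (guarded at 1e6 partial states); path
probabilities plus the failure mass sum to one, and the stochastic engine
is required — in the acceptance suite — to match it within binomial
sampling error and total-variation distance < 0.01 at 1e6 walks.

Path post-processing drops paths below frequency 1e-6 — the scale-free
form of the production cut of 100 per 1e8 walks; the desk default is 1e5
walks per target with the same threshold — and keeps the top 10 per
target, with deterministic tie-breaking (shorter path first, then
lexicographic). Retained paths are decomposed into directed
consecutive-node edges whose weights accumulate across targets
(condition-specific information-flow network), and each effector's
traversal weight is the sum of retained-path frequencies containing it.
Frequency weighting is the default because it is scale-free in the number
of walks; a raw path-count mode is exposed because the published heatmaps
("how often an effector is traversed") do not pin down the weighting.

# The synthetic-data generators

`simulate_lfq()` emulates the study design: per-protein log2-normal
baselines (mean 25, SD 1.5 — the magnitude range of typical LFQ
intensities) shared between sample and bead-control runs; biological
noise of SD 0.5 log2 units per (protein, condition, biological
replicate); technical noise of SD 0.2; per condition, 10% of proteins
spiked by +2 log2 units in that condition's sample runs only (bead
controls never receive spikes); MAR dropout uniform at 5%; MNAR dropout
logistic in −log2 intensity with the intercept calibrated by root-finding
so the realized rate matches the 10% target. MAR and MNAR masks are
disjoint, and the generator returns them with the spiked-protein lists as
ground truth. Everything is a deterministic function of the seed.

What the generator does *not* emulate: peptide-level identification,
match-between-runs structure, correlated contaminant background,
batch/order effects, and the long-tailed abundance distribution of real
lysates. Passing recovery and calibration tests on this generator
therefore demonstrates that the pipeline's inference machinery is correct
under its own assumptions — not that real AP-MS data meet those
assumptions.

`simulate_network()` produces a connected graph (random spanning tree
plus uniform extra edges to hit the target mean degree) with edge scores
Uniform(0.5, 1) so the 0.7 confidence filter has bite; `simulate_go()`
grows a rooted DAG with 1–2 parents per term and annotates each gene to
1–5 leaves.

# Numerical choices and problem sizes

* Hommel adjustment uses the standard quadratic-time closed algorithm;
  both BH and Hommel are verified against exhaustive closed-testing
  references on vectors of length ≤ 8.
* The trigamma inverse is solved by Newton iteration to relative 1e-8.
* Probabilistic-PCA imputation (the MNAR alternative) uses rank 2, EM to
  relative tolerance 1e-6, at most 500 iterations.
* MinProb-style MAR imputation draws Normal(q0.01 of the run's observed
  values, median per-run SD), seeded.
* The test and acceptance suites run at desk scale by design: 100–150
  proteins, reduced condition grids (4–9 conditions), 40-term ontologies,
  toy walk graphs of ≤ 8 nodes with 1e5–1e6 walks, and 10 simulation
  seeds per calibration claim. These sizes were chosen so each claim is
  statistically meaningful (e.g. binomial SEs at 1e6 walks resolve path
  probabilities to ~1e-4) while the whole suite stays interactive.

# Known limitations

* The walk analysis inherits the structural biases of the procedure it
  implements: shorter paths are systematically more likely, so traversal
  weights are comparable across conditions for a fixed target but not
  across targets with different shortest paths.
* Hommel correction across all term x effect p-values is conservative
  when terms are strongly dependent through shared genes (propagation
  guarantees such sharing).
* kNN imputation assumes MAR cells have informative neighbours; in very
  sparse groups it degrades to run medians, which shrinks fold changes.
* The ID-mapping step of real deposits (UniProt → HGNC → database-specific
  names, with occasional manual renames) is interactive by nature and is
  replaced here by a user-supplied static two-column table.
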