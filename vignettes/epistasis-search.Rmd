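---
title: "Detecting hierarchical gene-gene interactions with QMDR and multiobjective evolutionary search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hierarchical gene-gene interactions with QMDR and multiobjective evolutionary search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(epiqmdr)
```

## The problem

Most genome-wide association analyses test one SNP at a time, which is blind
to *epistasis*: genotype combinations whose joint effect on a phenotype
deviates from the sum of their marginal effects. Exhaustively scoring all
K-SNP combinations is infeasible beyond K = 2 or 3 even on a filtered SNP
panel, so a search over the model space is required. `epiqmdr` implements a
stochastic alternative: a multiobjective evolutionary search whose unit of
evaluation is a *constructed attribute* built by quantitative multifactor
dimensionality reduction (QMDR), guided by entropy-based expert knowledge,
with a simulator and study harness to quantify detection power against a
random-search baseline.

## The QMDR kernel

Given K SNPs (additive 0/1/2 coding) and a quantitative trait, QMDR pools
the up-to-3^K multilocus genotype cells into one binary attribute:

1. assign every sample to its genotype cell;
2. label a cell **high-level** when its mean trait strictly exceeds the
   overall (grand) mean, otherwise **low-level** — equality is low, and
   unobserved cells are recorded as `empty` (low if ever queried);
3. pool high cells into group G1 and low cells into G0, and score the
   attribute by the pooled-variance two-sample t-statistic of G1 versus G0.

The t-statistic is a *training* score: it is computed on the same data that
labeled the cells, so it grows with model order through overfitting. The
search does not correct this with cross-validation; it instead opposes it
with an explicit parsimony objective (below), which is the design stance of
the Pareto approach. A standalone k-fold scorer (`qmdr_cv()`) is provided
for post-hoc assessment of chosen models: it labels cells on the training
folds and evaluates the t-statistic on held-out samples, treating cells
unseen in training as low.

Degenerate layouts — an empty G1 or G0, fewer than two samples in either
group, or zero pooled variance — score t = 0 with `valid = FALSE` rather
than erroring, so an evolutionary run never stops on a pathological model.
When either group is large the statistic is insensitive to the Student
versus Welch choice; the pooled form is the default and Welch is available
via `qmdr_t_statistic(welch = TRUE)`. For binary endpoints the classic MDR
rule is available (`mdr_attribute()` with a case/control ratio threshold,
default the overall case/control ratio; ties are again low), but the search
objectives assume a quantitative trait.

## Expert knowledge: pairwise interaction information

For every SNP pair (A, B) the package computes the interaction gain

IG(A,B;C) = I(A,B;C) − I(A;C) − I(B;C)   (bits),

where (A, B) is the 9-category joint genotype and C a binary class.
Positive gain means synergy (the pair carries information beyond its main
effects); negative gain means redundancy, as under linkage disequilibrium.
Because the trait is continuous and interaction information needs a
discrete class, C is the trait binarized at its overall mean — the same
high/low semantics QMDR uses; a median split is available by flag. All
entropies are plug-in (maximum-likelihood) estimates with no bias
correction, which keeps them exactly checkable against a closed-form
oracle; the cost is a small positive finite-sample bias (about
4/(2N ln 2) bits for the 3×3×2 layout), which cancels in comparisons
between pairs and is irrelevant to ranking.

The full gain matrix is the *expert-knowledge lookup table*
(`build_expert_knowledge()`). It serves twice:

* **Sensible initialization** — initial models draw their size uniformly
  from 1–5 (3 ± 2); the first SNP is uniform, and each subsequent SNP
  follows the table's best partner of the previously selected SNP with
  probability 0.5 (skipping duplicates), else is uniform. Seeding with
  plausible interacting pairs gives the search building blocks instead of
  noise. Only the best partner (k = 1) is consulted, though the full
  matrix is stored.
* **Search objective** — a model's interaction-information score is the
  mean gain over all its unordered SNP pairs (0 for single-SNP models).

Note the expert knowledge is computed from the same data being searched —
it is a data-driven prior, not an independent one.

## Three objectives and NSGA-II

Each candidate model (an ordered set of distinct SNP indices) is scored on:

1. **t-statistic** (maximize) — association strength of the constructed
   attribute;
2. **mean pairwise interaction information** (maximize) — rewards models
   built from genuinely interacting SNPs;
3. **model size K** (minimize) — parsimony pressure, since smaller models
   generalize better.

Models are ranked by standard NSGA-II nondominated sorting (a model
dominates another iff it is at least as good on all three objectives and
strictly better on one; equal-objective duplicates share a front) with
crowding distance as the within-front diversity measure (boundary models
get infinite distance; zero-range objectives contribute zero). The Pareto
front preserves both small strong models and larger exploratory ones,
which keeps SNP diversity in the population and avoids fixation.

## Search architecture

The engine mirrors a client/worker island design, run sequentially
in-process (per-task RNG streams are derived from the root seed, so a
parallel scheduler could reproduce the same results):

* A **steady-state client population** (default 200) is created by
  sensible initialization and scored.
* Each round the client breeds seed offspring for each of 4 **generational
  tasks**: two rank/crowding tournaments of size 3 pick parents, the
  second winner is mutated (per-SNP rate 0.5% for ~1000-SNP panels, 5% for
  ~100-SNP panels — scaled to panel size so the expected SNP turnover per
  model is comparable), then any-point crossover produces the offspring.
* Inside a task (population 50, 25 generations), children are produced by
  crossover 90% of the time — first parent from a size-6 parsimony
  tournament (smallest model order wins, ties uniform), second from a
  size-3 rank/crowding tournament — and by mutation of a uniformly drawn
  model (rate 0.5%) the remaining 10%. Parents and children are merged and
  truncated elitistically back to the task size by rank then crowding.
* Returned subpopulations merge into the client population with the same
  NSGA-II truncation.

**Any-point crossover** cuts each parent's SNP list at an independent
uniform point in [0, length] and swaps tails, so children shrink and grow;
models larger than 5 SNPs arise here and are truncated at `max_model_size`
(default 10 — with 3^K cells, cells empty out and scores degenerate long
before K = 10, and the cap bounds memory). Duplicate SNPs within a child
are removed keeping the first occurrence; an empty child is repaired to a
single random parental SNP. Tournament ties resolve uniformly at random.

Scoring is cached by SNP set: re-evaluating a set already seen is free,
and only cache misses consume the **evaluation budget**, the sole
termination condition (default 50,000). The result is the rank-0 front of
the union of the final population and a running nondominated archive
(capped at 1000 by crowding pruning); both components' sizes are recorded.
Every run is reproducible from one integer seed.

The **random-search baseline** (`run_random_search()`) draws models from
the same initial-sampling distribution with the expert-knowledge path
disabled, scores them through the same kernel for the same budget, and
returns the Pareto front of everything it evaluated — the matched-budget
control for the simulation study.

## The simulator

The generator builds hierarchical quantitative-trait epistasis:

* Each **gene** is a pair of SNPs sharing the configured MAF with a 3×3
  *pure-epistasis* penetrance table: every Hardy-Weinberg-weighted row and
  column marginal equals the population mean K, so neither SNP has a main
  effect. Tables are produced by projecting a random deviation table onto
  the zero-marginal subspace (alternating weighted row/column centering to
  convergence — deterministic and exactly verifiable, unlike a stochastic
  table search) and scaling deviations around a baseline K₀ = 0.5 to hit
  the target heritability h² = Σp(f−K)²/(K(1−K)) exactly; draws that would
  clip outside [0, 1] are rejected. K₀ = 0.5 maximizes the feasible
  deviation range, and only dispersion matters for a quantitative trait.
  h² here is a property of the penetrance table, not a phenotypic-variance
  ratio: the trait dispersion σ is an independent knob, so the two can be
  set orthogonally.
* Each gene contributes Normal(f(g₁, g₂), σ) per sample — noise applied
  per gene, then summed (a single post-sum draw is available by flag);
  with σ = 0 the phenotype is an exact deterministic function of the
  functional genotypes, which the tests exploit.
* Noise SNPs are HWE draws at MAFs uniform in [0.05, 0.5] (the common
  GWAS MAF filter bound), independent of the trait; functional columns are
  placed at shuffled positions so column order carries no signal.

Study-condition defaults follow the simulation grid: genes ∈ {2, 4}
(4 or 8 functional SNPs), MAF ∈ {0.2, 0.4}, h² ∈ {0.001, 0.01, 0.1, 0.2},
σ ∈ {0.05, 0.1, 0.2, 0.3}, n ∈ {2000, 8000}, 100 or 1000 total SNPs,
10 replicates per cell. Both SNPs within a gene share one MAF.

What the generator does *not* emulate: linkage disequilibrium between
SNPs, covariates and population structure, genotyping error or
missingness, and multi-allelic variants. Passing the simulation study
therefore shows power to recover planted pure interactions among
independent SNPs — not robustness to the correlation structure of real
genotype panels, where upstream LD pruning is assumed.

## The simulation study

`run_cell()` simulates replicate datasets and runs both engines with
identical budgets; `run_grid()` sweeps a list of cells, checkpoints
completed cells as TSV so interrupted grids resume identically, and emits
a long table for heatmap rendering (`autoplot()`). Success is judged per
replicate under three criteria of increasing strictness, all recorded:

* `front_union_contains_all` (default) — every functional SNP appears
  somewhere on the Pareto front: gene/pathway-level identification, the
  level the study design targets;
* `best_model_contains_all` — the highest-t front model contains all
  functional SNPs;
* `best_model_exact` — that model is exactly the functional set.

Success rates are exact integer ratios (successes/replicates).

## Problem sizes used by the tests and the acceptance script

The package's own verification runs at the 100-SNP scale: the
strong-signal comparison cell (2 genes, MAF 0.4, h² 0.2, σ 0.05,
n 2000) at a 20,000-evaluation budget, and the two hard cells — 2 genes
at h² 0.001 and 4 genes at h² 0.01, both MAF 0.4, σ 0.05, n 8000 — at a
50,000-evaluation budget, 10 replicates each. These sizes keep a full
verification run in the tens of minutes on one core while preserving the
qualitative structure of the full grid; the 1000-SNP grid
(`grid_preset("grid-1000")`) is provided for offline study and is
substantially more expensive per dataset.

## Numerical and design choices

* **Tie rules**: a cell mean equal to the grand mean is low; a
  case/control ratio equal to the threshold is low ("exceeds" is strict).
* **Degenerate scores**: t = 0 with `valid = FALSE`, never an exception.
* **t sign**: the statistic is G1 − G0, non-negative by construction
  except in pathological tie layouts; it is reported signed, not as an
  absolute value.
* **Missing genotypes**: sample rows with missing values are dropped at
  load and counted — MDR cells are count-based and assume complete data.
* **Allele orientation**: genotypes are taken at face value; MDR scores
  are invariant to relabeling codes within a SNP, so no re-polarization.
* **Seeds**: one root seed per run; replicate, engine and task streams are
  derived deterministically (double arithmetic mod 2^31−19, keeping every
  derived seed a valid 32-bit integer).
* **Population sizes** (steady-state 200, task 50 × 25 generations,
  4 tasks/round) are configurable defaults chosen to balance exploration
  against per-round overhead at the 100–1000-SNP scale.

## Limitations

* The t objective is a training score; front membership is not a
  significance statement, and no permutation testing is included.
* Expert knowledge is data-driven and reused as an objective, so the
  interaction-information score is not independent evidence.
* The search is heuristic: a missed functional SNP at low heritability is
  expected behaviour at tight budgets, which is exactly what the success
  heatmaps quantify.
* Binary endpoints get the MDR attribute construction but not a
  search objective; the engine is for quantitative traits.

## A worked miniature

```{r example, eval = FALSE}
spec <- simulation_spec(n_genes = 2, maf = 0.4, heritability = 0.2,
                        trait_sd = 0.05, n_samples = 500, n_total_snps = 30)
sim <- simulate_epistasis(spec, seed = 42)
res <- run_mdr_search(sim$dataset,
                      search_config(evaluation_budget = 2000), seed = 7)
glance(res)
is_success(res, sim$truth, sim$dataset, "front_union_contains_all")
autoplot(res)
```
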