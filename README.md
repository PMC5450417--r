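# epiqmdr

Multiobjective evolutionary search for gene-gene interactions (epistasis)
in SNP panels with a quantitative-trait MDR kernel.

## What it does, and for whom

Single-SNP association scans miss *epistasis* — genotype combinations
whose joint effect on a trait is non-additive — and exhaustive scans of
K-SNP combinations collapse combinatorially beyond K ≈ 2–3. `epiqmdr` is
for statistical geneticists who have already filtered a GWAS panel to a
tractable set of SNPs (a pathway's tag SNPs, say 100–1000) and want to
search that panel for interacting SNP sets of *any* order.

Three pieces work together:

* **QMDR kernel.** A candidate SNP set is collapsed into one binary
  attribute: each multilocus genotype cell is labeled high-level iff its
  mean trait strictly exceeds the grand mean, samples are pooled into
  G1/G0 by cell label, and the attribute is scored by the pooled
  two-sample t-statistic of G1 vs G0. Classic case/control MDR (cell high
  iff cases/controls > T) is included for binary endpoints.
* **Entropy-based expert knowledge.** For every SNP pair the interaction
  gain IG(A,B;C) = I(A,B;C) − I(A;C) − I(B;C) (bits, plug-in estimates,
  C = the trait binarized at its mean) is stored in a lookup table; a
  positive gain indicates synergy. The table seeds the initial population
  ("sensible initialization": each SNP after the first follows its
  predecessor's best partner with probability 0.5) and supplies one
  search objective.
* **NSGA-II evolutionary engine.** Models are evolved under three
  objectives — maximize the t-statistic, maximize mean pairwise
  interaction gain, minimize model size — with nondominated sorting,
  crowding distance, parsimony + rank/crowding tournaments, any-point
  crossover and per-SNP mutation, in a steady-state client population
  that launches generational tasks (an in-process island model). The
  search stops when its evaluation budget is spent and returns the Pareto
  front; a matched-budget random-search baseline provides the control.

A hierarchical quantitative-trait simulator generates the evaluation
data: each "gene" is a pair of SNPs with a *pure-epistasis* 3×3
penetrance table (all Hardy-Weinberg-weighted marginals equal, so no main
effects) at an exact target heritability h² = Σp(f−K)²/(K(1−K)); gene
products f + Normal(0, σ) are summed into the phenotype and the
functional SNPs are hidden among noise SNPs. A study harness sweeps
parameter grids and reports detection success rates per cell for both
engines.

## Worked example

Simulate a strong-signal dataset (2 genes = 4 functional SNPs among 100,
MAF 0.4, per-gene h² = 0.2, trait SD 0.05, n = 2000), then search with a
20,000-evaluation budget:

```r
library(epiqmdr)

spec <- simulation_spec(n_genes = 2, maf = 0.4, heritability = 0.2,
                        trait_sd = 0.05, n_samples = 2000, n_total_snps = 100)
sim <- simulate_epistasis(spec, seed = 42)
sim$truth
#> <truth_set> 2 genes, functional SNPs: snp_0043, snp_0038, snp_0003, snp_0004

ek <- build_expert_knowledge(sim$dataset)
head(rank_pairs(ek), 4)
#> # A tibble: 4 × 3
#>   snp_i    snp_j    gain_bits
#>   <chr>    <chr>        <dbl>
#> 1 snp_0003 snp_0004   0.284
#> 2 snp_0038 snp_0043   0.234
#> 3 snp_0003 snp_0038   0.0160
#> 4 snp_0039 snp_0048   0.00837
```

Both planted pairs top the expert-knowledge ranking (their gains, ~0.23–0.28
bits, sit an order of magnitude above the noise floor). Now the search:

```r
res <- run_mdr_search(sim$dataset, search_config(evaluation_budget = 20000),
                      seed = 7)
glance(res)
#> # A tibble: 1 × 6
#>   engine       evaluations front_size best_t best_model                    seed
#>   <chr>              <int>      <int>  <dbl> <chr>                        <dbl>
#> 1 evolutionary       20000         53   64.9 snp_0003,snp_0004,snp_0043,…     7

is_success(res, sim$truth, sim$dataset, "front_union_contains_all")
#> [1] TRUE
```

All four functional SNPs appear on the Pareto front (`success = TRUE`);
the best model's t of 64.9 is the training score of its constructed
attribute. The matched-budget random baseline reaches a clearly lower
best t with a sparser front:

```r
base <- run_random_search(sim$dataset, search_config(), seed = 7,
                          budget = 20000)
glance(base)
#> # A tibble: 1 × 6
#>   engine evaluations front_size best_t best_model                         seed
#>   <chr>        <int>      <int>  <dbl> <chr>                             <dbl>
#> 1 random       20000          8   38.7 snp_0004,snp_0003,snp_0072,snp_0…     7
```

`autoplot(res)` draws the front (t vs interaction information, sized by
model order); `tidy(res)` returns it as a tibble. Power studies over
parameter grids run through `run_cell()` / `run_grid()`, with
`autoplot()` rendering the success-rate heatmap.

A thin CLI wraps the same functions
(`inst/cli/epiqmdr simulate|rank-pairs|search|baseline|experiment`); all
entry points are byte-reproducible from their `--seed`.

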