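# tadlink

Enhancer–promoter association analysis constrained by topologically
associating domains (TADs), for regulatory-genomics analyses built on
CAGE-style promoter/enhancer activity tracks and Hi-C-derived TAD maps.

Gene promoters are preferentially regulated by enhancers located in the same
TAD. Given two parent TAD tracks, promoter and enhancer interval sets
(BED), per-sample read-count tables and per-tissue differential-expression
tables, tadlink:

* builds a **consensus TAD set** from the two parents (pairwise-intersection
  or chained-merge construction) and reports interval counts,
  tissue-specific TADs and the base-level Jaccard statistic;
* enumerates candidate **enhancer–promoter pairs** by linear proximity
  (midpoint distance ≤ 500 kb) or same-TAD co-localisation, and retains
  pairs whose two members are both differentially expressed (BH FDR < 0.05);
* quantifies the four **sign-pattern classes** per tissue. For a TAD with
  *p* DE promoters and *e* DE enhancers the interaction total is the product
  *p·e*, split into `++`, `+-`, `-+`, `--` by the per-direction counts
  (promoter sign first); tissue totals are normalised to 1. *Consolidated*
  TADs (all DE promoters one direction, all DE enhancers one direction) are
  identified, and the class counts can be restricted to an annotated gene
  subset (e.g. transcription factors);
* tests the **TAD-level association**: per-TAD summed counts, log2(x+1)
  transformed, related by Pearson's *r*, Spearman's ρ, Kendall's τ-b, simple
  linear regression and the robust Theil–Sen estimator (slope = median of
  all pairwise slopes), with an **adjacent-TAD null** that re-pairs each
  TAD's enhancer aggregate with the next TAD's promoter aggregate;
* ships a **synthetic-data generator** with known ground truth (shared
  per-TAD activity a_t ~ N(0, σ_a²), feature baselines, TAD-wise condition
  effects with a configurable sign-pattern mixture), so every stage is
  testable without external sequencing data.

## Worked example

```r
library(tadlink)

sim <- simulate_tad_genome(sim_config(n_chromosomes = 2,
                                      tads_per_chromosome = 10,
                                      tad_length = 1e5, seed = 42))
ap  <- assign_to_tads(sim$promoters, sim$tads)
ae  <- assign_to_tads(sim$enhancers, sim$tads)
agg <- aggregate_by_tad(total_feature_counts(sim$prom_counts),
                        total_feature_counts(sim$enh_counts), ap, ae)
tad_association(agg)
#> TAD-level enhancer-promoter association (same-TAD pairing)
#>   n = 20 TADs
#>   Pearson  r   =   0.7686   P(r!=0)   = 7.53e-05
#>   Spearman rho =   0.7188   P(rho!=0) = 0.000356
#>   Kendall  tau =   0.5684   P(tau!=0) = 0.000458
#>   SLR:       slope   0.7239, intercept   3.1263
#>   Theil-Sen: slope   0.7696, intercept   2.5216

adjacent_tad_null(agg, sim$tads)
#> TAD-level enhancer-promoter association (adjacent-TAD pairing)
#>   n = 18 TADs
#>   Pearson  r   =   0.1860   P(r!=0)   = 0.46
#>   ...
```

The same-TAD pairing recovers the shared per-TAD activity the generator
planted (strong positive correlation); the shifted pairing does not — the
association respects TAD boundaries. Sign-pattern quantification on the same
simulation:

```r
de_p  <- naive_de(sim$prom_counts, sim$condition)
de_e  <- naive_de(sim$enh_counts, sim$condition)
pairs <- filter_differential(pairs_by_tad(sim$promoters, sim$enhancers,
                                          sim$tads), de_p, de_e)
tissue_profile_from_pairs(pairs, "sim")
#> Tissue interaction profile: sim
#>   total interactions: 250
#>          count     prop
#>   ++       175   0.7000
#>   +-        50   0.2000
#>   -+         0   0.0000
#>   --        25   0.1000
```

The recovered proportions track the generator's pattern mixture. A
command-line wrapper over the same functions lives at
`inst/cli/tadlink.R` (`simulate`, `consensus`, `pairs`, `quantify`,
`correlate`, `run` subcommands; exit codes 0/2/3 for success/config
error/data error).

See `vignettes/tad-association.Rmd` for the model, parameter meanings,
generator assumptions and numerical choices.

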