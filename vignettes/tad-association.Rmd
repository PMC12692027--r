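---
title: "Linking enhancers to promoters through TAD structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking enhancers to promoters through TAD structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(tadlink)
```

## The problem and the model

Topologically associating domains (TADs) are self-interacting regions of
chromatin within which most enhancer-promoter contacts are confined. If TAD
boundaries are functionally real, then the transcriptional output of the
enhancers inside a domain should co-vary with the output of the promoters of
the same domain, while showing no systematic relation to promoters of the
neighbouring domain. tadlink operationalises this idea as a pipeline of
small, separately testable stages:

1. **Consensus TADs.** Two Hi-C-derived TAD tracks (e.g. from two cell
   types) are combined into a consensus set, either as the maximal pairwise
   overlap regions (`mode = "intersect"`) or by chaining all overlap
   regions that derive from the same first-parent TAD into one interval
   (`mode = "merge_chained"`). Both constructions are exposed because the
   two natural readings of "consensus overlap" genuinely differ: pairwise
   intersection can *split* parent domains and so produce more consensus
   intervals than either parent has, whereas chaining merges them. The
   accompanying report counts tissue-specific TADs (zero overlapping bases
   with the whole other set; a single shared base disqualifies, since no
   minimum-overlap fraction is defined for this comparison) and the
   base-level Jaccard statistic of the two merged covers.
2. **Pair enumeration.** Candidate pairs are promoter x enhancer
   combinations either within 500 kb of each other (midpoint to midpoint,
   inclusive; midpoints are compared as doubled integers so the boundary is
   exact rather than rounded) or assigned to the same TAD. Assignment is by
   largest overlap with ties broken toward the lower-coordinate TAD, so
   every feature belongs to at most one TAD and per-TAD aggregates conserve
   totals. This uniqueness is a deliberate choice: coverage-style counting
   would attribute a boundary-straddling feature to both neighbours and
   break the conservation identities the correlation stage relies on.
3. **Differential-expression filtering.** A pair is retained when both
   members are significantly up- or downregulated between the two
   conditions (BH-adjusted FDR strictly below 0.05), and is then labelled
   with its sign pattern, promoter sign first: `++`, `+-`, `-+`, `--`.
4. **Interaction quantification.** Within a TAD holding p differentially
   expressed promoters and e differentially expressed enhancers, all p x e
   combinations count as putative interactions, so the per-class counts are
   exact integer products (e.g. `c_mp = n_prom_down * n_enh_up`). Tissue
   totals normalised to 1 give the class proportions; *consolidated* TADs
   are those where all DE promoters share one direction and all DE
   enhancers share one direction (a promoter-only relaxation is available,
   since uniformity could also be read as a promoter-side property only).
5. **TAD-level association.** Per-TAD summed promoter and enhancer counts,
   transformed as `log2(sum + 1)`, are related by Pearson's r, Spearman's
   rho, Kendall's tau-b, a least-squares line and the Theil-Sen line
   (enhancers on the x axis). The negative control re-pairs each TAD's
   enhancer aggregate with the *next* TAD's promoter aggregate along the
   chromosome.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `max_distance` | 500,000 | bases | conventional upper range of enhancer action used for the proximity level |
| `fdr_threshold` | 0.05 | — | strict (`<`) BH-adjusted significance cut for both pair members |
| `pseudocount` | 1 | counts | anchors `log2(0 + 1) = 0` for empty aggregates; any positive value preserves monotonicity |
| consensus `mode` | `"intersect"` | — | the construction that never discards overlap structure; `"merge_chained"` gives the coarser one-per-parent reading |
| `promoter_only` | `FALSE` | — | relaxation of the consolidated-TAD definition to promoter-sign uniformity only |

Distance is measured midpoint to midpoint because promoter and enhancer
intervals here stand for point-like transcription-initiation clusters;
the boundary is inclusive. Strand is carried through I/O but ignored by all
spatial operations, as enhancer action is orientation-independent.

## The synthetic-data generator

`simulate_tad_genome()` emulates exactly the statistical structure the
analysis is designed to detect, with known ground truth:

* TADs tile each chromosome end to end; promoters (100 bp) and enhancers
  (400 bp) are placed uniformly at random inside their TAD, non-overlapping
  by bounded rejection.
* The count of feature *f* in sample *s* is
  `round(2^(b_f + a_t + g_f c_s + eps_fs))`: a shared per-TAD activity
  `a_t ~ N(0, sigma_a^2)` (the quantity the same-TAD correlation should
  recover), a per-feature baseline `b_f ~ N(mu_b, sigma_b^2)`, sample noise
  `eps ~ N(0, sigma_e^2)`, and a TAD-wise condition effect: a fraction
  `de_fraction` of TADs draws one sign pattern from `pattern_mixture` and
  applies `+-effect_size` to all its promoters/enhancers according to the
  pattern's two signs.
* Defaults (`sigma_a = 1`, `mu_b = 4`, `sigma_b = 1`, `sigma_e = 0.5`,
  `effect_size = 2`, mixture `0.7/0.2/0.05/0.05`, 6+6 samples) describe a
  clearly detectable but noisy regime: per-TAD activity and feature noise
  of comparable magnitude, a four-fold condition effect, and a mixture
  dominated by concordant upregulation with a minority of discordant
  domains — the qualitative picture the analysis is meant to resolve.

Counts are rounded log-normal rather than negative binomial: the shared
log-scale activity factor is what induces the correlation under test, and a
log-normal mean structure carries it exactly; overdispersed count noise
would change the marginals but not the design of the test. The generator
also does **not** emulate library-size differences, mappability artefacts,
polymerase run-on signal bleeding across boundaries, or correlated
activities of neighbouring TADs. Passing tests therefore show the
*machinery* is correct (assignments, products, aggregation, statistics),
not that real tissue data will reach any particular effect size; on real
data the adjacent-TAD null may be less flat than here because neighbouring
domains share compartments.

`naive_de()` is a plain Welch t screen on `log2(count + 1)` with BH
adjustment — deliberately not a count-model fit. It exists so the FDR
filtering contract can be exercised end to end on synthetic data; real
analyses are expected to bring DE tables from a dedicated tool.

## A worked run

```{r}
sim <- simulate_tad_genome(sim_config(n_chromosomes = 2,
                                      tads_per_chromosome = 10,
                                      tad_length = 1e5, seed = 42))
ap <- assign_to_tads(sim$promoters, sim$tads)
ae <- assign_to_tads(sim$enhancers, sim$tads)
agg <- aggregate_by_tad(total_feature_counts(sim$prom_counts),
                        total_feature_counts(sim$enh_counts), ap, ae)
same <- tad_association(agg)
same
adjacent_tad_null(agg, sim$tads)
```

```{r, fig.width = 5, fig.height = 4}
plot(same)
```

```{r}
de_p <- naive_de(sim$prom_counts, sim$condition)
de_e <- naive_de(sim$enh_counts, sim$condition)
pairs <- filter_differential(pairs_by_tad(sim$promoters, sim$enhancers,
                                          sim$tads), de_p, de_e)
tissue_profile_from_pairs(pairs, tissue = "synthetic")
```

## Numerical choices and degenerate inputs

* **Coordinates** are BED (0-based half-open) on disk and 1-based closed
  in memory (`GRanges`); conversion happens only in `read_bed()` /
  `write_bed()`. Bookended BED intervals merge, matching the default
  behaviour of the usual interval toolchain.
* **Theil-Sen** uses the median of all pairwise slopes with undefined
  (vertical) slopes excluded, and the median-residual intercept; even
  sample sizes average the two central order statistics. All x equal is a
  degenerate-input error rather than a silent `NA`.
* **Correlation p-values**: Pearson via the t transform on n-2 degrees of
  freedom, Spearman as Pearson on average ranks with the same t
  approximation, Kendall as tau-b with the tie-corrected normal
  approximation — ties are common after aggregation of small counts, which
  is why the tie-corrected variant is the right default. Fewer than 3
  points: coefficients are computed, p-values are reported missing. Zero
  variance on either axis: the whole battery is reported missing with a
  diagnostic. P-values below 1e-300 print as `<1e-300` instead of an
  underflowed 0.
* **Adjacent-TAD pairing** walks the coordinate-ordered TADs of each
  chromosome restricted to those with both aggregates, pairs each with its
  successor, and never wraps around or crosses chromosomes. TADs without
  usable features are skipped over rather than breaking the chain, since
  the control needs the nearest usable neighbour, not a literal index
  shift.
* **BH adjustment** is the textbook step-up computed directly; the test
  suite cross-checks it against an exhaustive-minimum oracle and against
  the standard library implementation.

## Design notes

The association battery and the Theil-Sen estimator are classed model
objects (`print`, `coef`, `predict`, `residuals`, `plot` methods) because
they are the estimators of the package; the remaining stages are plain
functions over data frames and `GRanges`, which keeps the pipeline
composable. Problem sizes used by the test suite — 300 TADs with 5+5
features for the correlation properties, 500 TADs for mixture recovery,
2,000 features for null calibration — were chosen as the smallest designs
at which the targeted effects are unambiguous for the property being
checked.

## Known limitations

* The consensus construction assumes each parent set is disjoint;
  overlapping domain calls must be resolved upstream.
* Unique TAD assignment diverges from coverage-style counting for
  boundary-straddling features (documented above); there is no option to
  double-count.
* `naive_de()` is not a replacement for a proper count model and is not
  meant to be used on real data.
* The pipeline consumes pre-lifted coordinates; no assembly conversion is
  performed.
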