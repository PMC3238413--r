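# expclad — parsimony cladistics of gene expression profiles

`expclad` stratifies diseased specimens by treating their expression
profiles the way cladistics treats taxa. It is aimed at researchers who
want to model a heterogeneous pathology (endometriosis, tumours, any
cohort with matched normal references) as an *accumulation* of expression
aberrations rather than as a single two-group contrast.

The chain it implements:

1. **Polarity assessment (outgroup comparison).** A reference set of
   normal specimens defines, per gene *g*, the interval
   [min<sub>g</sub>, max<sub>g</sub>] of normal expression. Every studied
   value is coded ancestral (0, inside the interval) or derived (1):
   `derived_over` above it, `derived_under` below it, `derived_absent`
   when unmeasurable. This turns the real-valued matrix into a binary
   character matrix and, unlike t/F statistics, keeps *dichotomously
   expressed asynchronous* (DEA) genes — genes whose values fall both
   above and below the normal range across specimens — fully visible.
2. **Maximum parsimony.** The rooted cladogram minimising the number of
   state changes is found under Wagner (reversible, Fitch counts) or
   Camin–Sokal (irreversible gains) parsimony, with the root fixed
   all-ancestral (equivalently: a hypothetical all-zero ancestor leaf).
   Exact branch-and-bound search up to 9 taxa; deterministic
   random-addition + SPR hill-climbing beyond.
3. **Synapomorphy mapping.** For every clade, the genes derived in all
   members (its synapomorphies), the *additional* ones not already
   counted at an ancestor, the cumulative counts along the main axis, a
   per-direction partition (over/under/mixed/absent), per-branch
   gain/loss maps, and a three-colour heat-map coding.
4. **Synthetic validation.** A generator plants a known tree and
   per-branch events in lognormal expression data (plus optional noise,
   DEA genes and missing values); `evaluate_recovery()` scores the whole
   chain by Robinson–Foulds distance and per-clade synapomorphy
   precision/recall against the planted truth.

## A worked example

```r
library(expclad)

sim <- simulate_dataset(simulation_config(n_genes = 500, n_outgroup = 6,
                                          n_ingroup = 6, events_per_branch = 4,
                                          dea_fraction = 0.2, seed = 11))
pol <- polarize(sim$matrix, outgroup_profile(sim$matrix, sim$design), sim$design)
pol
#> polarity_matrix: 500 genes x 12 samples (6 outgroup, 6 ingroup), 1080 derived calls, 0 excluded genes

ts <- exhaustive_search(pol, taxa = sim$design$ingroup)
ts
#> tree_set: 1 tree(s) retained of 1 optimal, length 20 (wagner, exhaustive)

ann <- annotate_cladogram(root_cladogram(ts$trees[[1]]), pol)
ann
#> annotated_cladogram over 6 samples
#>   N7 (6 members): +4 additional, 4 cumulative
#>   N8 (5 members): +4 additional, 8 cumulative
#>   N9 (4 members): +4 additional, 12 cumulative
#>   N10 (3 members): +4 additional, 16 cumulative
#>   N11 (2 members): +4 additional, 20 cumulative

evaluate_recovery(ann, sim$truth)
#> recovery_report: RF = 0, precision = 1.000, recall = 1.000
```

Reading the annotation: all six diseased specimens share 4 derived
expression states (synapomorphies) that separate them from the normal
references; each nested clade adds 4 more, and cumulative counts grow
additively toward the tip of the main axis — exactly the 4 events per
branch the generator planted. The recovery report confirms the inferred
cladogram equals the planted tree (Robinson–Foulds 0) and that the
per-clade gene sets were recovered without false positives or misses.

`run_pipeline(matrix, design, out_dir)` performs the same chain on real
data (TSV or GEO series-matrix input) and writes the polarity matrix,
gene-class report, DEA list, Newick cladogram (plus strict consensus when
several co-optimal trees exist), per-node synapomorphy reports, heat-map
codes and a run log. The numbered scripts under `analysis/` walk through
the whole study — toy matrices, simulation, polarity, cladogram and
recovery benchmark — and `analysis/06_gse7305.R` applies the pipeline to
the public ovarian-endometriosis accession GSE7305 once its series matrix
has been downloaded (instructions in the script header).

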