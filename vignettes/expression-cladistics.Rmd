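---
title: "Expression cladistics: outgroup polarity coding and parsimony analysis of expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression cladistics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expclad)
```

## The model

`expclad` treats a cohort of diseased specimens the way cladistics treats a
set of taxa. The premise is that disease progression behaves like descent
with modification: expression aberrations accumulate clonally, so specimens
that share many *derived* (deregulated) expression states are plausibly
related stages of one pathological process, and a rooted tree — a
cladogram — over specimens summarises that hierarchy.

Three ingredients make this operational.

**Polarity assessment (outgroup comparison).** A reference set of normal
specimens, the *outgroup*, defines for every gene the interval
$[\min_g, \max_g]$ of its normal expression ("the normals' range"). Every
value of a studied (*ingroup*) specimen is then coded

* `ancestral` (0) if it lies inside the interval (boundaries inclusive),
* `derived_over` (1) if above, `derived_under` (1) if below,
* `derived_absent` (1) if the value is unmeasurable (missing) while the
  gene is measurable in the outgroup.

Any derived state collapses to 1 in the binary view; the coding turns the
real-valued matrix into a qualitative 0/1 character matrix. This is
deliberately not a statistical test: a gene whose values scatter *both*
above and below the normal range — a *dichotomously expressed
asynchronous* (DEA) gene — splits the cohort into two opposite-signed
groups and would be averaged into insignificance by t- or F-statistics,
yet every one of its values is individually abnormal. `detect_dea()`
reports exactly these genes.

**Parsimony.** The preferred cladogram is the rooted tree requiring the
fewest character-state changes to explain the binary matrix. Two criteria
are provided: *Wagner* parsimony (changes reversible; the per-character
cost is the Fitch small-parsimony count) and *Camin–Sokal* parsimony
(derived states cannot revert; the cost is the minimum number of 0→1
gains). The root is fixed all-ancestral in both: conceptually a
hypothetical ancestor with every character 0 is attached below the tree,
which both orients the cladogram (base = most normal) and makes the
Camin–Sokal criterion well-defined.

**Synapomorphies.** A *synapomorphy* of a clade is a gene derived in
*every* member (set semantics). Because shared-derived sets grow as clades
shrink, the counts are additive: each node's *additional* synapomorphies
are its shared-derived genes minus its parent's, and cumulative counts sum
along the root-to-node path. `annotate_cladogram()` computes both;
`fitch_map_changes()` separately reports a minimum-change mapping of every
character onto branches (ties resolved toward the ancestral state nearer
the root), whose total equals the tree length by construction.

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `tolerance` | `outgroup_profile()` | 0 | fractional symmetric widening of the normal interval, in units of its width; 0 is the strict min–max range. Widening only removes derived calls (monotone), so it is a noise guard, not a fit parameter. |
| `leave_one_out` | `polarize()` | `TRUE` | each outgroup sample is coded against the interval of the *other* outgroup samples. Without it an outgroup value can never leave the interval it helped define, and reference specimens could never show derived states — yet transitional reference specimens are a real phenomenon. Ingroup samples always use the full interval. |
| `model` | searches | `"wagner"` | `"camin_sokal"` encodes the irreversibility premise; it never scores below Wagner. |
| `n_starts`, `seed` | `heuristic_search()` | 20, 42 | random-addition starts; the whole search is deterministic given the seed. |
| `max_taxa` | `exhaustive_search()` | 9 | exact search bound; beyond it the heuristic is required. |

## Search algorithms and numerical choices

Scoring is implemented in C++ over weighted site patterns (identical gene
columns are collapsed with multiplicities). The exhaustive search
enumerates rooted topologies by stepwise leaf insertion with
branch-and-bound: the length of a partial tree never decreases when a leaf
is added, so partial trees longer than the incumbent are pruned; ties are
always kept, so the full set of co-optimal trees is returned (up to a
retention cap of 1,000; the exact optimum count is reported regardless).

The heuristic search uses random-addition-order stepwise insertion (ties
broken toward the lowest-index insertion position, for determinism)
followed by steepest-descent hill climbing over the
subtree-prune-and-regraft (SPR) neighborhood, with up to five sideways
(equal-length) moves guarded by a visited set. SPR rather than
nearest-neighbor interchange is a deliberate design choice: on random
binary matrices we found Camin–Sokal optima sitting in funnels whose NNI
neighbors are all several steps longer, so no amount of NNI plateau
handling reaches them, while the SPR neighborhood (a strict superset of
NNI) does. With 20 starts the heuristic matched the exhaustive optimum on
every one of 200 random 4–7-taxon matrices under both models (the suite
recomputes this).

Other fixed conventions: boundary values code ancestral (closed interval);
co-optimal trees are ordered by canonical newick (sorted sibling
serialization), making every downstream artifact byte-reproducible;
`strict_consensus()` intersects rooted clade sets and may return
polytomies; the Robinson–Foulds distance between rooted cladograms is the
symmetric difference of their nontrivial clades, each clade canonicalized
to the bipartition it induces, so the two complementary children of a root
count once.

Degenerate inputs: genes observed in fewer than two outgroup samples have
no range and are excluded (coded all-ancestral, listed on the polarity
object and in the run log); an outgroup sample whose leave-one-out
complement is entirely missing codes ancestral; missing *outgroup* values
are never scored as derived, which keeps the no-leave-one-out invariant —
zero derived calls among outgroup samples — true on any input.

## The synthetic generator

`simulate_dataset()` emulates the data-generating story the method
assumes: per-gene lognormal baselines (`meanlog` uniform over
`baseline_mu_range`, default `[3, 8]`; `sdlog = baseline_sd`, default 0.3,
i.e. a realistic ~30% intensity CV), a planted rooted tree over the
ingroup, and `events_per_branch` derived-expression events on every
internal branch: each event displaces all leaves of the branch's clade
beyond the *realized* outgroup extreme by `effect_size` per-gene SDs
(default 2), so planted events are derived by construction at zero noise.
Ingroup baselines are drawn from the gene's lognormal *truncated to the
realized outgroup range*: a non-event, noise-free ingroup value therefore
always polarizes ancestral, which is what makes the generator a usable
oracle (the null model yields an all-zero binary matrix, and planted
events are recovered with precision = recall = 1).

Corruption processes default to off and are opted in per run: Gaussian
measurement noise of `noise_sd` per-gene SDs added to every cell last,
`dea_fraction` of events converted to DEA events (the clade split at
random into an over- and an under-displaced half), and
`missing_fraction` of ingroup cells masked. The defaults (2,000 genes,
8 outgroup, 10 ingroup, 5 events/branch) are the package's benchmark
conditions; the validation suite runs 20 replicates of the clean and the
noisy (`noise_sd = 0.25 * baseline_sd`) condition, and the search-oracle
benchmark uses 200 random 4–7-taxon matrices — sizes chosen so the whole
suite re-runs on a laptop in a couple of minutes.

What the generator does **not** emulate: probe-level array artifacts,
normalization effects, batch structure, or the matched-pair correlation of
designs where outgroup and ingroup samples come from the same patients.
Passing the recovery benchmarks therefore shows the *inference chain* is
correct and noise-tolerant under its own assumptions; it does not certify
performance on any particular real accession, where the unknown upstream
preprocessing dominates.

At the benchmark noise level the per-cell spurious-derived rate is on the
order of 1%, and with 5 events per branch the planted tree is genuinely —
not as a search failure — no longer the unique maximum-parsimony optimum
in a minority of replicates: noise occasionally makes an alternative tree
one step shorter, or ties it. The recovery scripts report this honestly
(RF-zero fraction and pooled recall per condition) rather than selecting
replicates.

## Known limitations

* The min–max outgroup range is sensitive to outliers in the reference
  set by design (any widening is evidence of normality); the `tolerance`
  knob and leave-one-out coding are the only guards. A percentile-based
  range would trade sensitivity for robustness and is deliberately not
  the default, since the coding is defined by the range of observed
  normal values.
* Binary expression characters are highly homoplastic; multiple
  co-optimal trees are common. All co-optima are retained and the strict
  consensus is reported, but downstream per-clade counts are computed on
  one (canonically first) tree.
* Real-accession reproduction depends on the depositors' preprocessing
  (normalization, transform, probe summarization), which series matrices
  do not record; the real-data driver script records every decision in
  its run log instead of promising the published counts.
* `derived_absent` treats every missing ingroup value as a derived
  (unmeasurable) state, following the synapomorphy conditions; with
  non-ignorable missingness this inflates shared-derived counts, which is
  why the per-clade direction partition separates `absent` and `mixed`
  from `over`/`under`.
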