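---
title: "Methods: cohort statistics and interactome separation for herb-symptom analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort statistics and interactome separation for herb-symptom analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnetsep)
```

## The question and the two-sided design

Given an inpatient cohort with a diagnosis of interest, a flag for
whether each patient received a particular herb, and symptom sets at
admission and discharge, the package answers two linked questions:

1. **Clinical**: is the herb preferentially prescribed under the
   diagnosis, and do users' symptoms resolve more often than non-users'?
2. **Mechanistic**: do the herb's protein targets sit near the
   symptom-associated genes in the protein-protein interactome (PPI)?

The clinical side is classical categorical statistics; the mechanistic
side is the network-medicine separation score. Keeping both behind one
configuration means the symptom list flowing into the network stage is
exactly the list the cohort statistics selected.

## Cohort statistics

Usage-by-diagnosis is a 2x2 contingency table tested with Pearson's
chi-square on one degree of freedom. The **continuity correction is off
by default** (`yates = FALSE`): on published per-symptom admission
tables of this size the uncorrected test reproduces reported p-values
(e.g. the 76/48 vs 92/102 comparison gives p = 0.0157, printing as
0.016), while the corrected one does not. A flag turns the correction
on. Group means (age, length of stay) are compared with **Welch's
unequal-variance t-test**; the pooled-variance variant assumes equal
arm variances for no benefit here. Degenerate inputs are conventions,
not errors where a convention is defensible: two constant equal groups
give p = 1, a table with a zero margin is refused as degenerate.

The **improvement ratio** of a symptom within a usage arm is 100 x
relieved/present, computed on exact integers and **rounded half-up to
two decimals** (half-to-even would turn 19/32 = 59.375% into 59.37 and
disagree with standard clinical-table rounding). A symptom nobody
presents has an undefined ratio, reported as `NA`/`-`, never as 0 —
zero relief and no data are different findings. No multiplicity
correction is applied across symptoms; the per-symptom p-values are
descriptive, and correcting them is a one-liner downstream
(`p.adjust`) if a confirmatory reading is wanted.

**Top-k symptom selection** ranks admission prevalence within a usage
arm, ties broken alphabetically for determinism. The pipeline ranks
with `relieved_only = TRUE`: candidates are restricted to symptoms
with at least one relief record in the cohort. The rationale is that
the selection feeds a relief-mechanism analysis — a symptom tracked at
admission but never observed relieved (in our replay data, e.g.
white-colored sputum) has no relieved-state gene interpretation and
would displace a symptom the downstream stage can actually use. The
literal all-symptoms ranking remains the default of the exported
function.

## Network separation

All distances are **unweighted shortest-path hop counts** on an
undirected PPI (no reliable edge weights exist at interactome scale).
With `d(x, y)` the hop distance:

- closest distance `d(X, Y)`: average over `y` in `Y` of
  `min over x in X` of `d(x, y)`;
- internal distance `d_AA`: the same with the minimum over *other*
  members (self excluded) — including self would make it identically
  zero and the score uninformative; a singleton set takes `d_AA = 0`
  by convention and is flagged;
- separation `S_AB = d_AB - (d_AA + d_BB)/2`.

`S_AB < 0`: the sets overlap in network space; `S_AB > 0`: they are
separated.

Two genuinely open choices were fixed as follows:

- **Symmetrization.** The one-directional `d(X, Y)` makes `S_AB` depend
  on argument order, yet a single value per herb-symptom pair is the
  meaningful report. The default symmetrizes (one average over the
  nearest-cross-member distances of *both* sets' members), the standard
  convention in network-medicine separation work; `directed = TRUE`
  reproduces the literal one-directional form with the herb as source
  set. Both are exposed and both are oracle-tested.
- **Unreachability.** Genes absent from the network are dropped (exact
  symbol match after uppercasing; no alias resolution, since silent
  alias mapping changes results irreproducibly) and nodes unreachable
  from the counterpart set are excluded from averages and counted,
  rather than assigned an arbitrary large distance. When nothing is
  mappable or reachable the pair's result is `status = "undefined"`,
  rendered `-` in reports. Undefined results never raise: a batch over
  twelve symptoms must complete with partial results, matching how such
  tables are published.

Distances are computed by breadth-first search (via igraph); the test
suite checks every metric against an exhaustive, dependency-free
per-source BFS oracle to 1e-9 on hundreds of random graphs of up to 50
nodes, and checks monotonicity (adding edges never increases a
distance).

## What the synthetic generators emulate — and what they do not

**Planted-module interactomes** (`plant_spec()`, `generate_ppi()`,
`plant_gene_sets()`). Defaults: 500-node preferential-attachment graph
with `m = 2` edges per step (mean degree ~4 — sparse and heavy-tailed
like a thresholded physical interactome), a 20-gene herb module, a
10-gene symptom module, planted **proximal** (every symptom gene within
1 hop of the herb set) or **distal** (all farther than 3 hops, topping
up with the farthest available nodes when the graph is too compact,
with a warning). These sizes mirror the working scale of real
herb-target (~hundreds) and symptom-gene (~tens) sets after mapping,
scaled down for test-time tractability. Under these settings the
proximal mean `S_AB` is about -0.6 and the distal mean about +1.4
across seeds, with the proximal score lower in essentially every
replicate — the benchmark the recovery tests assert at 100 seeds. A
preferential-attachment graph reproduces the degree heavy tail but not
the community structure, clustering, or study bias of a curated PPI, so
passing recovery here shows the *statistic* separates planted geometry,
not that any particular biological pair will score negatively.

**Cohort simulator** (`cohort_spec()`, `generate_cohort()`). Diagnosis
is Bernoulli (default prevalence 0.4%, a rare-cancer rate), usage is
Bernoulli conditioned on the arm (defaults 39% vs 8%, the observed
usage contrast), admission symptoms are independent Bernoulli per
symptom, and relief of a present symptom is Bernoulli with arm-specific
probability. Independence across symptoms and patients is a deliberate
simplification: it supports law-of-large-numbers and pipeline tests but
does not model symptom co-occurrence, dosage, or time.

**Replay fixture** (`paper_replay_fixture()`). A deterministic cohort
whose *marginals* equal a published LUAD cohort's tables cell for cell:
318 LUAD patients (124 users: 83 male/41 female; 194 non-users:
121/73), 85,119 non-LUAD patients (6,796 users), 17 symptoms' admission
counts per arm and 12 symptoms' relieved counts per arm. Joint
co-occurrence was never published, so symptoms are dealt to patients by
a deterministic round-robin with a running offset — every marginal is
preserved and every statistic computed here depends only on marginals,
so the filling convention is immaterial to the results while keeping
patients' symptom sets heterogeneous. Ages and lengths of stay are
constants at the published group means: per-patient values were never
published, which also means published age/LOS t-test p-values are *not*
reproducible and are deliberately out of the fixture's claims.
Non-LUAD patients carry no symptom data (the symptom tables concern the
LUAD group only). `lean = TRUE` shrinks the symptomless non-LUAD bulk
100-fold for fast unit tests; only the full fixture reproduces the
usage table.

All generators take explicit integer seeds, restore the caller's RNG
state, and are bit-reproducible for a fixed seed and package version.

## Numerical and reporting conventions

- Gene symbols: uppercased, trimmed, exact match; duplicates dropped
  with counts in load reports. Cohort symptom terms: lowercased,
  trimmed free strings.
- Every ranking (symptoms, overlap genes, edge tables) breaks ties
  alphabetically, so outputs are byte-stable across runs and platforms.
- A cohort record claiming relief of a symptom absent at admission is
  repaired by intersection and counted — a data-quality event surfaced
  in the manifest, not a hard error, since single malformed EMR rows
  should not kill a batch run.
- Result tables are written as TSV (UTF-8, LF, `-` for undefined) or
  JSON; identical inputs and configuration produce byte-identical
  bundles, manifest included.

## Problem sizes in the shipped tests

The suite runs the full 85,437-record fixture for the contingency
statistics, ~200-250 random graphs of 8-50 nodes against the BFS
oracle, and 100 seeded planted-module replicates at n = 500; the whole
suite completes in well under a minute on a single core. These sizes
were chosen as the smallest at which each property is meaningfully
exercised (marginal exactness needs the full fixture; oracle agreement
needs graph diversity, not graph size; recovery needs enough seeds for
a stable mean).

## Known limitations

- Exact published separation values for a specific herb cannot be
  reproduced without the same gene-set extracts and interactome version,
  which were not published; the package validates the statistic by
  construction (oracles, planted ground truth) instead.
- No degree-preserving randomization z-score is computed for `S_AB`;
  the raw score is reported, as in the motivating analyses. A
  permutation reference would be a natural extension.
- No identifier mapping, no free-text EMR parsing, no multiple-testing
  correction, no survival modelling — each is upstream or downstream of
  this package's scope.
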