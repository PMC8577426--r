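---
title: "Scoring metabolic task activity from transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring metabolic task activity from transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaboTask)
```

## The model

A *metabolic task* states a minimal metabolic capability: given only a
defined list of input substrates, each available up to a bounded uptake
rate, the network must be able to produce a defined set of output
metabolites at or above required rates. Whether a genome-scale metabolic
model (GEM) can do this is a steady-state feasibility question: does a flux
vector $v$ exist with $S\,v = 0$, reaction bounds respected, all exchange
reactions closed, inputs entering only through task-specific uptake fluxes
and outputs leaving through demand fluxes whose lower bounds enforce the
required production?

`metaboTask` splits the analysis into a model-dependent precomputation and a
data-dependent scoring step.

### Task-essential sets

For each feasible task we solve a parsimonious FBA: minimise $\sum_r |v_r|$
subject to the task environment, encoding the L1 objective exactly by
splitting reversible reactions into irreversible pairs. The reactions
carrying flux above `fluxTolerance` in the optimum form the task's
*essential reaction set*; the *essential gene set* is every gene appearing
syntactically in those reactions' gene-protein-reaction (GPR) rules — the
genes that *may* contribute to the function, not only the currently
rate-determining ones.

Two numerical choices matter here:

* **Degenerate optima.** L1-minimal flux patterns need not be unique (e.g.
  two equal-length parallel routes). After the first solve we fix the
  optimal total flux and re-minimise each reaction's flux in lexicographic
  id order, fixing each minimum before moving on. This produces one
  canonical support deterministically. The task collections this method is
  designed for are built so that the shortest route is unique, in which
  case the pass is a no-op; the canonicalisation only matters for
  pathological networks, and `canonical = FALSE` skips it.
* **LP engine.** The task environments are small but highly degenerate —
  closing all exchanges forces many fluxes to zero through equality rows —
  so the package uses a dense two-phase simplex with Bland's anti-cycling
  rule (`R/lp.R`). Bland's rule guarantees termination under degeneracy at
  the cost of speed, which is irrelevant at these problem sizes. The test
  suite cross-checks optimal values against an independent simplex
  implementation and verifies every stored solution against
  $\lVert S v\rVert_\infty < 10^{-6}$.

`fluxTolerance` defaults to `1e-6` in the model's flux units (the solver's
noise floor); supports are insensitive to it over several orders of
magnitude because pFBA solutions at these scales are vertex solutions with
fluxes either exactly zero or of order one.

### From expression to gene scores

Each gene's activity threshold is its mean expression across samples,
clamped into the window between the `lowerPct` = 25th and `upperPct` = 75th
percentile of the overall expression distribution (*local* thresholding).
The clamping keeps constitutively low genes from being declared active by
trivial fluctuations and constitutively high genes from never being
declared inactive. The gene score is

$$\mathrm{GeneScore} = 5\,\log\!\left(1 + \frac{\mathrm{expression}}{\mathrm{threshold}}\right),$$

so a gene at its threshold scores $5\log 2 \approx 3.466$, the same
constant used later as the binary activity cutoff.

Open choices we had to fix:

* **Log base.** Natural log. The internal consistency constraint is only
  that the threshold-level score equal the binary cutoff $5\log 2$ — any
  base satisfies that simultaneously in both places — but the continuous
  scale must be pinned down; natural log matches the convention of the
  constraint-based modelling toolchain family this method belongs to.
* **"Overall distribution".** Percentiles are computed over the per-gene
  mean expression values (one value per gene), not over all gene×sample
  entries; `distribution = "all_values"` switches to the latter. Gene-means
  is the variant consistent with thresholding families that define bounds
  on the *gene activity profile*; with many samples the two differ mainly
  when sample sizes are small or dropout is heavy.
* **Global mode.** With `mode = "global"` a single percentile
  (`globalPct`, default 50) of the overall distribution is used for every
  gene; local mode falls back to global (with a warning) when fewer than
  two samples are available, since a per-gene mean over one sample would
  make every gene sit exactly at its own threshold.
* **Zero thresholds.** An all-zero expression pool would give a zero
  threshold and an undefined ratio; thresholds are floored at the smallest
  positive double, so all-zero genes simply score 0 everywhere.

Scores are invariant to rescaling the whole matrix by any $c > 0$
(percentiles and means are linear), which the tests verify end-to-end for
$c \in \{0.1, 7, 1000\}$.

### Reaction activity and determinants

Gene scores propagate through each GPR rule with min over AND (a complex is
limited by its scarcest subunit) and max over OR (any isozyme suffices).
The reaction activity level (RAL) is the propagated value; the gene whose
score reaches the root is the reaction's *determinant*.

* **Ties** break towards the lexicographically smallest gene id. This
  matters because determinants are counted: a nondeterministic choice would
  make gene significance, and hence scores, run-dependent.
* **Unmeasured genes** (absent from the matrix or `NA`) are dropped from
  their parent operator; a node with all children missing is dropped
  recursively; a rule with no measured gene evaluates to *undefined* — not
  zero. Zeroing would assert that an unmeasured complex subunit is absent,
  which a missing probe or filtered gene does not license. This is the
  package's reading of an underdetermined corner of the method; the
  alternative (treating unmeasured as inactive) can be emulated by adding
  explicit zero rows to the expression matrix.
* Determinant selection follows **value propagation** through the nested
  rule, not a flat min/max over all genes of the rule; for non-nested rules
  the two coincide.

### Task scores

Gene significance in a sample is $S(g) = 1/\#\{$reactions across the union
of all task-essential sets whose determinant is $g\}$; it down-weights
promiscuous enzymes. Because determinants depend on the sample's expression,
$S$ is computed **per sample** ("in the observed condition"); counting once
per dataset would let one sample's hierarchy leak into another's score.

The continuous task score is $\mathrm{mean}(\mathrm{RAL}\cdot S)$ over the
task's essential reactions; the binary call is
$\mathrm{mean}(\mathrm{RAL}) > 5\log 2$, **strictly** — a sample whose
determinants all sit exactly at threshold is inactive; the combined score
is binary × continuous.

* **Denominator.** Reactions with undefined RAL are excluded from both
  numerator and denominator (default), with the fraction measured reported
  as `coverage`; dividing by all task reactions (the literal reading,
  available as `denominator = "all"`) silently biases scores toward zero
  whenever genes are unmeasured, which is the rule rather than the
  exception in single-cell data. `minCoverage` (default 0) turns
  low-coverage scores into explicit `NA` markers instead.
* Scores compare across samples within a task, never across tasks: a task
  relying on constitutively low-expressed genes will always score low. The
  result object documents this; it is not enforced in code.

## Downstream procedures

* **Group similarity.** Observed statistic: mean Euclidean distance over
  all unordered pairs of within-group task-score profiles (a centroid
  variant is available). Null: the same statistic for `nRandom` uniformly
  random same-size subsets of the pool of entities belonging to any
  considered group (groups need more than two members to be considered).
  Empirical p = proportion of null distances **strictly lower** than
  observed, with no +1 correction (a conservative $(r+1)/(n+1)$ variant is
  a flag). Consequence: on a degenerate pool of identical profiles p is
  exactly 0, not small-but-positive. `nRandom` defaults to 10,000; it is a
  parameter because the appropriate depth depends on the smallest p one
  needs to resolve.
* **Binary-combination clustering.** Samples sharing an exact on/off
  signature over the selected tasks (those active in **strictly more** than
  `fraction` = 50% of samples) form a cluster; labels M1, M2, … follow
  canonical signature order (signatures read as binary strings, descending,
  so the all-active signature is M1 when observed). With $k$ tasks there
  are at most $2^k$ clusters; unobserved signatures are omitted but counted
  in the universe size.
* **Trait enrichment.** Per cluster and trait level, a 2×2 table of cluster
  membership against trait presence over samples with non-missing values;
  p is the one-tailed Fisher exact test computed as the hypergeometric
  upper tail (over-representation by default — the direction used when
  asking which clusters are enriched in a pathology — with
  `alternative = "under"` for depletion). The tests verify the tail against
  a direct binomial-coefficient summation on every table with margins ≤ 30.
* **Patient aggregation.** Patients are ranked by the fraction of their
  samples in target clusters; given binary labels the ranking is
  thresholded at the label prevalence (top-$k$, $k$ = number of positives)
  and classification accuracy reported. Ties in the ranking break by
  patient id for determinism.

## The fixture generator

`makeToyModel()` builds disjoint linear pathways, one per task, with GPRs of
selectable complexity (single gene, isozyme pair, two-subunit complex, or
nested `(a and b) or c`), endpoint exchange reactions for the environment
logic to close, and optional one-step bypasses that make the parsimonious
route differ from the obvious chain. The known minimal route is returned as
ground truth, which the test suite compares against exhaustive
minimal-subset search on models of up to 12 internal reactions.

`makeExpression()` draws baseline expression log-normally around a common
scale (default 10, arbitrary platform units; log-scale noise SD 0.1) and
plants each task active or inactive per sample by scaling **all** genes of
its essential set by `effect` = 4 above or `inactiveEffect` = 0.25 below
baseline — all genes, so that min-based AND rules respond and ground truth
is unambiguous. With half the samples active per task, gene means sit
around 2× baseline, so active samples land near ratio ≈ 1.9 (score ≈ 5.3,
above the 3.466 cutoff) and inactive near 0.12 (score ≈ 0.6). Defaults were
chosen once to represent a clear, biologically plausible fold-change regime.

What the fixtures do *not* emulate: single-cell dropout, batch effects,
overlapping pathways sharing genes, platform-specific mean–variance
relationships. Passing the recovery tests therefore demonstrates that the
pipeline's logic is correct and well-calibrated under clean planted signal,
not that any particular sensitivity will be achieved on real data.

## Problem sizes

The shipped tests and the acceptance script run on: toy models of 1–3
pathways (≤ 13 reactions), 1000 random GPR trees of ≤ 8 leaves against a
brute-force evaluator, exhaustive 2×2 tables with margins ≤ 30 for the
Fisher tail, planted-activity recovery over 3 tasks × 200 samples, and
permutation tests at 10,000 random groups. These sizes make every oracle
comparison exhaustive or near-exhaustive while keeping a full run around
half a minute.

## Known limitations

* The SBML reader/writer covers the Level 3 + FBC subset used by
  constraint-based models (species, reactions, flux-bound parameters, gene
  product associations); it is not a general SBML implementation. The BiGG
  style JSON dialect is the primary interchange format.
* The dense simplex is built for task-environment LPs (tens of variables).
  Genome-scale extraction (thousands of reactions) would need a sparse LP
  solver; the scoring path is unaffected since it consumes precomputed
  essential sets.
* One expression platform per dataset is assumed; normalisation and batch
  correction are the caller's responsibility (only global rescaling is
  provably irrelevant).
* GPR semantics are boolean min/max; isoenzyme-specific activity weighting
  and probabilistic rules are out of scope.
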