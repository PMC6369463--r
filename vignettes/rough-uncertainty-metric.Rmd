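---
title: "The rough uncertainty metric: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The rough uncertainty metric: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumselect)
```

## The model

`rumselect` scores attribute subsets of a continuous decision table by how
much uncertainty about the class remains once samples are granulated by the
subset. Three ingredients combine:

1. **Fuzzy similarity.** After min-max normalization, two samples'
   similarity under one attribute is the complement of their absolute value
   difference, zeroed when the difference exceeds `1 - alpha`; a subset's
   relation is the pointwise minimum over its attributes (min t-norm — a
   subset is only as similar as its most discriminating attribute allows).
2. **Fuzzy neighborhood granules.** The radius `alpha` cuts memberships
   below it out of each sample's similarity row. Both cuts — the
   per-attribute one and the final one on the aggregate — are applied as
   stated; the composition is implemented literally even though the second
   cut is almost always subsumed by the first. Granules shrink entrywise as
   `alpha` grows.
3. **Rough decision.** Rather than crisp decision classes, each sample gets
   a graded membership in every class: its similarity mass inside the class
   over its total mass, computed from the *full* attribute set. The rough
   decision is the fixed reference that candidate subsets are scored
   against; accordingly it is built from the un-granulated relation (the
   per-attribute cut at `alpha` applies, the final radius cut does not).
   Row sums are exactly 1 by construction.

The conditional entropy of the rough decision given subset `B` averages
`log2(|granule| / |granule soft-in its class's rough decision|)` over
samples, where the **soft-inclusion cardinality** `|S n T|` counts objects
with nonzero `S`-membership whose membership does not exceed their
`T`-membership. Two semantic points are fixed by the worked five-sample
system that the unit tests pin down: ties count, and objects with zero
`S`-membership never count regardless of their `T` value.

Attribute **significance** is the entropy drop from adding a candidate to
the current subset, and a subset is accepted as a reduct when its entropy
is within the variable-precision tolerance `beta` of the full set's.

## The greedy search

The selection algorithm is the significance-greedy forward search the
definitions jointly imply: starting from the empty subset, add the
candidate with maximal significance (ties broken by the smallest attribute
index, making the procedure fully deterministic) until the `beta` stopping
rule is met. Three guard rails:

- The empty subset is given a well-defined entropy through the *universal
  granule* (every granule is the whole universe): the empty attribute set
  induces the indiscernibility relation that relates everything. Zero
  soft-inclusion counts there are clamped to 1 silently — that clamp is the
  convention, not a pathology.
- Elsewhere a zero granule–decision count (possible on degenerate data when
  the sample's self-membership of 1 exceeds its own rough-decision value
  and nothing else qualifies) is clamped to 1 with a warning; it equals the
  value obtained if only the sample itself counted, and keeps every term
  finite. The worked examples never trigger it.
- If no remaining candidate has significance above `1e-12` while the
  tolerance is still unmet, the search stops and flags the trace as not
  converged instead of looping — with noisy data the criterion can be
  genuinely unreachable.

No backward pass runs by default; `prune = TRUE` removes, in reverse
selection order, any attribute whose removal keeps the subset within
tolerance. The forward pass alone can retain an attribute that a later,
stronger addition makes redundant, which is what pruning addresses.

## Monotonicity has real counterexamples

Growing a subset provably shrinks every granule, and the entropy is claimed
to be non-increasing under subset growth. For the soft-inclusion counting
this is **not** a theorem: an entry that leaves a granule also leaves its
intersection count, and removing a counted member from both the numerator
and denominator of `card/count` *raises* the ratio whenever `count < card`.
The property suite freezes a five-sample counterexample in which adding an
attribute raises the conditional entropy by 0.022 bits, and a seeded scan
of 200 random nested-subset cases finds violations at a rate of a few
percent. The package therefore tests monotonicity empirically and reports
violations rather than silently enforcing the inequality; the greedy search
is unaffected in practice because it only ever moves along steps of
positive measured significance, but "significance is always non-negative"
is deliberately not asserted anywhere. The exact special case that *is*
asserted: an attribute that leaves all granules unchanged (e.g. an exact
duplicate) has significance exactly zero.

## Parameters

| parameter  | default | meaning |
|------------|---------|---------|
| `alpha`    | 0.1     | fuzzy neighborhood radius in [0, 1); larger values cut weak similarities, shrinking granules and filtering noise |
| `beta`     | 0.25    | variable-precision tolerance in bits; the entropy gap a reduct may leave to the full attribute set |
| `gridStep` | 0.05    | sweep increment over [0, 0.5] for both parameters (11 × 11 grid) |
| `cvFolds`  | 10      | stratified cross-validation folds |
| `knnK`     | 3       | neighbours for the KNN classifier |
| `seed`     | 42      | fold assignment (and KNN tie-break) seed |

`alpha` and `beta` interact with the data's correlation structure, and no
single setting generalises across data sets; the sweep exists precisely
because the suitable pair must be found per data set. How to pick the
single preferred row is genuinely open; `bestSweepRow()` implements one
defensible rule — maximise SVM accuracy, then prefer the smallest subset,
then the largest `alpha` and `beta` — and the sweep output keeps every row
so users can apply their own.

A behaviour worth knowing when choosing `alpha`: at small radii the entropy
rewards any attribute that shrinks granules, including class-independent
ones with large spread, because the soft-inclusion count also grows as
memberships fall below the rough-decision values. Informative attributes
dominate once the radius is large enough that between-class similarities
are cut while within-class ones survive. On the synthetic generator's
default conditions this happens around `alpha = 0.45`.

## Evaluation protocol

Accuracy is stratified k-fold cross-validation, pooled over folds, percent
to 2 decimals. Stratification is a deliberate choice: the intended data
sets are small and imbalanced, where unstratified folds are unstable. The
classifiers are fixed: linear-kernel SVM at cost 1 without internal
rescaling (values are already in [0, 1]), and KNN with Euclidean distance
and majority vote. A single seeded split is used, not averaged repeats.
If the smallest class has fewer members than the requested folds, the fold
count drops to that size with a warning. Fold assignment is seeded and the
caller's RNG state is restored afterwards.

## The synthetic generator

`syntheticDecisionTable()` plants known structure so selection and
evaluation are testable without downloads: class-conditional Gaussian
informative attributes (class means `effectSize` apart, centred on 0.5, sd
`noiseSd`, clipped to [0, 1] then min-max rescaled per column so the
similarity semantics stay valid), exact-duplicate redundant attributes, and
class-independent uniform noise attributes, with balanced labels. The
defaults — 60 samples, 2 classes, 2 informative + 1 duplicate + 5 noise
attributes, effect size 0.6, within-class sd 0.1 — are a small,
well-separated two-class design of the kind the method targets; they are
deliberately easy, so passing recovery tests shows correct mechanics, not
robustness.

What the generator does **not** emulate about real expression data:
gene–gene correlation beyond exact duplication, heavy-tailed or batch
effects, class imbalance, and p >> n dimensionality. Results on it say
nothing about those regimes.

Calibration, done once and then frozen: at the default conditions the
suitable pair `(alpha, beta) = (0.45, 0.25)` recovers the planted signal —
both informative attributes selected, no duplicate selected — in 20 of 20
replicate seeds; the regression guard asserts at least 18 of 20. Exact
set equality (no noise attribute tagging along) held in 15 of 20 and is
not guarded: with an effect size this large a single informative attribute
already classifies perfectly, so parsimonious solutions legitimately vary.
For the same reason every sweep cell reaches 100% accuracy there, and the
sweep-recovery check asserts that the preferred row's subset consists of
planted informative attributes, not that it equals the full planted set.

## Numerical choices

- Base-2 logarithms throughout; entropies are in bits. The five-sample
  worked system fixes this: its conditional entropy is 1.0118 bits.
- Boundary cases are closed: a value difference of exactly `1 - alpha`
  keeps similarity `alpha`, and an aggregate of exactly `alpha` survives
  the radius cut. (Tests exercise this with dyadic values, where the
  comparison is exact in floating point.)
- Similarities and memberships are stored at full double precision;
  4-decimal values appear only in displays and frozen test expectations.
- Granule cardinalities and soft-inclusion counts are integers; equality
  assertions on significance of duplicates are exact, not tolerance-based.
- Test problem sizes: property suites use random tables of 4–8 samples and
  up to 4 attributes (where brute-force scalar oracles are cheap and
  counterexample search is dense), 200 replicates for the entropy
  decomposition identity; selection and sweep tests use the 60-sample
  synthetic default with the 11 × 11 or coarser grids.

## Known limitations

- Complexity is O(n²) in samples per similarity matrix and the greedy
  search recomputes granules per candidate step; comfortable for hundreds
  of samples, not engineered for tens of thousands.
- The conditional entropy is not monotone under subset growth (above), so
  the greedy search has no approximation guarantee; it is a heuristic that
  the stopping rule keeps honest.
- `alpha`/`beta` must be tuned per data set; the sweep is exhaustive rather
  than adaptive.
- Only the min t-norm and complement-of-distance similarity are
  implemented; no Gaussian or kernel similarities, and no
  discernibility-matrix or exhaustive minimal-reduct search.
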