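---
title: "Five-taxon Delta-statistics: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Five-taxon Delta-statistics: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltastats)
```

## The problem

The classic D-statistic compares the counts of the discordant allelic
patterns ABBA and BABA on a four-taxon tree: incomplete lineage sorting
produces both with equal probability, so a significant imbalance indicates
gene flow. Four taxa, however, cannot tell which population was the donor
and which the recipient. With five populations the extra symmetry makes
directionality detectable, which is what this package implements: a family
of *Delta-statistics* on the three five-leaf tree shapes

* symmetric `S = (((1,2),(3,4)),5)`,
* asymmetric `A = ((((1,2),3),4),5)`,
* quasisymmetric `Q = (((1,2),3),(4,5))`.

At a biallelic site the allele seen at least three times among the five
taxa is written `A`, the minority allele `B`, giving 15 possible patterns
(5 singletons such as `BAAAA`, 10 doubletons such as `BABAA`). No ancestral
state is inferred and no outgroup polarization is performed — this is the
*outgroup mutation assumption*: population 5 is treated like any other, and
sites where it carries the minority allele are deliberately retained.
Filtering them out would bias exactly the statistics that involve gene flow
touching population 5.

## Equal probability sets and the statistics

Two patterns form an *equal probability set* when a symmetry of the shape
(exchangeability of 1 and 2, of 3 and 4 in `S`, of 4 and 5 in `Q`, once the
relevant lineages sit in a common ancestral population) forces them to be
equally likely under the null hypothesis of no gene flow. Picking one
pattern for the left set and one for the right gives a *binomial*
Delta-statistic `n(L) - n(R)`, mean zero under the null; `binomial_specs()`
lists the twenty used here. Sums and differences of binomials give composed
statistics; after cancelling shared patterns the left and right sets are
disjoint, and the *scaled* statistic is `(n(L) - n(R)) / (n(L) + n(R))`,
always in `[-1, 1]`.

The preferred panels are eight statistics for `S`, four for `A` and eight
for `Q` (`panel_compositions()`). Panel entries right of the divider use
singleton patterns. Singleton symmetry needs the *synchronization
assumption* — the mutation intensity a lineage experiences depends only on
time, not on the population it is in. Ancient samples violate it: a
specimen dead for `d` time units is missing `d` units of terminal branch,
so its private mutations are depleted. Set `include_singletons = FALSE` for
such data; the collapsed panels and tables are used throughout.

Two classical methods are special cases of composed statistics and are
exposed as such: the DFOIL panel (`dfoil_panel()`, with both printed
composition forms agreeing identically through the linear relation
`S1 + S4 = S2 + S3`) and the Partitioned D (`partitioned_d()`, with
`D12 = S5*`, `D1 = -S3*`, `D2 = -S4*`).

One printed formula deserves a note: the published display of the
`Q1+2-6+8*` statistic has a numerator inconsistent with its own
denominator. The compositional definition `Q1 + Q2 - Q6 + Q8` resolves the
ambiguity and is what this package computes; it is the only reading
consistent with the binomial definitions.

## Classification

Under the null and independent sites, `n(L) ~ Binomial(n(L) + n(R), 1/2)`,
so `Z = (n(L) - n(R)) / sqrt(n(L) + n(R))` is approximately standard
normal. A statistic is classified `+` when `Z >= z_crit`, `-` when
`Z <= -z_crit`, `0` otherwise, with `z_crit = qnorm(1 - alpha/2)` computed
at run time (2.576 at the default `alpha = 0.01`; the published account of
the rule carries a sign typo in its `+` branch, and the implementation
follows the reading consistent with the `-` branch and with all published
classifications). The degenerate case `n(L) = n(R) = 0` is classified `0`.
Reported alongside is the 99% Wald interval radius
`z_crit * sqrt(4 n(L) n(R) / (n(L)+n(R))^3)`. No multiple-testing
correction is applied across a panel: `alpha` is per statistic, matching
the method's published usage. Linkage disequilibrium inflates `|Z|` in real
genomes; the package applies no correction (block-jackknife is out of
scope), which is why windowed scans and a per-window binomial `Z` are the
intended usage on real data.

Frequency-mode counts (fractional weights from population allele
frequencies) reuse the same `Z` formula; this is an approximation, since
the binomial sampling argument assumes integer counts of single haploid
draws.

## Prediction tables

The `{+, -, 0}` expectation of every panel statistic under every
unidirectional gene-flow event with a detectable effect is encoded as data
in `prediction_table()`: 32 events for `S`, 18 for `A`, 34 for `Q`; all
other events produce the all-zero signature. The tables were transcribed
from the published classification results of million-pattern simulations,
which the source reports to match the theoretical predictions except for
one flagged event on tree `S` (`3>12`, where two statistics predicted zero
came out weakly positive in their run; the encoded prediction keeps them
zero). The package cross-checks the encoded tables three ways: against the
published classification columns (a transcription test), against the
collapsed-table projection property, and against its own coalescent
simulator (the sign-recovery tests).

Collapsed tables are the projection onto the singleton-free entries, with
events merged when their projections coincide and dropped when the
projection vanishes. Events sharing a signature form an ambiguity class,
labelled by a representative with a trailing `*` (a `<>` label means both
directions of that pair are members); `match_signature()` always returns
the full member list, plus the special categories `"Nothing"` (all-zero
signature) and `"Unknown scenario"` (nonzero but matching no row).
Matching is exact equality on signs — a mixture of two events produces the
union signature, and disentangling it is the purpose of windowed scans, not
of fuzzy matching.

The expected DFOIL signatures (`dfoil_prediction()`) were derived inside
the same framework rather than transcribed: writing
`DFO = (S1 - S2) - (S6 + S8)`, `DIL = -(S1 - S2) - (S6 + S8)`,
`DFI = (S3 - S4) - (S5 + S7)`, `DOL = -(S3 - S4) - (S5 + S7)` and using
`S1 - S2 = S3 - S4`, the four expectations under any event are determined
by one core term and the two singleton-side terms. Anchoring `1>3` at
`(+++0)` and propagating through the relabeling symmetries of tree `S`
(swap 1 and 2, swap 3 and 4, swap the cherries) fixes the signatures of
all eight terminal-pair events; events whose graph is symmetric under one
of those relabelings force the corresponding terms to zero, which fixes
the remainder. The derivation reproduces the known facts that DFOIL is
blind to gene flow into population 5 from terminal branches and that
ancestral donors give `(++00)`-type signatures; the simulator provides an
independent check.

## The coalescent simulator

`species_model()` builds a five-population species tree: within every
population each lineage pair coalesces at rate `lambda` (default 1), time
is measured in units of roughly `2 lambda Ne` generations, and the root of
the five populations sits at time 3. The remaining nodes are placed
roughly evenly per shape: `S` at `(t12, t34, t1234) = (1, 1, 2)`, `A` at
`(0.75, 1.5, 2.25)`, `Q` at `(t12, t123, t45) = (1, 2, 1)`. Mutation
intensity `mu` defaults to `1e-4` per unit time per lineage, and the
admixture proportion `beta` defaults to `0.1`. These defaults are the
study conditions for every simulation experiment in the package.

A gene-flow edge `src>tgt` is instantaneous when the two branches coexist
(the event sits at the midpoint of their overlap): backward in time, each
lineage in the target branch independently switches to the source with
probability `beta`. When the source branch is older, the flow is mediated
by a ghost population joining the source at the source-interval midpoint —
introgression through unsampled relatives is the biologically typical
case, and the admixture branch is allowed nonzero length on purpose. When
the source branch dies before the target is born (a terminal branch
donating into an ancestral branch, such as `3>12`), no time-consistent
edge exists under the default node times; `scenario_model()` then raises
the node closing the source branch to the midpoint between the target's
birth and the next node up. This is legitimate because the predictions are
proven for arbitrary branch lengths and the null symmetries each tree
shape actually uses (1 with 2, 3 with 4 in `S`, 4 with 5 in `Q`) survive
the shift — no equal probability set of any panel statistic relies on the
two cherries of `S` having simultaneous nodes.

Patterns are generated in the exact rare-mutation limit: mutation counts
per branch are independent Poissons, so conditioned on the total number of
patterns the pattern classes are multinomial with probabilities
proportional to the expected subtending branch length. The sampler
therefore draws each pattern from an independent gene tree chosen with
probability proportional to its observable branch length (rejection
against a fixed generous cap; the vanishing fraction of trees heavier than
the cap, of order `1e-7`, is accepted outright) and places one mutation
uniformly. The result is identical in distribution to accumulating Poisson
mutations at vanishing intensity until `n` patterns are collected — and it
makes the null calibration exact: each equal probability set is a true
binomial. Mutations above the sample MRCA are unobservable as polymorphism
and never generated; sites below the MRCA are never constant, so no
rejection loop for constant sites is needed. `drop_mutations()` implements
the literal finite-intensity protocol (Poisson count, uniform placement)
for use on explicit gene trees.

All randomness flows through R's RNG, so `set.seed()` (or the `seed`
arguments) governs everything including the compiled core;
`scenario_suite()` derives per-scenario substreams from its master seed.

## What the simulation experiments show, and their problem sizes

`scenario_suite()` simulates every detectable event of a shape and
compares observed classifications with the prediction table. The package's
validation experiments use 100,000 patterns per scenario for the
singleton-free ("core") statistics and 1,000,000 for the full panels —
at 100,000 the singleton-dependent statistics are underpowered, which
reproduces the source's own observation, and at 10,000 none of the
statistics function well, so that size is used only for null calibration.

Thresholds for these stochastic checks were fixed once by replicate
calibration (three master seeds, both sizes, before the tests were
frozen), not tuned afterwards:

* a *sign flip* (`+` predicted, `-` observed, or vice versa) never
  occurred in calibration and is never tolerated;
* a predicted-zero cell misfires with probability `alpha` by construction
  (a true binomial at the 0.01 threshold), so across the ~140 core
  zero-cells (or ~380 full-panel zero-cells) a small number of borderline
  `|Z|` just above 2.576 is expected and allowed (12 and 13 respectively,
  about three standard deviations above the mean misfire count);
* a few predicted-nonzero cells are genuinely weak under these node times
  (for example both directions between an ancestral cherry branch and the
  far cherry), with expected `|Z|` around 1–3 at 100,000 patterns; up to 8
  misses to `0` are allowed at 100,000 and 5 at 1,000,000.

Null calibration uses 200 replicates of 10,000 patterns: each of the
twenty statistics must reject within three binomial standard errors of the
nominal 1%. The ancient-sample demonstration plants a tip dead at 0.5 time
units in an otherwise null `S` tree: the statistics using that tip's
singletons (`S5+7`, `S3+4-5+7`) classify `+` (the dead tip lacks private
mutations, so its singleton pattern is depleted), while the four
singleton-free statistics stay `0` — the collapsed panel is safe for
ancient data, the singleton panel is not. Statistics whose singletons
belong to other, modern tips (`S6+8`, `S1+2-6+8`) are unaffected.

## Windowed scans

Introgressed material arrives chromosome-sized and is broken down by
recombination, so different genomic windows may carry traces of different
events. `scan_windows()` buckets sites into fixed-width, nonoverlapping
windows anchored at coordinate 1 of each chromosome (reported in 0-based
half-open coordinates; VCF positions are 1-based and converted on read),
computes per-window counts, panels and signatures, and classifies each
window against the prediction table. Windows small enough to satisfy the
*single-event assumption* — each window affected by at most one event —
separate a bidirectional mixture like `2<>3` into windows matching `2>3`
and windows matching `3>2`, while a window containing both shows the union
signature. Window size is a compromise the user owns: smaller windows
satisfy the assumption better but lose power and retain more linkage
between the few sites they contain. Windows with no retained sites are
classified `"Nothing"`; `aggregate_scan()` tallies categories, which
partition the windows.

## Degenerate inputs and numerical choices

* `n(L) = n(R) = 0`: scaled value, `Z` and Wald radius are reported as 0
  and the class is `0` (extending the published zero-count convention).
* Sites with missing data in any taxon are skipped and counted, as are
  multiallelic and constant sites; skip reasons are kept on the counts
  object.
* Diploid genotypes in haploid mode use the first allele of the designated
  sample's genotype — deterministic, matching single-individual usage.
* Frequency-mode weights sum the two complementary products per pattern,
  which performs the complement merge exactly and needs no explicit
  majority call; degenerate 0/1 frequencies reproduce haploid counting to
  machine precision.
* The critical value is computed from `qnorm` at run time, never
  hard-coded.

## What the synthetic data does not emulate

The simulator draws independent sites: no linkage, no recombination, no
window structure, no sequencing error, no reference bias, and a single
haploid lineage per population. Passing tests therefore demonstrate the
mathematics of the statistics and the faithfulness of the implementation,
not robustness to the correlation structure of real genomes — on real
data, per-window `Z` values are inflated by linkage and the `alpha`
threshold is nominal, not exact. Admixture proportions, times and ghost
configurations beyond single unidirectional pulses (and the non-binomial
tree-A statistic mentioned in the source as a possible extension) are out
of scope.
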