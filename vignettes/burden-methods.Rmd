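---
title: "Methods: redistribution, burden, attribution and quality scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: redistribution, burden, attribution and quality scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burdenr)
```

This vignette is the package's account of its methods: the models, the
assumptions behind them, the parameters that matter, and the design
decisions taken where practice leaves the arithmetic open. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## Cause lists and code matching

Causes are defined as inclusive ICD-10 code intervals. Codes are compared
after dot-stripping, upper-casing and truncation to four characters, as in
mortality tabulation practice, so `"i21.9"`, `"I219"` and `"I2194"` all
match a range `I21–I25`, and the closing endpoint is inclusive of its
subcodes (`I259` lies inside `I21–I25`). Intervals of *different* causes
must be disjoint — this is what makes `map_code()` a total function — and
the check is exact because codes order as base-36 integers, independent of
locale. Codes no range covers map to the reserved cause `"_unmapped"`
rather than erroring or being dropped: conservation must remain auditable
even for dirty inputs.

Ages are kept as single integer years 0–100 internally, because years of
life lost needs an exact-age life-table lookup; aggregation to the
conventional five-year groups (open-ended at 85+ by default) happens only
when cells are formed. Sex is a two-level factor, matching the reporting
dimensions of vital registration.

## Redistribution of ill-defined causes

Each record carries a non-negative fractional *weight* in death
equivalents. Redistribution never resamples: a death of weight $w$ assigned
a probability table $\{(t_j, p_j)\}$ becomes one record per target of
weight $w\,p_j$. This makes conservation exact (the suite checks total
weight to $10^{-9}$ relative on every path) and output independent of
record order. A stochastic mode that samples a single target per death
under a stated seed exists for workflows that require whole deaths, but it
is off by default precisely because it conserves only in expectation.

The indirect MCOD pattern for a source cause $s$ is the weight-tally of
underlying causes among records that (i) mention $s$ in their associated
causes and (ii) do not themselves have an underlying cause flagged for
redistribution. Exclusion (ii) is a package decision: it prevents
ill-defined weight from propagating into the pattern that is supposed to
resolve it. Tallies are unstratified by default (age/sex stratification of
patterns is a plausible refinement, but sparse strata would need shrinkage
the package does not attempt). When no eligible mention exists the method
falls back to proportional redistribution over the non-source causes of the
source's own disease group — and over all non-source causes if the group
has none — with a warning, since silently keeping ill-defined weight would
violate the post-condition that no weight remains at a non-retaining
source.

Rules may feed other ill-defined causes (unspecified cancer feeding cancer
of unknown primary, which in turn feeds specific sites). Sources are
therefore processed in topological order, upstream first, so a cascade
collapses in a single pass and equals the closed-form product of its
tables; cyclic rule sets are rejected as configuration errors rather than
iterated to a fixpoint, because a cycle has no auditable interpretation. A
direct-evidence table may retain weight at its own source (the
unknown-primary retention); retained weight is reported separately and does
not count as redistributed, since its cause class did not change. One
consequence is documented rather than hidden: rerunning `redistribute()` on
already-redistributed output is a no-op exactly when no rule retains weight
at its source — retained weight would be split again, because a second run
cannot distinguish it from unprocessed input.

The audit report defines *redistributed fraction* as the share of total
weight whose final cause class differs from its original one (cascaded
weight is not double-counted), the *within-group fraction* as the share of
that moved weight whose destination stays in its origin's disease group,
and *method shares* as the proportion of processed source causes per
method, with a combination rule counted once under `combination`.

## Fatal and non-fatal burden

YLL multiplies deaths by remaining life expectancy at the exact age of
death, linearly interpolated from the standard life table; ages beyond the
table are errors, not extrapolations, because an aspirational table has no
defensible tail. No age weighting and no discounting are applied anywhere.
The standard life table is a configuration input; the package ships a
synthetic demonstration table (life expectancy 91.5 years at birth,
declining exponentially), not any published standard, and applies the same
table to both sexes.

YLD is prevalence-based: prevalent persons per sequela cell are spread over
the sequela's severity levels and weighted by disability weights in
$[0,1]$, so cell YLD can never exceed cell prevalence. Severity proportions
must sum to one per sequela ($\pm 10^{-9}$); every prevalence sequela must
belong to exactly one disease model, and orphans are configuration errors
rather than silently dropped burden. No incidence modelling, internal
consistency adjustment or comorbidity correction is attempted; prevalence
is taken at face value on the output age grouping, with no within-group age
spreading.

DALY is the cellwise sum of YLL and YLD; a component missing from one side
of the join is treated as zero with a note, since YLD-only (e.g. mental
health) and YLL-only causes are both legitimate. The identity
$\mathrm{DALY} = \mathrm{YLL} + \mathrm{YLD}$ is enforced at construction
and preserved bit-for-bit through file round trips by writing the
six-decimal-rounded components and their exact sum.

HALE uses the Sullivan method — the standard construction when, as here,
the name is used without further specification: person-years lived at each
age are discounted by the proportion of that year lived in ill health
(per-age YLD per person, a rate in $[0,1]$), then accumulated like an
ordinary life expectancy. Two identities pin the implementation down and
are tested on random life tables: zero morbidity gives HALE equal to life
expectancy at every age, and constant morbidity $d$ gives
$\mathrm{HALE} = (1-d)\,\mathrm{LE}$.

## Risk attribution

Exposures are categorical; continuous exposures are discretised by the
caller, as no continuous-exposure machinery (distribution fitting, shift
integrals) is in scope. The potential impact fraction compares
exposure-weighted relative risk under the factual and a counterfactual
distribution; the attributable fraction is its special case with the
counterfactual at the theoretical-minimum category, whose relative risk is
1 by convention (a deviation is flagged, not repaired). Where direct
evidence of the attributable proportion exists it overrides the modelled
value. Protective mixes yield negative fractions: they are computed and
reported with a warning but excluded from attributable totals, and no
clipping is applied unless the caller sets a floor. Joint effects across
risk factors are out of scope — overlap needs mediation assumptions the
package does not model — so attributable burdens are per risk-outcome pair
and must not be summed across risks.

## Quality index

The published framework describes two dimensions rated A–E and says the
entity-level index weights each contributing source by its contribution to
the estimate, but not the arithmetic. The package adopts the simplest
monotone scheme consistent with that description: letters score A=1 … E=5,
the entity score per dimension is the contribution-weighted mean, sources
with no methods rating are excluded with the remaining weights
renormalised, and the score rounds to the nearest integer with exact ties
going to the *worse* letter (a conservative tie-break: quality should not
improve on a knife edge). The scheme is scale-free in contributions and
monotone in every source rating — both property-tested — and it reproduces
every recomputable percentage cell of the published summary from the
built-in fixture under half-up rounding at one decimal, which is the only
rounding rule that matches all those cells. One printed aggregate
(risk factors on relevant-or-better data) disagrees with its own counts by
0.1 percentage points in the original table; the package reproduces the
counts, not the slip.

## The synthetic generator

The generator emulates the structure a national multiple-cause mortality
extract presents to this pipeline, not any country's actual frequencies.
Each death draws a true cause from a configured distribution, an age
(rounded normal, default mean 75, sd 15, clamped to 0–100) and a sex
(default an even split). With probability `garble_fraction` (default 0.105,
the order of magnitude a modern vital registration system redistributes)
the underlying cause is replaced by an ill-defined code, drawn from a
configurable distribution over source causes.

The load-bearing assumption is symmetric certificate co-mention with
probability `assoc_mention_prob` (default 0.9): a garbled death lists its
true cause among its associated causes, and a well-certified death lists
the ill-defined condition among its associated causes. The second direction
is what the indirect MCOD tally actually observes — exactly as, on real
certificates, septicaemia appears as an associated cause on deaths whose
underlying cause is specific — and because mentioning is independent of the
true cause, the tallied pattern is an unbiased estimate of the garbled
deaths' true-cause distribution. The recovery test exploits this: after
redistribution, per-cause weights match the generator's realized truth
table within three standard errors of the estimator's sampling noise,
$\sqrt{G\,p(1-p)(1+G/M)}$ for $G$ garbled deaths and a pattern estimated
from $M$ mentions.

What the generator does *not* emulate bounds what passing tests show about
real data: mentioning is independent of cause, age and sex, whereas real
co-mention is strongly differential (septicaemia accompanies some causes
far more than others); garbling is independent of age, whereas real
ill-defined coding concentrates at the oldest ages; associated-cause lists
carry at most one code; and cause frequencies are a round-number sketch.
Recovery on this generator therefore demonstrates correctness of the
estimator, not unbiasedness of the indirect MCOD method under differential
certification — on real data the method inherits whatever selectivity the
certificates have.

## Numerical conventions and problem sizes

Probability tables, severity proportions, exposure distributions and
contribution weights must sum to one within $10^{-9}$; conservation and the
DALY identity are checked to the same relative tolerance. Summary
percentages round half away from zero at one decimal. Degenerate inputs
have defined behaviour throughout: empty record sets and empty burden
tables pass through; an all-zero proportional base falls back to a uniform
split with a warning; an empty indirect pattern falls back as described
above; zero-variance prevalence generation returns medians exactly.

The shipped test suite runs the conservation property on 250 randomized
fixtures through all four paths (1,000 cases), compares the vectorized
indirect tally against a naive double-loop oracle on 200 fixtures of up to
10,000 records, and runs the recovery check at 100,000 deaths for five
fixed seeds — sizes chosen so the whole suite completes in about a minute
on one core while keeping the recovery test's sampling noise far below the
effects it must detect.
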