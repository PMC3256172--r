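---
title: "Methods: miRNA-mRNA association from matched and unmatched expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-mRNA association from matched and unmatched expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirnapair)
```

# Scope and assumptions

`mirnapair` scores putative miRNA–mRNA pairs for associated,
opposite-direction expression changes. It consumes (i) feature-by-sample
expression matrices that are **already normalized and on a log scale** —
platform-specific preprocessing is upstream and out of scope; (ii) a design
table naming one reference condition (e.g. healthy donors); and (iii) a
two-column putative target-pair list from any sequence-based predictor.
Target prediction itself is consumed, never computed. Feature matching
across studies is by exact id string: probe-to-gene summarization and alias
resolution are assumed done, one row per feature.

# Differential expression and discretization

For every feature and non-reference condition we test equality of group
means with a Welch two-sample t-test. The test is deliberately plain: the
input is assumed log-scale and pre-normalized, groups are small and
possibly unequal-variance, and no moderated-variance machinery is used
(a non-goal). The FC-value is `mean(condition) - mean(reference)` in log
units; a feature is DE when `|FC| > fc_threshold` (default 1.5, strict
inequality) **and** the BH-adjusted p-value is below `alpha` (default
0.05). BH is scoped within one feature kind and one condition, matching the
per-group framing of the DE step. Missing values are dropped per feature
and group; fewer than two observations in a group yields `p_raw = 1` and
never a DE call. Discretization then maps each (feature, condition) cell to
+1 (DE, overexpressed in the condition), −1 (DE, overexpressed in the
reference) or 0 (not DE); a DE call with FC exactly 0 is contradictory
input and raises an error rather than being silently coerced.

Multi-study ("master") profiles concatenate the condition columns of two
discretized profiles over the intersection of their features, keeping
features that are nonzero somewhere in the union; overlapping condition
labels are an error because the merge would be ambiguous.

# The unmatched-data measure

A pair's two length-C discretized vectors populate a 3×3 contingency table
whose cell (r, s) counts conditions with miRNA value r and mRNA value s.
The null model is multinomial over the nine cells; its probabilities are
estimated by resampling from the pooled Z×C discretized mRNA matrix:

1. pool all Z×C values;
2. form a jumbled matrix of the same shape whose every entry is an i.i.d.
   uniform draw (with replacement) from the pool;
3. sample `n_rep` rows with replacement — the pseudo-mRNAs;
4. tabulate every pseudo-mRNA against the miRNA's vector and normalize the
   pooled counts.

Two choices deserve note. First, the pooled counts are divided by
`n_rep * C`, not `n_rep` alone: the nine averages must form a probability
vector (unit sum) for the multinomial test to be defined, and dividing by
`n_rep` only would leave them summing to C. Second, both resampling layers
are kept even though step 2 alone already produces exchangeable rows; the
row-resampling in step 3 adds a small amount of extra Monte-Carlo noise but
follows the published construction faithfully. The null is computed once
per miRNA (it does not depend on the candidate mRNA) and shared across that
miRNA's pairs.

Significance is the exact multinomial goodness-of-fit p-value: the total
probability of all 9-cell outcomes with the observed total whose
probability does not exceed that of the observed table. Ties in outcome
probability are included (≤, evaluated with a relative tolerance of 1e−9 on
the log scale so floating-point noise cannot flip a tie). Outcomes
occupying a zero-probability cell contribute nothing; an observed count in
such a cell returns p = 0 with a warning. Full enumeration over all
`choose(C + 8, 8)` compositions is used while that count is at most 5×10⁶
(C ≤ 15 is well inside); beyond it the same quantity is estimated by
Monte-Carlo multinomial sampling with an add-one correction and a reported
standard error. Independently of that limit, the pair test switches to the
Pearson χ² goodness-of-fit approximation when C > 15, the regime where the
approximation is conventionally considered adequate; degrees of freedom
count only cells with positive null probability, minus one.

Pairs are tested only if miRNA and mRNA are nonzero with opposite signs in
at least one condition (miRNAs repress their targets); pairs failing the
filter are reported with status `"filtered"`, never tested, which keeps the
BH family well-defined as exactly the direction-passing candidates. A pair
whose two vectors are all zero carries no information and is flagged
not-testable with p = 1 rather than dropped silently.

# The matched-data measure

With N_ref reference and N_biol case samples measured on the same
individuals, CE-values subtract per-feature reference **medians** — robust
to outliers at the very small N_ref typical of these designs (the default
simulated shape is 3 vs. 14). For two-channel data each array is already a
case-vs-reference contrast, so values pass through unchanged and supplying
a reference group is rejected as contradictory.

The association model is a through-origin regression of mRNA CE on miRNA
CE; the origin is forced because both variables are already changes
relative to the reference state, so a zero miRNA change should predict a
zero mRNA change. The estimator is ordinary least squares,
`λ̂ = Σ x̃ỹ / Σ x̃²`, the minimal estimator consistent with "change in mRNA
expression per unit change in miRNA expression"; a robust alternative was
considered and rejected to keep the null distribution and the estimator
aligned. An all-zero miRNA CE vector leaves the slope undefined and raises
an error.

The permutation null reuses the pool-jumble-resample construction on the
Z×N_biol mRNA CE matrix and computes the slope of every pseudo-mRNA against
the miRNA. The p-value is left-tail, `Pr(λ ≤ λ̂)`, with the add-one
correction `(1 + #{null ≤ obs}) / (1 + n_rep)` so permutation p-values are
never zero. Significance requires both λ̂ < 0 and BH-adjusted p < 0.05
(strict), after a filter keeping only pairs whose average miRNA and mRNA
CE-values have strictly opposite signs; zero averages are dropped with a
warning. The Pearson-correlation comparator runs the same null construction
on the correlation statistic but — as conventionally applied — without the
direction filter, which is precisely why the two measures can disagree: a
pair anti-correlated around same-sign average changes is
correlation-significant yet fails the direction requirement for a
repressive interaction.

Per-miRNA pseudo-mRNA pools are drawn from substreams derived
deterministically from the run seed, so (a) results do not depend on how
many other miRNAs were processed first, and (b) the MD test and the
correlation comparator see identical nulls for the same miRNA, making their
disagreements attributable to the statistic, not the noise.

# Resampling configuration and reproducibility

`perm_config(n_rep, seed)` governs every stochastic step; the conventional
`n_rep` is 10000, and tests use smaller values (300–2000) purely to keep
suites quick. All generator and pipeline outputs are deterministic
functions of (inputs, n_rep, seed); the command-line interface writes a
manifest with the exact parameters and seed of each run.

# The synthetic-data generator

`simulate_matched()` emulates a single-channel matched cohort: per-feature
baselines uniform on [6, 12] log-units, Gaussian noise (default sd 0.2),
case-vs-reference shifts of ±2 log-units for every miRNA, and planted pairs
whose mRNA case values follow the through-origin change model against the
miRNA's realized CE-values — so the generating model is exactly the model
the MD test fits, and in the noiseless limit the slope is recovered to
machine precision. Non-planted mRNAs are independent noise around their
baselines. `simulate_unmatched()` emulates discretized multi-condition
profiles: background entries are i.i.d. over {−1, 0, +1} with
P(nonzero) = 0.1 split evenly between signs, and planted pairs are forced
to opposite-signed values in a chosen number of conditions (default 5 of
9). Default shapes mirror the cohort geometry the measures were designed
around — 3 reference vs. 14 case samples, 9 disease subgroups — with
feature counts scaled down about tenfold (12 miRNAs, 326 mRNAs) so that
simulated pipelines complete in seconds.

What the generator does **not** emulate: probe- and platform-level
artifacts, batch effects, correlated gene modules, heavy-tailed noise, and
mRNAs that are differentially expressed for reasons unrelated to any
planted miRNA. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
feature of real microarray data.

# Validation design and problem sizes

The test suite checks each statistical component against an independent
oracle computed a different way: the exact multinomial test against
brute-force enumeration via `expand.grid` and `dmultinom` (all C ≤ 5, 50
random probability vectors), the table builder against a nested-loop
counter (1000 random vector pairs), BH against a hand-written step-up, and
the slope against a general-purpose no-intercept fit. Calibration runs use
exchangeable null constructions: 500 null pairs at N_biol = 14 and
n_rep = 1000 for the type-I error of the MD test, and unit-scale CE pools
(x ~ N(0,1), pool entries N(0,1), noise sd 0.2, 200 replicates per slope)
for recovery and power — a scale at which the null and the alternatives
overlap enough for power differences between λ = −0.5 and λ = −1 to be
measurable. Recovery of planted unmatched pairs is measured on scenarios
with 50 miRNAs, 1000 mRNAs, C = 9, 20 planted pairs among 1000 candidates
and n_rep = 2000 across ten seeds.

# Known limitations

- **Pooled nulls understate shared reference noise when N_ref ≪ N_biol.**
  In single-channel matched data the reference-median error is a per-feature
  offset shared across all case samples, but the pseudo-mRNA null scatters
  pool values independently, so the null row-means are less variable than
  real ones. With 3 reference samples and noise comparable to the signal
  this inflates small p-values among direction-passing pairs; on
  two-channel (directly contrast-valued) data, where values are
  exchangeable with the pool, the pipeline is calibrated. Interpret
  single-channel MD results at very small N_ref as a ranking rather than
  exact FDR control, or increase the reference cohort.
- The exact multinomial test conditions on the resampled null
  probabilities; their Monte-Carlo error (order `1/sqrt(n_rep * C)`) is not
  propagated into the p-value.
- The UD table extremeness is omnibus: strong *same*-direction
  co-dysregulation also yields small p-values, and only the direction
  filter (≥1 opposite-signed condition) guards the repression
  interpretation.
- Single-miRNA models only: cooperative regulation of one mRNA by several
  miRNAs is out of scope.
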