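---
title: "Methods: dormancy, soil and pH analytics for early establishment in lupins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dormancy, soil and pH analytics for early establishment in lupins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lupinest` analyses early-establishment trials in *Lupinus* built around
three environmental filters studied one at a time: release of physical
seed dormancy (scarified vs intact seeds censused weekly for up to a
year), soil physicochemical context (an ordinal 0–5 establishment score
across contrasting agricultural soils), and substrate pH (organ growth at
pH 5.5 / 7.0 / 8.5 measured 7 and 14 days after sowing). This vignette
documents the statistical procedures, the tunable parameters and the
numerical choices, and what the bundled synthetic-data generators do and
do not emulate.

## Experiment 1: germination and physical dormancy

A trial is one accession × treatment census series: cumulative
germination counts at strictly increasing census days, with the number of
viable seeds as denominator (seeds that never germinate are
viability-checked at the end of the assay, so non-viable seeds are not
counted as dormant). Metrics per trial:

* **FGP** — final germination percentage, `100 * final count / viable`.
* **MGT** — mean day of germination over germinated seeds only;
  undefined (`NA`) when nothing germinated.
* **IVG** — germination velocity index in the Maguire convention,
  `sum(newly germinated at census i / day i)`. The literature holds
  several "velocity" indices; the Maguire sum is the standard one that
  rewards both speed and synchrony, so it is the one implemented.
* **DDS50** — first crossing of 50 % of viable seeds on the cumulative
  curve, linearly interpolated between the bracketing censuses (the
  curve is anchored at 0 on day 0). A trial that never reaches 50 % is
  *right-censored at the horizon* (365 d), never assigned an arbitrary
  large number; the censoring flag travels with the value. The viable-seed
  denominator is this package's documented choice; counts relative to sown
  seeds would differ when viability is imperfect.
* **PD** — physical dormancy, `100 − FGP(NS)`, defined for the
  non-scarified treatment only. `PD + FGP(NS) = 100` holds exactly by
  construction and is asserted in the test suite.

Event times are the census day of first observation: weekly scoring
interval-censors the true germination day, and the package deliberately
collapses the interval to its right endpoint rather than imputing a
midpoint, because that is the observable quantity.

Time-to-germination curves use the product-limit (Kaplan–Meier)
estimator with "survival" = probability of remaining ungerminated, and
groups are compared with the standard log-rank chi-square (df = groups −
1). Both are delegated to the `survival` package and cross-checked in
the tests against a hand-coded product-limit table.

**Dormancy classes.** The class rule (low < intermediate < high) is this
package's explicit construction: the four NS metrics are standardized
with dormancy as the positive direction (MGT, DDS50 as-is; FGP, IVG
negated), the first principal axis of the standardized matrix becomes a
continuous dormancy score (oriented so it increases with dormancy), and
the score is split at its tertiles. Undefined MGT and censored DDS50
enter at the horizon value, which is the most-dormant end of the scale.
Identical metrics for every accession collapse to class `low` — an
arbitrary but documented tie rule. The continuous score reflects the
view that dormancy is a quantitative trait; the tertile cut is only a
reporting convenience.

## Experiment 2: ordinal establishment across soils

Scores on the 0–5 scale map to three nested binary outcomes:
germination (≥ 1), cotyledon emergence (≥ 3), establishment (= 5).
Score 4 (arrested growth or fungal damage) counts toward germination and
cotyledon emergence but never establishment — it is a failure mode, not
a developmental stage — so the nesting establishment ≤ cotyledon ≤
germination holds in every group by construction.

Group rates carry 95 % **Wilson score intervals**. The Wilson interval
is boundary-safe at 0/n and n/n, which matters at the experimental unit
size of five seeds; Wald intervals degenerate there.

The accession × soil performance matrix averages the establishment rate
over the two scarification treatments (computed per treatment first, then
averaged, so unbalanced treatment counts do not bias the cell); missing
cells stay `NA` and are never zero-filled.

**Logistic modelling.** Outcomes are modelled with a fixed-effects
binomial logistic regression fitted by the package's own IRLS routine
(QR-based weighted least squares per iteration, coefficient-change
convergence at 1e−12, Wald covariance from the final Fisher
information). Accession-level clustering is handled by aggregating to
accession-level summaries rather than by random intercepts; the output
metadata records this approximation, and population-average effects under
moderate random-intercept variance are attenuated relative to
conditional (mixed-model) effects — the sign and ordering of effects,
which the downstream synthesis uses, are preserved. Rank-deficient
designs abort naming the aliased columns; diverging estimates
(|coefficient| > 15 on the logit scale) abort with a separation
diagnostic rather than returning meaningless Wald intervals.

The dormancy–establishment link is tested per soil with Pearson r,
Fisher-z 95 % intervals and two-sided t-based p-values; accessions with
censored DDS50 are excluded from the correlation (and counted in the
output) rather than imputed at the horizon, which would manufacture
spurious correlation at the boundary.

## Experiment 3: pH × time seedling growth

Per-seedling traits: total length (hypocotyl + epicotyl, mm), the
hypocotyl-to-epicotyl ratio `H / (E + 1)` (the 1 mm constant stabilizes
seedlings with measured but non-elongated epicotyls), hypocotyl
allocation `H / total`, and binary establishment at total ≥ 30 mm
(inclusive, exactly as defined). Seedlings lacking either organ
measurement are retained in the data with `valid = FALSE`, excluded from
growth analyses, and counted per pH × DAS stratum.

* **Two-way ANOVA** (`response ~ pH * DAS`) reports type-II sums of
  squares via `car::Anova`; the generated designs are balanced, where
  type I and type II coincide, but type II keeps unbalanced real data
  well-defined. The tests verify the full table against an independent
  projection (normal-equations) oracle at 1e−10.
* **Pairwise contrasts** use a seeded permutation null of the maximum
  |t| over all pairwise pooled-variance t statistics. This controls the
  family-wise error rate like Tukey's HSD but replaces the studentized
  range distribution with a permutation distribution; it is exact under
  exchangeability, slightly conservative at finite permutation counts
  (p ≥ 1/(B+1)), and reduces to a plain permutation test with two
  groups. Dunnett-style comparisons are not provided: the designs here
  have no control group.
* **Polynomial pH response** is least squares on pH centered at the mean
  of the design levels, raw polynomial basis. With three pH levels a
  quadratic is saturated in the level means; the fit is flagged
  `saturated` so users do not over-read curvature.
* **Allocation regression** clamps the proportion to [0.005, 0.995]
  before the logit — the data contain exact 0/1 allocations where the
  logit is undefined, and ε = 0.005 keeps the transformed range within
  ±5.3 logits.

## Integration

Accession-level trait tables are z-scored (sample SD, n − 1; constant
columns dropped with a warning), then:

* **PCA** via eigendecomposition of the covariance of the standardized
  matrix (`prcomp`), components ordered by variance, each loading
  column's sign fixed so its largest-magnitude entry is positive —
  a deterministic convention so repeated runs and the test oracle agree.
* **Ward.D2 clustering** on Euclidean distances, silhouette at the
  chosen k (k is an input, default 5; no selection criterion is
  imposed). Node stability is an ordinary bootstrap co-clustering
  support: accessions (rows) are resampled with replacement, the
  resample re-clustered, and a node counts as recovered when its members
  present in the resample form a clade with no outsider. Resamples where
  fewer than two distinct members or no non-member survive are excluded
  from that node's denominator. This is deliberately *not* the
  multiscale-bootstrap AU statistic; the field is named `support` to
  avoid implying it.
* **Spearman screen**: pairwise ρ on midranks, percentile bootstrap 95 %
  intervals (rows resampled), asymptotic p-values, and
  Benjamini–Hochberg step-up q-values over all tested pairs. Constant
  traits yield an undefined marker and are skipped by the correction.

**Integrated Selection Index.** Three components per accession, all from
the pH experiment at DAS 14 and restricted to pH 5.5 and 7.0 (the
alkaline level is excluded so an inhibitory environment cannot dominate
the stability term): mean establishment proportion, mean total length,
and stability `1 / (|est(7.0) − est(5.5)| + 1)`. Establishment enters as
a proportion in [0, 1], so raw stability lies in (0.5, 1]; had
percentages been intended, the min–max rescaling absorbs the difference.
Each component is min–max rescaled to [0, 1] *jointly across all
accessions* (a within-species normalization would change rankings; joint
is the default and the function's contract), a constant component is set
to the neutral 0.5, and the index is the unweighted mean, so ISI ∈
[0, 1], it is invariant to affine rescaling of any raw component, and
improving one component can never lower an accession's index. Ranks are
dense with ties broken lexicographically by accession id, making output
deterministic.

**Recommendations** per soil follow a fixed fill rule: accessions in the
top-n of both the soil establishment ranking and the ISI ranking come
first (ordered by soil rank, flagged `overlap`), then the soil ranking
fills the remaining slots (`fill`).

## Synthetic data: what it emulates, and what it does not

The generators exist so that every stage is testable without any
download, and their defaults are the study conditions of the designs
being emulated: 16 accessions × 2 treatments × 5 seeds censused weekly
to day 365; 48 accessions (three species) × 5 soils × 2 treatments × 3
blocks × 5 seeds; 48 accessions × 3 pH × 2 DAS × 3 replicates × 5
seedlings.

* **Germination** is a cure-fraction process: a seed is impermeable
  with its accession's dormant fraction π_d (0 under scarification);
  permeable seeds draw a gamma germination time (mean 12 d, shape 4 —
  rapid germination typically within ~20 days; scarification rescales
  the mean by 0.7); dormant seeds are released at each census with
  hazard 0.005/week (geometric), leaving strongly dormant accessions
  largely ungerminated within the year. Event times snap to the next
  census day, reproducing the weekly interval-censoring of the real
  observable. The default dormant fractions give a panel of mostly
  low-dormancy accessions with two intermediate and two high, mirroring
  a panel in which a minority shows measurable dormancy.
* **Ordinal scores** come from an ordered-logit latent scale:
  species × soil means (BV depressed despite fertility, MBG3 and COPMO
  permissive, COPSA favourable for *L. albus*, MEC restrictive),
  accession random intercepts (SD 0.5), a scarification shift (+1 logit)
  and logistic noise, thresholded at cutpoints (−2.5, −1.5, −0.5, 0.5,
  1.5).
* **Growth** draws organ lengths around pH × DAS cell means (total
  gain of ~26 mm between DAS 7 and 14 pooled over pH; epicotyl collapse
  at pH 8.5 by DAS 14) scaled by a per-accession lognormal vigour
  multiplier (SD 0.08) and species factors, with 4 mm residual SD,
  left-censored at zero (the normal tail below zero is negligible at
  these means). Each organ is independently missing with probability
  0.108, chosen so that roughly a fifth of seedlings lack at least one
  organ — the order of magnitude of the real exclusion count.

Passing tests on these fixtures demonstrate that the estimators recover
the structure the generators encode — dormant fractions, effect signs,
mean contrasts, calibrated type-I error — not that real trials satisfy
the generators' assumptions: real censuses have contamination and plate
replacement, soils act on germination through correlated physical and
biotic channels absent here, and organ missingness in real data is
likely related to seedling state rather than independent.

Every stochastic function takes an explicit seed; each generator derives
a fixed offset stream from the configuration seed and draws in a
documented order (accessions in panel order, NS before S, seeds in index
order), so identical configuration implies byte-identical output files —
asserted end-to-end in the pipeline tests.

## Problem sizes and reproducibility

The test suite works at deliberately small scale: calibration uses 1000
null replicates for log-rank and ANOVA type-I error and 500 for the
family-wise error of the permutation adjustment (199 permutations each);
parameter recovery uses 1000 seeds for the dormant-fraction check and
100 replicates for the DAS-effect power check. These sizes give
Monte-Carlo standard errors comfortably inside the asserted bands
([0.03, 0.07] around a nominal 0.05; ≤ 0.07 family-wise; ≥ 99/100
detections).

`run_pipeline()` executes simulate → germination metrics → soil
outcomes → pH growth → integration in order, fails fast with
stage-named errors, and writes every table as CSV plus a JSON manifest
recording the config digest, all derived seeds, row counts and output
paths. `scripts/acceptance.R` re-runs the same computations from scratch
against the installed package and writes the headline numbers as JSON.

## Known limitations

* No mixed-model variance components: accession heterogeneity is
  simulated and aggregated over, not estimated.
* No parametric (hydrotime/thermal-time) germination models; the
  survival machinery is non-parametric.
* Cluster count k and the PCA components retained for reporting are
  inputs, not inferred quantities.
* The bootstrap co-clustering support is not comparable numerically to
  multiscale-bootstrap AU p-values.
* Repeated measures across DAS are treated as independent samples, as
  the factorial design does.
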