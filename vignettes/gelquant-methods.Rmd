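---
title: "Methods: bootstrap differential analysis of 2-DE spot volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bootstrap differential analysis of 2-DE spot volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelquant)
```

## The measurement and its model

A 2-DE experiment separates a protein extract by isoelectric point and
molecular mass; each resolved spot is quantified on each gel as an
integrated, background-subtracted densitometric volume in arbitrary units.
The data for one study form a spots × gels matrix of non-negative volumes
with missing entries where a spot was not detected on a gel, plus a design
mapping gels to groups (cultivars) with a small number n of biological
replicates per group — n = 4 in the design this package emulates.

Spot volumes are positive, right-skewed and noisy at small n, and whole
gels differ by multiplicative staining/loading factors. The pipeline
therefore assumes, and the synthetic generator implements, a
multiplicative error model: the volume of spot *s* on gel *g* is
log-normal around `baseline_s × multiplier_{s,group(g)} × scale_g`, with a
replicate coefficient of variation `cv_replicate` (mean parameterization,
so the sample mean of a null spot estimates its baseline).

## Stages

### Presence and reproducibility

A spot is *present* in a group when detected (non-missing; an explicit 0
counts as detected) on at least `min_present_replicates` gels of that
group, default 3 of 4. Spots present in at least one group are retained
("validated"); the rest are discarded. We deliberately use an *any-group*
rule rather than an all-groups rule: spots reproducibly present in one
group and absent from another — *unique* spots — are the strongest
qualitative differences and must survive filtering (an all-groups rule
would make the ±∞ fold-change case unreachable). `presence_scope = "all"`
is available for the stricter reading. A group with 1–2 stray detections
below the threshold is treated as absent: its mean is 0 and the stray
values are excluded from resampling, keeping unshared-spot semantics
consistent.

### Total-density normalization

Each volume is replaced by `raw / total_g × C` where `total_g` is the
gel's summed validated-spot volume. `C = "mean-total"` (default) keeps the
output on the raw scale; any positive constant (e.g. `1e6`, ppm) may be
supplied. After normalization all per-gel totals are equal, so a per-gel
rescaling of the input is removed exactly — with a fixed `C` the
normalized table is strictly invariant, with `"mean-total"` it is
invariant up to one common factor, which cancels in FC and is absorbed by
the RC denominator. Pixel-level background subtraction is upstream: the
input volumes are assumed already background-subtracted as exported by the
imaging software.

### Bias-corrected percentile bootstrap

For each spot and ordered group pair (x, y), B = 2000 resamples are drawn
with replacement, independently per group and of the same size as the
observed group. The default statistic is the difference of means
DV = ȳ* − x̄*; the bias-corrected percentile interval at confidence
1 − α uses

* `z0 = Φ⁻¹(p)`, `p` = proportion of resampled statistics strictly below
  the observed one, clamped to `[1/(2B), 1 − 1/(2B)]` before the probit
  (Φ⁻¹ is undefined at 0/1);
* endpoints at the empirical quantiles `Φ(2·z0 + z_{α/2})` and
  `Φ(2·z0 + z_{1−α/2})`, using linear interpolation between order
  statistics (`stats::quantile`, type 7) — fixed so alternate conventions
  can be compared;
* a degenerate resampling distribution (all values equal) yields the
  zero-width interval at that value; ties are kept as-is (no jitter).

With `p = 0.5` the construction reduces exactly to the plain percentile
interval. Intervals are widened for multiplicity by Bonferroni:
the level becomes `1 − (1 − confidence)/m` with family size m = number of
group pairs (3 here) by default. The per-spot family is the default
because it reproduces differential fractions of the order typically
reported for such designs; a global spots × pairs family can be requested
via `bonferroni_family` and is far more conservative. A spot is
significant for a pair when the adjusted interval for DV excludes 0.

"Assess differences between group means by bootstrap CIs" also admits a
second reading — per-group mean intervals, compared for overlap — so
`mode = "group_ci_overlap"` implements it: each present group gets its own adjusted BC interval (an
absent group contributes the point interval [0, 0]) and the spot is
significant when the intervals are disjoint. Neither mode is privileged
on statistical grounds alone; the difference-interval mode is the default
because it operationalizes the stated comparison directly. The overlap
mode is strictly more conservative in practice.

For unshared spots the absent group has mean 0 and is excluded from
resampling, so the statistic reduces to ±(present group's resampled
mean) — consistent with the FC = ±∞ convention.

### Effect sizes

For significant entries only (non-significant entries are reported `ns`):

* **FC** = ȳ/x̄; values below 1 are replaced by −x̄/ȳ, equal means give
  +1, and an absent group gives ±∞ regardless of the magnitude.
* **RC** = DV/|DVR_max|, with DVR_max the maximum-|DV| entry across the
  significant results of *all* pairs jointly. We interpret the maximum in
  absolute value (not the signed maximum): RC is specified to range over
  [−1, +1] and the extreme entry may be negative, which is impossible
  under a signed-max reading. Exactly one entry (up to ties) attains
  |RC| = 1 in any non-empty run. When a spot is absent from both groups
  of a pair the comparison is not applicable (`N/A`).

RC is preferred over FC as a general effect measure precisely because it
stays bounded and comparable across shared and unique spots.

### PCA and reporting

PCA runs on gels × significant spots with missing entries imputed as 0 —
absence is informative; unique spots are what separates groups most.
Columns are centered; unit-variance scaling is off by default (covariance
PCA, which keeps high-abundance spots influential) and is exposed as
`scale` for a correlation PCA. Component signs are fixed by making each component's
largest-magnitude loading positive, so results are platform-reproducible.
The report aggregates validated/significant counts (percentages rounded
half-up, 1 decimal; a 0-decimal variant for identification-rate style
figures), per-pair counts, the formatted FC/RC table and the PCA variance
summary, and echoes the full configuration including seeds.

## The generator as study stand-in

Defaults mirror the emulated study: 345 spots, 3 groups × 4 replicates,
22% differential spots (log2 shifts drawn uniformly from 0.5–2, direction
± with equal probability), 3% unique-to-one-group spots, replicate
CV 0.25, 5% detection dropout, per-gel log-normal scaling with log-sd 0.2.
No within-group CV is fixed by the emulated design, so 0.25 is our choice
of a realistic replicate CV for densitometric spot volumes; it is a
visible config parameter, not a constant. Baselines are log-normal (median ≈ 5000
arbitrary units, log-sd 1) to produce the strong dynamic range of real
gels. One master seed drives deterministic per-stage substreams, so
individual stages are reproducible in isolation.

What the generator does **not** emulate: spot detection/matching errors,
saturated regions (e.g. the dominant storage-protein zone of potato gels),
spatially correlated staining artifacts, and missingness that depends on
abundance (dropout is independent of volume). Passing tests therefore
validate the statistical pipeline on its own assumptions, not the imaging
steps upstream of it.

## Measured operating characteristics

The test suite measures (rather than assumes) the procedure's behavior at
n = 4; problem sizes were chosen to keep each property estimable in a few
seconds to a couple of minutes:

* **Coverage.** Unadjusted 95% BC intervals for a mean of 4 normal
  observations (2000 simulated samples, B = 1000) cover the truth ~79% of
  the time. Percentile-family intervals are known to under-cover at very
  small n; the suite asserts the measured band (0.72–0.88) and this
  document records it.
* **Null error rate.** On 20 null datasets at study scale
  (no true effects, B = 2000), ~13% of spots per pair are flagged in
  difference mode (~8.5% in overlap mode) — above the 5% one might expect
  from the Bonferroni-adjusted nominal level. Two mechanisms, both
  faithful to the procedure: the small-n anticonservatism above, and
  detection dropout occasionally leaving ≤2 detections in one group,
  which makes a null spot look unique and such spots are flagged almost
  surely. Conclusions from this pipeline at n = 4 should treat
  "significant" as a screening call, not a calibrated 5% test.
* **Power.** Spots with |log2 shift| ≥ 1.5 are flagged in >99% of
  pair-comparisons involving the affected group across 20 seeded runs —
  far above the null rate, so the screening ranking is informative.
* **RC bound.** In every run with a non-empty significant set,
  max |RC| = 1 exactly and all |RC| ≤ 1, by construction of the
  DVR_max normalization.
* **Oracle agreement.** For n = 4 the full resampling distribution of the
  mean has 4⁴ = 256 atoms and is enumerated exactly; Monte-Carlo BC
  endpoints at B = 20000 agree with the exhaustive-distribution endpoints
  within 0.15 volume units on ≥95% of 100 seeds.

## Known limitations

* The bootstrap is anticonservative at n = 4 (above); the Bonferroni
  family default (pairs, not spots × pairs) is a screening choice.
* Missing-as-zero PCA imputation overstates separation when dropout is
  abundant-dependent in real data.
* FC/RC are ratios of means; they inherit the means' sensitivity to
  outliers at small n.
* Volumes are unit-free; no cross-study calibration is attempted.
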