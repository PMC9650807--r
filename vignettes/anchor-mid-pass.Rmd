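---
title: "Anchor-based MID and PASS estimation: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-based MID and PASS estimation: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(midpass)
```

## The estimation problem

Patient-reported outcome instruments produce bounded scores whose clinical
meaning is not self-evident: a 7-point drop on a 0–100 disability scale may
or may not matter to patients. Two complementary thresholds translate scores
into patient-relevant terms. The *minimal important difference* (MID) is the
smallest change patients perceive as beneficial; the *patient acceptable
symptom state* (PASS) is the score level at which patients consider
themselves well. Both are estimated against an *anchor*: here, a 7-level
satisfaction item (1 = "Very satisfied" … 7 = "Very dissatisfied") asked at
every scheduled visit. This is a *current-state* anchor — participants rate
how they are now, not how they compare to baseline — which avoids the recall
bias of retrospective transition items; retrospective anchors are
deliberately unsupported.

The unit of MID analysis is the *consecutive-interval change pair*: for a
participant observed at adjacent scheduled visits with both anchor and score
present, Δ = score(t+1) − score(t) paired with the anchor transition. A
skipped or incomplete visit breaks the chain — no pair ever spans a gap,
because a 6-month change and a 3-month change are not exchangeable
observations. Missing data are handled by complete-case exclusion at the
pair level only; no imputation is attempted, which is defensible when
per-visit missingness is in the 5–10% range the generator emulates and would
need rethinking beyond that.

Two anchor dichotomies coexist by design. The ROC and predictive methods
compare *any improvement* (anchor moved ≥ 1 level toward satisfaction)
against *not better* (same or worse); the mean-change and mean-difference
methods use *exactly one level* of improvement, the group whose mean change
operationalises a "minimal" perceptible improvement. The not-better group is
shared, and anchor worseners always stay in it — dropping them would bias
both ROC and mean-difference estimates toward zero.

## The four MID estimators

**ROC.** All pairs are ranked by Δ and the empirical ROC curve of the
improved/not-better classification is scanned for the threshold minimising
$(1-\mathrm{Se})^2 + (1-\mathrm{Sp})^2$ (closest-to-top-left). Candidate
thresholds are the *midpoints between consecutive distinct pooled values*,
plus $\pm\infty$ sentinels, so no observation ever sits exactly on a
threshold even with heavily tied integer scales; observed-value thresholds
would make the ≤/< convention consequential, midpoints make it moot. Note
estimates can therefore differ from observed-value conventions by up to half
the score resolution. Ties in the distance are broken deterministically:
higher sensitivity first (an MID is used to detect improvement), then the
threshold nearest the pooled median (the least extreme claim), then
curve order. Determinism here is not cosmetic — the bootstrap would
otherwise mix selection rules across resamples.

**AUC.** Discrimination is the Mann-Whitney concordance probability (ties
count ½), computed from midranks. Its CI is a stratified bootstrap
percentile interval by default (2000 resamples); a DeLong
structural-components interval is available (`auc_ci(method = "delong")`)
and is cross-checked in the tests against direct enumeration and against
pROC.

**Mean change** is the arithmetic mean of Δ among one-level improvers with
a normal-theory t interval. **Mean difference of change** subtracts the
not-better group's mean and uses a Welch interval; whether the original
convention in this literature is Welch or pooled-variance is not knowable
from published descriptions, and Welch is the safer default when group
variances differ (improvers are usually more variable).

**Predictive modelling.** A logistic regression of improvement status on Δ
gives intercept C and slope B; the MID is the change score at which the
likelihood ratio of belonging to the improved versus not-better group
equals 1:

$$\mathrm{MID} = \frac{\ln\!\big(p/(1-p)\big) - C}{B},$$

with p the observed proportion improved. The prior-odds offset matters: the
naive −C/B is the *posterior* odds-1 point and is biased toward the
majority group whenever p ≠ ½. Under equal-variance Gaussian change
distributions the true coefficients make the offset cancel exactly, so the
estimator targets the group-mean midpoint at any p — the property the
simulation suite exploits. Complete separation or non-convergence raises an
error pointing at the ROC method instead of returning a meaningless MLE.
The later small-sample "adjusted MIC" correction to this estimator is not
implemented; only the original likelihood-ratio definition is offered.

All bootstrap CIs are *percentile* intervals (2.5/97.5 of the resampled
statistic): the simplest construction consistent with a plain
"nonparametric bootstrap" description, at the cost of the known small-n
undercoverage that BCa would partially repair. ROC bootstraps are
*stratified* (resampling within improved and not-better groups separately),
preserving the group ratio that the closest-to-top-left criterion is
computed under; the predictive and Spearman bootstraps resample pairs
jointly, since the proportion improved is part of the estimator. Pairs from
the same participant at different intervals are treated as independent, in
estimation and resampling alike — the pooled primary analysis is defined
that way — and the within-participant correlation this ignores is the main
caveat on the CI widths.

## PASS

PASS is a state threshold, so it is estimated from the records' own scores
pooled over all visits against the satisfied (anchor ≤ 2) / not-satisfied
dichotomy. The ROC method reuses the cut-point machinery unchanged. The
percentile method takes the score quantile among satisfied participants
that leaves 75% of them at or beyond the threshold: the 75th percentile for
higher-is-worse instruments, the 25th for higher-is-better. Quantiles use
linear interpolation between order statistics at index $h = q(n-1)$
(`quantile(type = 7)`); published descriptions never state the rule and
rules differ by up to one resolution step on small samples, so one rule is
fixed and documented. PASS CIs (bootstrap, same conventions) are computed
as an extension; published PASS tables traditionally omit them.

## The credibility gate

MID/PASS estimates are only as good as the anchor. The screen computes
Spearman's rho (Pearson on midranks) between the anchor change and (1) the
outcome change, (2) the prescore, (3) the postscore, each with a bootstrap
CI. Instruments with |rho(change)| below the threshold have every MID/PASS
cell *withheld* — marked as such in the tables, never silently dropped, so
a consumer of the report can see what was screened out and why. The default
threshold of 0.3, with labels poor (< 0.3) / moderate (0.3–0.5) /
good (≥ 0.5), is a documented convention consistent with how such
correlations are described in the clinimetric literature, not a claim of a
universal rule; at moderate correlation the gate warns rather than refuses.
The gate is direction-symmetric: reflecting an instrument flips rho's sign
but not credibility.

## The synthetic cohort

Real anchor–outcome trial datasets are rarely shareable, so the package
generates its own with the statistical structure the analysis assumes.
Each participant has a latent disability trajectory
$L_{it} = \mu_t + b_i + e_{it}$ with a decreasing mean curve
$\mu = (46, 30, 20, 14, 10)$ over the five default visits (6 weeks, 3, 6,
12, 24 months), participant effect $b_i \sim N(0, 15^2)$ and visit noise
$e_{it} \sim N(0, 8^2)$. The anchor is an ordinal cut of
$L + N(0, 5^2)$ at cutpoints (12, 32, 52, 72, 92, 112); each instrument
observes an affine map of $L$ plus its own noise, rounded to its resolution
where the scale is discrete, clipped to bounds last. Missingness is MCAR at
5% per cell.

Defaults were calibrated once so that, at the default size of 124
participants, the first-visit DASH-like instrument has mean ≈ 46 (SD ≈ 19),
roughly 40–45% of usable consecutive intervals show anchor improvement
(~400 pairs survive complete-case pairing out of 496), the DASH-like
anchor-change correlation sits near 0.5, the pain-on-activities-like and
Constant-like instruments near 0.35 and −0.45, and the pain-at-rest-like
instrument — whose loading on the latent trajectory is deliberately tiny —
stays below 0.25 and is withheld by the gate. Those parameter values are
the package's fixed study conditions; they are set in `cohort_config()`
and are not adjusted per analysis.

What the generator does *not* emulate: informative dropout (missingness is
MCAR only, as no dropout mechanism is identifiable from small reported
missing-item counts), treatment arms, floor/ceiling-driven skew beyond what
clipping induces, and any within-participant correlation structure beyond a
single random intercept (the true serial correlation of repeated anchors is
unknown; the random-effect SD is an exposed modelling choice, not a fact).
Passing tests on this cohort therefore demonstrate internal consistency of
the estimators under a plausible data-generating process, not agreement
with any particular trial's numbers.

A second generator, `generate_two_group()`, bypasses the trajectory model
entirely: improver and non-improver change distributions are specified
directly, so `true_targets()` can return closed-form values — the
group-mean midpoint for ROC and predictive (equal variances), $\mu_1$ for
mean change, $\mu_1 - \mu_0$ for mean difference — against which the
estimators are validated.

## Validation scale and numerical conventions

The test suite validates: exact agreement of ROC cut-points, PASS
cut-points and AUC with brute-force exhaustive search on 200 random tied
instances (n ≤ 30 per group); recovery of the Gaussian analytic limits at
n = 5000 per group (ROC and predictive within ±0.5 of the midpoint, mean
change within ±0.2, mean difference within ±0.3); estimator means within 2
Monte-Carlo standard errors of their closed-form targets over 200
replicates × 5 configurations at 400 pairs; ≥ 90% empirical coverage of
the nominal-95% percentile CIs for the ROC cut-off, predictive MID and
Spearman rho over 500 replicates at n = 150 per group with 400 bootstrap
resamples (percentile intervals run a few points below nominal at this n,
hence the 90% bar); Spearman's rho against the bivariate-normal closed form
$(6/\pi)\arcsin(r/2)$; and exact direction symmetry — reflecting a
higher-is-worse instrument to higher-is-better negates every MID and maps
every PASS to scale_max + scale_min − estimate. These problem sizes keep
the full suite in the minutes range on one core while leaving Monte-Carlo
error well below the asserted tolerances.

Degenerate cases are handled explicitly rather than by accident: empty ROC
classes error; bootstrap resamples whose pooled values are all tied (no
finite threshold) or whose logistic fit separates are redrawn and counted;
constant vectors make Spearman's rho an error, not NaN; a MID whose sign
contradicts the instrument's improvement direction triggers a warning but
is still reported, since sampling noise can legitimately flip a weak
signal. Every stochastic operation takes an explicit seed and restores the
caller's RNG state; nothing depends on hidden global state, which is what
makes the pipeline's JSON output byte-reproducible.

## Limitations

Estimates inherit the anchor's quality: a single-item satisfaction anchor
conflates symptom state with expectations, and the gate can only detect
weak correlation, not bias. Pair-level pooling ignores within-participant
correlation, so CIs are somewhat narrow if participants contribute many
pairs. The ROC cut-point is noisy at realistic cohort sizes (its sampling
SD at ~400 pairs spans several score points); the bootstrap CI conveys
this, and method disagreement in the reports is informative rather than a
defect. MID is estimated for improvement only; deterioration thresholds
are a different estimand and are out of scope.
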