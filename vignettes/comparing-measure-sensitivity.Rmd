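---
title: "Comparing the sensitivity of disparate repeated-measures outcomes"
author: "zsens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing the sensitivity of disparate repeated-measures outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zsens)
```

## The statistical model

The package addresses one question: in a fully within-subject study that
records many heterogeneous dependent measures, which measures respond
most strongly to the manipulation? The obstacle is scale: a reaction time
in seconds, a mood score in questionnaire points and a hormone
concentration in pmol/L cannot be compared directly, and neither can
their raw effect estimates.

The procedure places all measures on a common scale before comparing
them. Write $X_{ijm}$ for subject $i$'s value on measure $m$ at session
$j$ ($i = 1..n$, $j = 1..T$, $m = 1..M$). For each measure the full pool
of $nT$ observations — deliberately discarding the repeated-measures
structure for this one step — yields a grand mean $\bar X_m$ and grand SD
$\sigma_m$, and

$$z_{ijm} = \frac{X_{ijm} - \bar X_m}{\sigma_m}.$$

After the transform every measure has grand mean 0 and SD 1 exactly, so
session-to-session movements of different measures are in the same
(unitless) currency. Three layers of analysis follow.

**Quality-control gate.** Standardization is a positive affine map, and
every within-subject F statistic is invariant under positive affine maps
of a measure's data. The pipeline therefore re-runs the per-measure
one-way RM-ANOVA on both raw and z-scored data and requires F and p to
agree to 1e−9 (`qcEquivalence()`); "identical" is read as equal up to
floating-point round-off. This catches data-handling errors (mislabeled
sessions, values scrambled between the two analysis passes), not
statistical problems — hence the strict tolerance, and hence the default
of aborting the pipeline on failure (`strictQC = TRUE`).

**Omnibus two-way ANOVA.** The z-scores enter a fully within-subject
Time × Measure ANOVA (`rmAnovaTwoWay()`). Each effect is tested against
its own subject-interaction stratum (time vs subject×time, measure vs
subject×measure, interaction vs the three-way residual). The measure main
effect is analytically null on z-scores — every measure's marginal mean is
exactly the grand mean, 0 — so its sum of squares is floating-point noise
and $p = 1.000$; this is a built-in positive control. The scientific
content is the time × measure interaction: a significant interaction
means the measures disagree about the time course, i.e. they differ in
sensitivity, which licenses the per-measure follow-ups.

**Per-measure follow-ups.** For each measure: a one-way RM-ANOVA across
sessions; orthogonal polynomial trend contrasts (`polyContrasts()`,
`testTrend()`); and Fisher's LSD pairwise comparisons of all session
pairs (`lsdPairwise()`), deliberately with *no* multiplicity adjustment —
the goal is a comparable per-measure count of significant results, not a
family-wise confirmatory claim, so uniform per-comparison error rates
across measures are exactly what is wanted. With four sessions the
quadratic contrast is the focal one: the expected stress trajectory is an
inverted U (departure from baseline during the two stress sessions, a
near-return at recovery). The evidence is then aggregated per measure
(`summarizeSensitivity()`): significance counts over the $T-1$ contrasts
and $T(T-1)/2$ pairs, and the standardized change magnitudes
$|\Delta z| = |\bar z_{\cdot am} - \bar z_{\cdot bm}|$ for designated
session pairs.

## Sphericity and the Greenhouse–Geisser correction

Within-subject F tests assume sphericity (equal variances of all pairwise
level differences). The package always estimates the Box/Greenhouse–
Geisser $\hat\varepsilon$ and reports the corrected p alongside the
uncorrected one; downstream significance decisions use the corrected p.
$\hat\varepsilon$ is computed from the eigenvalues $\lambda_r$ of the
double-centered level covariance,
$\hat\varepsilon = (\sum_r \lambda_r)^2 / ((k-1)\sum_r \lambda_r^2)$,
clamped to $[1/(k-1), 1]$, which is algebraically the classical formula on
an orthonormal contrast basis (the test suite verifies the two routes
against each other). In the two-way design each effect gets its own
epsilon from its own contrast covariance: the time-collapsed and
measure-collapsed subject profiles for the main effects, and a Kronecker
product of orthonormal contrast bases for the interaction. A single
pooled epsilon for all effects is a known alternative convention; the
per-effect version is used because the three error strata are distinct
and there is no reason to tie their correction factors together.

One fine point: the common claim that the GG correction "always increases
the p-value when F > 1" is not exactly true. Shrinking numerator and
denominator df by the same factor can slightly *lower* the tail
probability for F just above 1; in simulation this only ever happens far
into the null region (uncorrected p above roughly 0.25). The property the
tests assert is the one that matters for decisions: conservativity of the
corrected p wherever the uncorrected p is at or near the rejection
region.

Degenerate designs — zero error variance, as happens with constant or
exactly-patterned toy data — are reported rather than raised: $F = \infty,
p = 0$ with a `degenerate` flag (or $F = 0, p = 1$ when the effect is zero
too), so a batch run over many measures does not abort on one pathological
column.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | two-sided level for every significance decision and count |
| `sdDenominator` | `"n-1"` | grand-SD denominator for z-scoring |
| `errorTerm` | `"separate"` | error term for contrasts and LSD tests |
| `qcTolerance` | 1e−9 | max allowed F/p discrepancy raw vs z |
| `deltaPairs` | (1,2), (1,3) | session pairs for the reported \|Δz\| |

Two of these deserve justification. The SD denominator ($n-1$ vs $n$) is
genuinely undetermined by the method's description: either choice leaves
every F, t and p downstream unchanged (affine invariance again), and only
rescales z magnitudes by $\sqrt{n/(n-1)}$ — about 0.4% at $n = 136$
pooled values. The sample SD is the default because it is what `sd()`
computes and what a reader will reproduce first; the option exists so
both conventions are available. The error-term choice for follow-ups is
likewise a convention the method's description leaves open: the default
uses each contrast's own error variance (per-subject contrast scores /
paired differences, df $n-1$), which is the mainstream default in modern
software and is robust to sphericity violation; the pooled variant
(omnibus $MS_{error}$, df $(n-1)(k-1)$) is available via
`errorTerm = "pooled"` for users matching older ANOVA programs.

`deltaPairs` defaults to baseline-vs-stress-1 and baseline-vs-stress-2.
Baseline-vs-recovery is excluded by default on purpose: measures are
expected to return toward baseline at recovery, so that comparison is
uninformative about sensitivity to the stressor.

The ranking key in `rankMeasures()` — omnibus significance, then total
significance count, then max |Δz|, with ties sharing a rank and the key
echoed in the output — is an explicit operationalization of a judgment
that is otherwise made informally by inspecting tables and bar charts.
It weighs exactly the three evidence classes the summary computes, in
decreasing order of how coarse they are. Users who weigh the classes
differently can sort the summary table themselves; the point of the
default is determinism and auditability, not a claim of optimality.
There is deliberately no formal test that one measure is *significantly*
more sensitive than another; the method provides ordering evidence, not
a between-measure inference.

## The synthetic-data generator

No subject-level dataset is distributed with this package, so the
generator is a first-class module, not a test shim. It emulates the
canonical design the method targets: `simulateStressStudy()` produces 34
subjects × 4 sessions × 18 measures. The model is

$$X_{ijm} = \mu_m + \sigma_m\,(\delta_{jm}\,d_m + b_{im} + e_{ijm}),$$

with per-measure native-unit baselines $\mu_m, \sigma_m$, effect
trajectory $\delta_{jm}$ in baseline-SD units, direction $d_m \in
\{+1,-1\}$, subject random intercepts $b_{im} \sim N(0,
\sigma^2_{subj})$ independent across measures, and residuals $e_{ijm}
\sim N(0, \sigma^2_{within})$. In the default variance-normalized mode
$\sigma^2_{subj} + \sigma^2_{within} = 1$, so $\sigma_m$ is the total SD
and the injected $\delta$ are effect sizes in total-SD units — directly
comparable across measures, which is the very property the analysis is
meant to detect.

Defaults, chosen once as a realistic rendering of a multi-stressor field
study:

* **Baselines** (`defaultProfiles()`): native-unit means/SDs typical of
  these instruments in healthy military populations, e.g. PVT mean RT
  0.30 s (SD 0.03), POMS Total Mood Disturbance 20.0 (17.8), cortisol
  0.2 µg/dL (0.1), NPY 84.5 pmol/L (29.4). Their only role is to make the
  raw data realistically incommensurable.
* **Trajectories**: inverted U, $(0, d, d, d/4)$ — the quarter-size
  session-4 entry encodes near-return to baseline at recovery.
* **Effect classes**: $d = 0.9$ for the seven mood sub-scales and
  cortisol, $0.45$ for the response-timing metrics, testosterone and NPY,
  $0.15$ for the accuracy counts, $0$ for BDNF. These express the
  qualitative sensitivity ordering repeatedly reported for mood scales
  versus cognitive and hormonal measures under severe stress, with
  magnitudes in the moderate-to-large range such stressors produce.
* **Variance split**: $\sigma^2_{subj} = \sigma^2_{within} = 0.5$, i.e. a
  between-session correlation of 0.5 — mid-range for test-retest
  correlations of cognitive/mood instruments over days.

The Gaussian random-intercept structure is compound-symmetric, so
sphericity holds *by construction* and $\hat\varepsilon$ concentrates
near 1. Two escape hatches exercise the machinery beyond that comfortable
regime: session-specific residual SDs (a `withinSD` vector) break
sphericity, and `family = "lognormal"` substitutes a variance-matched
right-skewed residual for robustness checks.

What the generator does **not** emulate — and what green tests therefore
do not certify about real data: skewed and bounded score distributions
(count floors, questionnaire ceilings), hormone assay noise and diurnal
structure, missingness mechanisms (the generator is always complete;
real-data missingness is handled only by complete-case deletion),
correlations *between* measures (real mood sub-scales correlate highly;
measures here are independent given the session), and any systematic
session-order effect other than the injected trajectory.

## Numerical and validation choices

Calibration and recovery claims about the statistics are checked by
simulation in the test suite at fixed problem sizes, chosen to make the
binomial checks sharp while keeping a full run in the low minutes: the
type-I-error check uses 1000 replicates of the 34-subject null design
(all $\delta = 0$) and compares the pooled per-measure one-way rejection
rate at $\alpha = .05$ against a 99% binomial interval — the uncorrected
p is used there because compound symmetry makes that F test exact, while
the GG-corrected test is mildly conservative under an estimated epsilon;
the ranking-recovery check runs 50 replicates of a 100-subject design
with effect groups $d = 0, 0.3, 0.8$ and requires the group-median
ranking to come out in the true order in at least 95% of replicates.

Other numerics: polynomial contrasts are reduced to exact smallest-integer
form (orthogonality then holds in integer arithmetic); epsilon estimates
are clamped to their admissible interval before use; sums of squares are
guarded against tiny negative round-off; long-CSV output writes doubles
with 17 significant digits so write→read round-trips are exact; and the
analysis path contains no randomness, so identical inputs produce
byte-identical report bundles.

## Limitations

Fully within-subject designs only: no between-subject grouping factors,
no unbalanced estimation, no imputation. Sessions are assumed equally
spaced for the trend contrasts. Sphericity handling is GG-only (no
Huynh–Feldt, no Mauchly pre-test). The significance-count indices inherit
the usual caveats of vote counting — they are sensitive to $n$ and to
$\alpha$, and the package intentionally provides no permutation-based
assessment of whether one measure's count credibly exceeds another's.
How much of a difference in counts and magnitudes is *practically*
significant remains a judgment for the investigator.
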