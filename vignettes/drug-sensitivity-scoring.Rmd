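---
title: "Quantitative drug sensitivity scoring: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative drug sensitivity scoring: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsskit)
```

## The problem

High-throughput drug sensitivity and resistance testing (DSRT) measures the
viability of cancer cells — cell lines or primary patient cells *ex vivo* —
across a panel of compounds, each plated in a dilution series (typically five
concentrations in 10-fold dilutions, spanning a 10,000-fold range, e.g.
1–10,000 nM). Summarizing each dose–response curve with a single parameter
such as the IC50 discards most of the curve: two compounds with identical
IC50 can have very different efficacy (top asymptote) and therapeutic window.
The drug sensitivity score (DSS) implemented here summarizes the whole fitted
curve as the analytic area between the curve and a minimum activity level,
normalized to a 0–100 scale, and supports differential scoring against
healthy-donor controls, responder sub-group detection, drug clustering by
response profile, and kinase-addiction scoring.

## Normalization and the response scale

Raw per-well readouts (e.g. CellTiter-Glo luminescence) are converted to
relative growth inhibition using the per-plate negative control (DMSO, 0%
inhibition) and positive control (benzethonium chloride, 100% inhibition):

$$\mathrm{inhibition} = 100\,\frac{\bar{c}_{neg} - \mathrm{raw}}{\bar{c}_{neg} - \bar{c}_{pos}},$$

clipped into [0, 100]. Clipping treats apparent growth stimulation as 0%
inhibition: DSS is designed as an area measurement with baseline noise
subtracted, and negative inhibition would otherwise leak into the scores.
Technical replicates are collapsed to their median per dose, including the
two-replicate case.

## The response model

Each curve is fitted with a four-parameter logistic in log10 concentration
$x$:

$$R(x) = R_{min} + \frac{R_{max} - R_{min}}{1 + 10^{\,s(m - x)}}$$

with bottom asymptote $R_{min}$, top asymptote $R_{max}$ (percent
inhibition, $0 \le R_{min} \le R_{max} \le 100$), log10 IC50 $m$ and slope
$s > 0$. The positive-slope constraint makes "inhibition does not decrease
with dose" structural; data with a genuinely decreasing trend settle on a
flat line ($R_{min} \approx R_{max}$), which is the model's honest answer
for them.

Fitting is bounded nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`), entirely deterministic: a fixed multi-start (slope starts
0.5, 1, 2; $m$ starting at the dose closest to the half-maximal response),
plus a coarse deterministic $(m, s)$ grid whose per-cell asymptotes come
from a closed-form linear solve, with the best cells polished by further
least-squares runs. Ties in the residual sum of squares are broken toward
the smallest slope, then the smallest $m$. Bounds: asymptotes in [0, 100],
$s \in [0.1, 10]$, and $m$ within the tested window widened by 2 log10
units — IC50 extrapolation is limited to 100× beyond the tested range
because extrapolated IC50s are notoriously dependent on the tested window.
Degenerate plateaus (zero response variance, e.g. an entirely inactive
compound) skip optimization: both asymptotes are set to the common level;
$m$ and $s$ are unidentifiable there and the scores depend only on the
asymptotes. On noiseless model data the fit recovers the generating
parameters to better than $10^{-6}$ across slopes 0.3–5; near-noiseless
data additionally trigger a finer grid scan because essentially-perfect
fits stuck above machine precision signal a shallow decoy valley.

Curves with fewer than three distinct concentrations are not fitted; their
scores propagate as missing.

## The scores

Given an activity threshold $A_{min}$ (percent inhibition; default 10,
reading the threshold as the assay's baseline-noise level — configurable),
the integral response over the tested window $[x_{lo}, x_{hi}]$ is

$$I = \int_{x_1}^{x_2} \left(R(x) - A_{min}\right)\,dx,$$

where $x_2 = x_{hi}$ and $x_1$ is the fitted curve's crossing of $A_{min}$
(clipped into the window), the lower bound if the curve is always above the
threshold, and the integral is zero if $R_{max} \le A_{min}$. The
antiderivative is closed-form:

$$F(x) = (R_{min} - A_{min})\,x + \frac{R_{max} - R_{min}}{s \ln 10}
  \ln\!\left(1 + 10^{\,s(x - m)}\right),$$

evaluated with a numerically stable softplus. The crossing $x_1$ uses the
fitted curve (not the first measured dose above threshold), consistent with
the continuous-model reading of the method. The three score variants are

* $\mathrm{DSS}_1 = 100\,I / \big((100 - A_{min})(x_{hi} - x_{lo})\big)$ —
  the area relative to the maximum attainable, so a compound at 100%
  inhibition across the whole window scores exactly 100;
* $\mathrm{DSS}_2 = \mathrm{DSS}_1 \cdot \log_{10}(\max(R_{max}, 1)) / 2$ —
  the $\div \log_{10} 100$ normalizer equals 1 at full efficacy and
  penalizes compounds that never reach high inhibition;
* $\mathrm{DSS}_3 = \mathrm{DSS}_2 \cdot (x_2 - x_1)/(x_{hi} - x_{lo})$ —
  additionally penalizes activity confined to a narrow high-dose window,
  favouring potency over a wide therapeutic window.

These two normalizer choices are this package's algebraic interpretation of
the verbal contracts attached to the score variants; they satisfy every
stated property ($\mathrm{DSS}_3 \le \mathrm{DSS}_2 \le \mathrm{DSS}_1$,
all zero exactly when $I = 0$, anchor at 100, unit-shift invariance) and
are deliberately isolated in one internal function (`dss_from_params()`) so
a different algebra can be swapped in by editing a single place.

The comparators are the discrete Activity Area,
$AA = \sum_i \max(0, \mathrm{response}_i)/100 \in [0, n_{doses}]$ (negative
responses clipped so the zero bound is exact under noise), and the relative
IC50, $10^m$, reported as missing when $R_{max} \le A_{min}$.

By default each curve is scored over its own tested window; a fixed
cohort-wide window (in nM) can be imposed so scores are comparable across
drugs tested at different ranges.

## Differential scores and responder sub-groups

dDSS subtracts, per drug, the mean score of the control samples (missing
controls excluded). Controls keep their own differential scores — they sum
to zero per drug — which makes the control-to-control variability visible in
the same units.

Drug-sensitive sub-groups are detected from the right tail of a drug's
score distribution: the moment skewness $\gamma = m_3 / m_2^{3/2}$ is
tested one-sided with D'Agostino's (1970) normal approximation (valid from
$n = 8$). Membership of the sub-group is not defined by the detection
statistic alone, so this package uses iterative peeling: remove the maximum
value, re-test, and stop as soon as the remaining distribution is no longer
significantly right-skewed; the responders are the removed top-$k$. This
ties membership deterministically to the detection statistic; its
characteristic failure mode is peeling one value too many or too few when
the re-test is marginal, which is bounded by the test's size (about 5%).
Benjamini–Hochberg FDR across drugs is reported alongside the raw p-values
(raw is primary), and a Wilcoxon rank-sum test of responders versus the
rest confirms each detected sub-group. The rank-sum test uses the exact
null distribution when both groups have at most 20 observations and no
ties, otherwise midranks with tie-corrected variance and continuity
correction.

## Metric evaluation

Given externally supplied activity labels per curve, each response metric
is evaluated by AUROC (midrank formula; ties count half; IC50-style metrics
are negated via `orientation = "lower_is_active"`), and pairs of metrics are
compared with DeLong's paired test computed from placement values. When the
variance of the AUROC difference degenerates (identical or rank-identical
score vectors) the difference is reported as zero with $p = 1$ and a
degeneracy flag rather than dividing by zero.

## Response-profile clustering

Drug profiles (typically dDSS across samples) are compared with Spearman
rank correlation (pairwise-complete; pairs overlapping in fewer than 3
samples get the maximum observed distance as a conservative separation),
clustered with Ward linkage applied to the un-squared dissimilarity
(`ward.D`): the rank-based distance has no Euclidean embedding, so the
squared-Euclidean Ward dialect is not meaningful here. Branches are cut
adaptively: a static cut at 99% of the maximum merge height defines
candidate branches, branches of at least 3 items (mirroring the exclusion
of mechanism-of-action classes with fewer than three drugs) become cores,
leftover items join the nearest core by average distance, and with no cores
everything is one cluster. This is a simplified "tree"-variant of dynamic
branch cutting without the medoid-refinement stage, whose extra heuristics
are not identifiable from the method description; the simplification is
fully deterministic.

Agreement with annotation classes uses pair-counting indices (Rand,
Hubert–Arabie adjusted Rand, Jaccard, Fowlkes–Mallows). Differences between
two clustering solutions are tested against a permutation null: item labels
are shuffled within each observed solution independently (cluster counts
and sizes preserved), the index difference is recomputed per permutation
(10,000 by default), and the empirical p-value is the fraction of null
differences at least as large as observed. Permutation p-values are
near-uniform under the null at realistic panel sizes (tens of drugs); with
very few items the index difference is too discrete for uniformity, which
is a property of the statistic, not of the implementation.

## Kinase addiction (KISS)

For one sample, the KISS of kinase $k$ aggregates the sample's dDSS over
the inhibitors that target $k$ and whose response distribution across the
cohort shows significant positive skewness ($p < 0.05$, one-sided
D'Agostino on the dDSS distribution — the dDSS scale is used because
eligibility is about cohort-selective response). The aggregate divides by
the number $n_k$ of contributing inhibitors: averaging keeps kinases with
different inhibitor coverage comparable and preserves rankings whenever
coverage is equal; the divisor is a single switchable argument
(`aggregate = "sum"`). Kinases with no eligible inhibitor are absent, not
zero. Affinity-valued target matrices are binarized at a threshold (default
1000 nM). Addiction networks connect kinases with KISS above a threshold
(default 5) when the Spearman correlation of their drug-selectivity columns
exceeds 0.5, optionally restricted to an expressed-kinase list; networks
export to SIF and GraphML.

## The synthetic cohort generator

The generator produces seeded, fully reproducible cohorts emulating the
study conditions: 5-point 10-fold dilution series (1–10,000 nM) for patient
screens or the 8-point CCLE series (2.5–8,000 nM); additive Gaussian noise
on the inhibition scale (default σ = 5 percentage points), clipped to
[0, 100]; cohorts of 20 patients and 4 controls by default, mirroring the
proportions of an ex vivo leukemia screen.

Backgrounds are defined on the score scale: each drug draws a base DSS1
uniformly in 7–15 (weak-to-modest activity, IC50 towards the top of the
tested window), and each sample adds a shared sensitivity effect (uniform
±3, representing overall sample quality / cellular composition) plus
bounded per-curve biological variation (uniform ±6). Each curve's top
asymptote is then solved so its true DSS1 hits the target exactly. Two
properties motivated this design over drawing curve parameters directly:
(1) the between-sample score variation of an unplanted drug is symmetric by
construction, so the skewness-based responder detector stays calibrated —
DSS is a convex function of the top asymptote in the weak-activity regime,
and symmetric parameter noise would otherwise masquerade as a responder
tail; (2) the bounded (uniform) supports avoid floor/ceiling truncation
that would re-introduce skew. Curve-fitting noise on 5-point series is
itself mildly right-skewed (occasional steep step-like fits overestimate
the area), so the symmetric biological variation is deliberately the
dominant source of between-sample spread, which is also the regime in which
a normality-based skewness test is applicable to real screens at all.

Planted responder sub-groups set the named samples' true DSS1 to the
drug's background mean plus the stated effect (+25 by default in the tests,
mirroring a four-sample sub-group against a quiet background), solving the
curve parameters exactly before noise. Planted mechanism-of-action classes
share a per-sample latent factor that shifts both efficacy and potency of
all drugs in the class, inducing the correlated profiles that clustering
should recover. The generator does not emulate plate-position artifacts,
batch effects, heavy-tailed measurement noise, or the polypharmacology that
blurs real MoA classes — so passing tests demonstrate correctness of the
scoring machinery under the stated model, not robustness to those
real-data phenomena.

## Problem sizes and numerical choices

The test and acceptance suites run at desk scale by design: 200 noisy
curves for parameter recovery, 10,000 null replicates for the skewness-test
calibration, 100 cohorts of 24 samples × 4 drugs for responder recovery,
588-point parameter sweeps for the closed-form-versus-quadrature check
(tolerance $10^{-6}$ relative, with the quadrature oracle evaluated on
panels so the threshold-crossing kink is resolved), and 500 × 1,000
permutations for the null-uniformity check. Fitting tolerances are
$10^{-15}$ (ftol/ptol); the closed-form integral uses a stable
$\ln(1 + 10^u)$ evaluation; score-matrix CSVs round-trip exactly through
`readr`'s shortest-round-trip number formatting.

## Known limitations

Confidence intervals on fitted parameters and scores are out of scope, as
are alternative response models (Hill variants), plate-layout corrections,
and consensus clustering. The exact algebra of the two DSS normalizers
follows the verbal contracts rather than a published derivation, and is
isolated behind one function for that reason. The adaptive branch cut is a
simplified, deterministic variant of dynamic tree cutting. Reported
sub-group memberships should be confirmed by inspecting the underlying
dose-response curves before any decision-making use.
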