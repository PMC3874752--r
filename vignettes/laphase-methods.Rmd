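---
title: "Phasic left atrial quantitation: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasic left atrial quantitation: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laphase)
```

## Scope

`laphase` quantifies phasic left atrial (LA) size and emptying function
from cine-derived planimetry measurements and evaluates those indices as
markers of elevated left ventricular end-diastolic pressure (LVEDP). It
also ships a synthetic-cohort generator so the whole chain — volumetry,
phase extraction, diagnostic statistics, agreement analysis — can be tested
against known ground truth. This vignette is the package's account of the
underlying models, the numerical choices, and what the synthetic world does
and does not establish.

## Volumetry

LA volume is computed by the biplane area-length method,

$$V = \frac{0.85 \, A_1 A_2}{L},$$

with $A_1$, $A_2$ the planimetered LA areas in the 2- and 4-chamber
long-axis views (cm²) and $L$ the LA length perpendicular to the mitral
annulus center in the 4-chamber view (cm); $V$ is in mL and is indexed to
body surface area for reporting (mL/m²). The LA appendage is never
modeled. Volumes below a configurable plausibility floor (default
1 mL/m²) are rejected rather than propagated: they would otherwise poison
ratio denominators and downstream statistics silently.

The three emptying fractions all share the $LAV_{max}$ denominator:

$$\mathrm{LAEF_{Total}} = \frac{LAV_{max}-LAV_{min}}{LAV_{max}}, \quad
\mathrm{LAEF_{Passive}} = \frac{LAV_{max}-LAV_{ac}}{LAV_{max}}, \quad
\mathrm{LAEF_{Contractile}} = \frac{LAV_{ac}-LAV_{min}}{LAV_{max}}.$$

Two consequences are used as invariants: passive + contractile equals total
(to ≤ 1e-12 in floating point, since only one shared division is involved),
and BSA indexing cancels, so fractions from indexed and absolute volumes
are identical. Fractions are stored in $[0, 1)$ internally and rendered as
percentages only in reports, avoiding double-scaling bugs.

## The time-volume curve model

Each synthetic patient carries a ground-truth triple
$LAV_{min} < LAV_{ac} < LAV_{max}$ and a cyclic curve over one RR interval,
sampled at the patient's cine frame count. Frames are 0-based with frame 0
at the R-wave (LV end diastole), matching retrospective ECG gating; times
are in ms. Four cosine-blended monotone segments give the physiologic
morphology:

1. **Reservoir rise** from $LAV_{min}$ at frame 0 to $LAV_{max}$ at the
   end-systolic landmark (40% of the cycle);
2. **Conduit fall** to a diastasis level by 65% of the cycle;
3. **Diastasis**, a gently rising plateau reaching $LAV_{ac}$ at the
   atrial-contraction-onset landmark (85% of the cycle);
4. **Contractile fall** back to $LAV_{min}$ at the final frame.

The cosine blend has zero end-slopes, so segments join smoothly; each
segment is monotone between values inside $[LAV_{min}, LAV_{max}]$, so the
curve never leaves the ground-truth envelope, and the three landmark values
are hit exactly (segment endpoints are assigned outside the blend formula —
`cos(pi)` is exact but the affine recombination is not). The diastasis
level sits strictly below $LAV_{ac}$ (at least 10% of the contractile
volume above $LAV_{min}$, at most a quarter of the passive drop below
$LAV_{ac}$), making the pre-contractile peak a genuine local maximum.

The frame count is set by heart rate to keep temporal resolution near
35 ms — `round(RR / 35)` clamped to the configured 20–30 range — matching
how retrospective gating trades phases against heart rate.

## Phase extraction

**Single-phase** reads the triple at supplied valve-event frames:
$LAV_{max}$ just before mitral valve opening, $LAV_{ac}$ immediately prior
to atrial contraction, $LAV_{min}$ at mitral valve closure. The frames are
inputs (in practice they come from visual cine review); the method never
searches.

**Multi-phase** uses only the curve:

* $LAV_{max}$: maximum within ventricular systole, i.e. frames in the
  first half of the RR interval;
* $LAV_{min}$: minimum over the end-diastolic window — the final 15% of
  the RR interval plus frame 0 (cyclic). Anchoring the search temporally
  guards against noise-induced spurious minima mid-conduit;
* $LAV_{ac}$: the pre-contractile peak, located by `detect_ac_onset()`:
  the frame of steepest negative slope within the final diastolic third is
  the contraction onset, and the last local maximum of late diastole at or
  before it is the $LAV_{ac}$ frame.

Ties break toward the earliest frame, for determinism.

**Smoothing.** A centered cyclic 3-frame moving average can be applied
before landmark detection (default: on when the data carry measurement
noise, off otherwise). A deliberate asymmetry: smoothing steers the
*search*, but extracted volumes are always read off the *raw* curve at the
located frames. Taking the maximum of raw noisy frames over a 10–15-frame
window inflates $LAV_{max}$ by extreme-value selection (≈ +1.8 mL/m² at 3%
planimetry noise in our measurements); reading smoothed values instead
flattens genuine peaks. Locating on smoothed, reading raw keeps the
single-vs-multi-phase bias below 0.5 mL/m² at that noise level while
leaving noiseless extraction exact.

**Degenerate morphologies.** A flat curve (range < 5% of the mean volume,
configurable — the failure criterion is our construct, since phase
identification is genuinely ambiguous when the LA barely changes volume)
returns a flagged $(V, V, V)$ triple. A single-peak curve with no atrial
kick has no pre-contractile local maximum; $LAV_{ac}$ then collapses to
$LAV_{min}$ (no booster contribution to attribute) and the record is
flagged. Extracted triples that violate the phasic ordering — possible
under heavy noise in either method — are flagged with a warning, excluded
from downstream statistics, and counted; the pipeline log reconciles input
and analyzed n.

Multi-phase search windows are R-wave-anchored by design, so rotating the
frame origin changes them; rotation invariance holds (and is tested) for
the single-phase method, whose event frames rotate with the data.

## The synthetic cohort

The generator emulates an LVEDP-dichotomized catheterization population.
Defaults are the published group summaries the package targets: elevated
(LVEDP > 12 mmHg, prevalence 14/41): $LAV_{min}$ 35 ± 20, $LAV_{ac}$
48 ± 18, $LAV_{max}$ 56 ± 21 mL/m², LVEDP 22 ± 7 mmHg; normal: 22 ± 9,
37 ± 11, 44 ± 13 mL/m², LVEDP 9 ± 2 mmHg. LVEDP is sampled truncated at
the 12 mmHg boundary per group (the groups are defined by the threshold,
not by a mixture fit), so every patient's label is consistent with its
pressure by construction.

**Correlation structure.** The three volume indices share a latent factor
with loading `index_cor` (default 0.95, calibrated to the published
inter-index correlations of 0.896–0.953) plus an LVEDP link: each index
regresses on the patient's standardized within-group LVEDP deviation with
coefficient `lvedp_link_rho` (default 0.3). The link is standardized by
the *truncated* group moments, so it shifts no group means. The pooled
(whole-cohort) LVEDP–volume correlations that emerge, ≈ 0.45–0.55, bracket
the published 0.41–0.54; the printed correlations are treated as empirical
outcomes to compare against, not as generative truth.

**Ordering and calibration.** Triples are rejection-resampled (cap 1000,
then error) until $LAV_{min} < LAV_{ac} < LAV_{max}$ and positivity hold —
resampling rather than clipping avoids distorting tails. Conditioning on
acceptance, however, shifts the accepted means (by ≈ +0.15 SD in the
elevated group with default parameters, mostly through the positivity
constraint's interaction with the shared factor). The generator therefore
pre-adjusts its proposal means by the conditioning shift, estimated once
per parameter set by a fixed-seed internal Monte Carlo (200,000 draws, two
fixed-point iterations, cached; the caller's RNG stream is saved and
restored). With this calibration the sample means recover the configured
values within 3 standard errors at $n = 10^4$, which the test suite checks.

**Measurement model.** Biplane projection inverts the volume formula
frame by frame: $L$ follows geometric similarity
($L = 1.4\,V^{1/3}$ cm, giving lengths near 5–6 cm for typical LA
volumes), $A_2/A_1$ is a fixed aspect ratio (1.1), and each of $A_1$,
$A_2$, $L$ receives independent multiplicative Gaussian noise (default
relative SD 3% — planimetry error scales with structure size). Error
propagation gives a per-frame relative volume error of
$\sqrt{3}\times 3\% \approx 5.2\%$, which the tests verify by Monte Carlo.
Distinct observers get independent noise draws. BSA (normal, 1.95 ± 0.25
m², truncated to [1.2, 2.6]) exists only to convert indexed and absolute
volumes; heart rate is normal 70 ± 12 bpm truncated to [40, 120].

## Diagnostic statistics

LVEDP is dichotomized strictly: elevated iff > 12 mmHg, so boundary
patients are normal (the text-and-table convention; a figure caption that
reads "≥" is treated as a typographical variant). AUC is the empirical
Mann–Whitney pair statistic with ties counted ½, oriented per index —
higher volumes and lower fractions are disease-like — and its two-sided p
against 0.5 uses the DeLong placement variance (the conventional default
of the clinical ROC tooling the analysis emulates). With zero placement
variance (perfect separation) p degenerates to 0, or 1 at AUC exactly 0.5.

Cutoffs maximize Youden's $J$ over midpoints between consecutive distinct
observed values (the standard empirical-ROC construction — deterministic,
and perfect separation yields the midpoint rule). Ties in $J$ break toward
the higher-specificity operating point, the behaviour that reproduces
specificity-leaning published cutoffs; it is a documented, configurable
convention, not a statistical necessity. Group comparisons use the
pooled-variance Student t by default (Welch by flag). No multiple-testing
correction is applied anywhere, deliberately mirroring the emulated
analysis; readers should interpret the per-index p-values accordingly.

## Agreement statistics

Bland–Altman differences are single-phase minus multi-phase; the report
gives the mean difference, SD of differences (the "±" convention adopted
for published biases, the standard reading), and 1.96-SD limits of
agreement. Lin's CCC is computed with population (n-normalized) moments,
as in Lin's original definition:

$$\mathrm{CCC} = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2},$$

so $|\mathrm{CCC}| \le |r|$ always, with equality only when means and
variances match — a property the suite tests on 10⁴ random pairs. The
replicate study mirrors the published design scale: 5 randomly selected
cases, 2 observers, fresh planimetry noise per observer, both extraction
methods quantified, CCC per index.

## What a green test does not establish

The synthetic world states its assumptions; three matter most.

* **Observer noise is purely statistical.** Both methods read the same
  per-frame measurements, so multi-phase reproducibility is degraded only
  by landmark-detection jitter. Measured over 40 seeded replicate studies,
  that effect is at parity with single-phase — the package does *not*
  reproduce the published finding that single-phase concordance (0.99/0.98)
  clearly exceeds multi-phase (0.92/0.90). We read that gap as the cost of
  human contouring across 20–30 frames and of visual phase ambiguity,
  neither of which this noise model emulates. The agreement tests
  therefore assert high concordance and parity, not the published
  direction.
* **Curve morphology is idealized.** Real curves carry beat-to-beat
  variation, diastasis that shortens or vanishes at high heart rate, and
  arrhythmia; the generator's four-segment family does not. Extraction
  accuracy on generated curves is an upper bound.
* **The printed cohort statistics are cohort-specific.** AUCs, cutoffs and
  sensitivities from a 41-patient sample carry wide confidence intervals;
  the acceptance suite checks the qualitative orderings (AUC of
  $LAV_{min}$ above $LAV_{max}$, $\mathrm{LAEF_{Total}}$ above
  $\mathrm{LAEF_{Passive}}$, all indices discriminating) on 50 seeded
  cohorts of n = 400, not numeric equality at n = 41.

## Reproducibility

Every stochastic stage accepts a seed; the pipeline derives per-stage seeds
from one global seed (kept within 32-bit range), and a fixed-seed pipeline
run is byte-identical across invocations — checked at file level in the
acceptance suite. Output CSVs are written so that write → read → write is
byte-stable (numbers serialized at full `as.character` precision).

```{r example}
cohort <- sample_cohort(cohort_config(n_patients = 41, seed = 1))
table(cohort$group)
p <- cohort[1, ]
cv <- build_curve(p)
mp <- extract_multi_phase(cv)
c(max = mp$lav_max == p$true_lav_max,
  ac = mp$lav_ac == p$true_lav_ac,
  min = mp$lav_min == p$true_lav_min)
```
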