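# laphase

Phasic left atrial (LA) volumetry from cine cardiac imaging, and its
diagnostic evaluation against elevated left ventricular end-diastolic
pressure (LVEDP).

## The problem

The left atrium works in three phases across one cardiac cycle: it fills
during ventricular systole (reservoir), drains passively in early diastole
(conduit), and contracts in late diastole (booster pump). Three volumes
capture this: LAV<sub>max</sub> at LV end systole (just before mitral valve
opening), LAV<sub>ac</sub> in late diastole immediately before atrial
contraction, and LAV<sub>min</sub> at LV end diastole (mitral valve
closure). Because the atrium is exposed to LV filling pressure whenever the
mitral valve is open, these volumes — and the emptying fractions derived
from them — are candidate noninvasive markers of elevated LVEDP.

`laphase` implements the complete quantitation and evaluation chain for
clinicians and methodologists studying these indices:

* **Biplane area-length volumetry** — `V = 0.85 · A1 · A2 / L` from
  planimetered 2- and 4-chamber areas and the LA long-axis length, indexed
  to body surface area (mL/m²).
* **Phase extraction**, by both methods used in practice: *single-phase*
  (volumes read at visually identified valve-event frames) and
  *multi-phase* (landmarks detected automatically on the full time-volume
  curve).
* **Emptying fractions** —
  LAEF<sub>Total</sub> = (LAV<sub>max</sub> − LAV<sub>min</sub>)/LAV<sub>max</sub>,
  LAEF<sub>Passive</sub> = (LAV<sub>max</sub> − LAV<sub>ac</sub>)/LAV<sub>max</sub>,
  LAEF<sub>Contractile</sub> = (LAV<sub>ac</sub> − LAV<sub>min</sub>)/LAV<sub>max</sub>;
  the shared denominator makes passive + contractile = total by construction.
* **Diagnostic statistics** — LVEDP dichotomized at 12 mmHg (strictly
  greater = elevated); empirical ROC AUC (Mann–Whitney pair statistic, ties
  ½) with DeLong variance for inference; Youden-optimal cutoffs with
  specificity-leaning tie-breaks; pooled-variance t tests, Pearson
  correlation, Fisher's exact test.
* **Agreement statistics** — Bland–Altman bias and limits of agreement for
  single- vs multi-phase volumes; Lin's concordance correlation coefficient
  for observer replicates.
* **A synthetic-cohort generator** emulating an LVEDP-dichotomized
  catheterization population: group-specific volume/pressure distributions,
  physiologic four-segment time-volume curves sampled at 20–30 cine frames
  (~35 ms resolution), consistent biplane projections, and multiplicative
  planimetry noise per observer.

## Worked example

```r
library(laphase)

cfg <- pipeline_config(cohort = cohort_config(n_patients = 41, seed = 1),
                       seed = 1)
res <- run_pipeline(cfg, out_dir = "study_out")
cat(res$summary)
```

prints (abridged):

```
Patients analyzed: 39 (excluded by QC: 2)
Elevated LVEDP (>12 mmHg): 14; normal: 27

Group comparison (mean +/- SD, elevated vs normal; Student t):
  lav_min              34.8 +/-  19.9  vs   24.2 +/-   7.6   p = 0.019
  lav_max              56.9 +/-  19.0  vs   46.3 +/-  10.9   p = 0.033
  ...
ROC vs elevated LVEDP (single-phase method):
  lav_min            AUC 0.694  p = 0.128  cutoff >= 39.0 mL/m^2  sens 58%  spec 100%
  lav_ac             AUC 0.707  p = 0.087  cutoff >= 50.7 mL/m^2  sens 58%  spec 96%
  ...
Method agreement and observer variability:
  single_vs_multi_lav_max          bias +0.34 +/- 3.59 mL/m^2 (LoA -6.69 to +7.38, n = 37)
  inter_observer_single_phase_lav_min CCC 0.997 (n = 5)
  ...
```

Reading this: of 41 simulated patients, 2 were excluded because measurement
noise produced a physiologically impossible volume ordering (a QC step).
Both LA volumes and emptying fractions separate the elevated-LVEDP group,
volumes discriminating with AUCs near 0.7 at this small cohort size; the
two extraction methods agree to within a fraction of a mL/m² on average;
and replicate observers are highly concordant (CCC ≳ 0.95). Larger cohorts
(`n_patients = 400`) reproduce the qualitative ordering
AUC(LAV<sub>min</sub>) > AUC(LAV<sub>max</sub>) and
AUC(LAEF<sub>Total</sub>) > AUC(LAEF<sub>Passive</sub>) in essentially
every replicate — see `tests/testthat/test-acceptance.R`.

The same chain is scriptable from the shell:

```sh
inst/cli/laphase pipeline --n 41 --prevalence 0.341 --seed 1 --out study_out
inst/cli/laphase simulate --n 100 --seed 7 --out sim/
inst/cli/laphase quantify --method both --curves sim/curves.csv --events sim/cohort.csv --out sim/phasic.csv
inst/cli/laphase evaluate --phasic sim/phasic.csv --cohort sim/cohort.csv --threshold 12 --out sim/
```

Exit codes: 0 success, 2 configuration/validation failure, 1 runtime error.

## Documentation

The methods vignette (`vignettes/laphase-methods.Rmd`) describes the curve
model, the landmark-detection algorithm and its windows, the noise and
correlation structure of the generator, every tunable parameter with its
default and rationale, and known limitations of the synthetic world.
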