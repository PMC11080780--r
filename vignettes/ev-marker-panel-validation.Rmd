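---
title: "Targeted MRM quantification and validation of an EV marker panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted MRM quantification and validation of an EV marker panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evmrm)
```

## The problem and the method

Characterising extracellular-vesicle (EV) isolates requires evidence that
established EV proteins are present and that common co-isolated
contaminants are absent or depleted (the MISEV reporting framework).
Western blotting, the conventional route, is semi-quantitative, low
throughput and hungry for sample. `evmrm` implements the alternative: a
targeted LC-MS/MS assay in multiple-reaction-monitoring (MRM) mode over a
five-protein panel -- the tetraspanins CD81 and CD9 (MISEV category 1) and
the ESCRT protein TSG101 (category 2) as positive markers, serum albumin
(category 3) and the ER protein calnexin (category 4) as contaminant
markers -- together with the complete bioanalytical validation and
reproducibility framework such an assay needs before it can be trusted.

Each protein is represented by one proteotypic tryptic peptide monitored
as three transitions (one quantifier, two qualifiers) in two forms: the
endogenous "light" peptide and a stable-isotope-labelled (SIL) internal
standard spiked at a known concentration (ALB 10, CD81 0.4, CD9 0.1,
CANX and TSG101 0.2 pmol/ml). The central quantity is the *normalized
response*

$$R = \frac{A_\text{light}}{A_\text{SIL}},$$

the light quantifier peak area over the SIL quantifier peak area from the
same injection. Matrix components suppress the ionisation of both forms
by the same factor, so $R$ is invariant to matrix effects; concentration
follows either by single-point scaling, $c = R \cdot c_\text{SIL}$, or by
inverting an external calibration line $R = a + b\,c$ fitted by ordinary
least squares (`fit_calibration()`, an `ev_calibration` object with the
usual `coef`/`predict`/`summary`/`plot` methods).

## Validation rules implemented

* **Sensitivity.** The LOD is the concentration at which the quantifier
  signal-to-noise ratio reaches 3:1; the LLOQ is exactly 5 x LOD. The
  criterion defines a threshold, not an estimator, so the package fits
  S/N against concentration through the origin over the lowest three
  calibrators and sets LOD = 3/slope -- deterministic and testable
  against closed forms.
* **Precision.** %RSD (sample SD over mean, n - 1 denominator
  throughout) of calibration slopes within day (reported per day, pooled
  as the worst day) and of day-mean slopes between days; repeatability as
  the %RSD of five consecutive injections of a mid QC.
* **Accuracy.** Back-calculated QC concentration as a percentage of
  nominal ("% True"), reported to three significant figures.
* **Carryover.** Blank injections after the top calibrator, classified
  against the limits: none (< LOD), detectable (>= LOD, < LLOQ),
  quantifiable (>= LLOQ, boundary inclusive).
* **Stability.** Percent change of duplicate means from baseline; a
  timepoint is stable only when the absolute change is strictly below
  20%. The comparison carries a 1e-9 numerical guard so that a change
  that is exactly 20% up to floating-point round-off (e.g. a simulated
  first-order loss of precisely one fifth) lands on the unstable side,
  as the strict rule demands.
* **Matrix effects.** Recovery as the ratio of SIL response-curve slopes:
  against mobile phase (absolute) or against the primary qEV70 EV matrix
  (relative). When relative recovery deviates from 100% by more than 20
  points, LOD/LLOQ are rescaled by 100/recovery (`adjust_limits_for_matrix()`);
  within the band they are left alone.
* **Reproducibility.** Over a 3-donor x triplicate-isolation x
  duplicate-digest design: an isolation "detects" an analyte when its
  digest-mean response exceeds the LOD; a digest pair is "equivalent"
  when both members fall on the same side of the LOD; percentages pool
  donors (n = 9) and round to integers. Quantification %RSD uses only
  values at or above the LLOQ; a cell in which every value is below the
  LLOQ is marked censored-reproducible rather than given a meaningless
  number. Values below the limits always keep their numeric estimate and
  a censor flag -- flagging, never imputation.

Two aggregation choices were genuinely open. Digest %RSD is aggregated
across pairs as a root mean square (a per-pair RSD of duplicate values is
|d|-based, and the RMS makes the aggregate a consistent estimator of the
underlying digest CV; the arithmetic mean is available via
`digest_aggregate = "mean"`). Isolation percentages pool donors into a
single denominator, matching how a nine-isolation design is naturally
summarised; per-donor splits can be recovered by filtering the dataset.

## The simulator and what it emulates

`sim_params()` defines the generative model used everywhere:

* one Gaussian peak per transition, area $A$, SD `peak_sigma` = 0.05 min,
  sampled at 0.01-min steps over the expected retention time +/- 1.5 min,
  on a flat baseline of 50 counts with iid Gaussian noise (SD 10 counts)
  and retention-time jitter (SD 0.015 min, reproducing the
  few-hundredths-of-a-minute RT scatter of a well-behaved column);
* per-analyte response factors (counts\*min per pmol/ml) calibrated once
  so that the signal-to-noise in qEV70 matrix reproduces the panel's
  validated detection limits (e.g. CD9 LOD near 0.005 pmol/ml);
* per-matrix ionisation-suppression factors equal to the assay's absolute
  SIL recoveries (e.g. CD81 retains only 13% of its mobile-phase response
  in ExoQuick matrix), applied identically to light and SIL forms --
  which is exactly why SIL normalization works, and the package asserts
  that invariance;
* multiplicative lognormal variability with CVs of 0.30 (donor), 0.20
  (isolation), 0.05 (digest) and 0.02 (injection), chosen so that
  replicate-study %RSDs span the single-digit-to-30% range a practitioner
  sees; injection noise is drawn independently for light and SIL
  transitions;
* geometric carryover (blank k carries `carryover_fraction^k` of the
  previous area) with default 2e-4, which puts the albumin blank-1
  response at 4 x LOD after the 80 pmol/ml top calibrator -- the
  borderline scenario the carryover classifier must resolve. A geometric
  decay cannot simultaneously place blank 2 at 1 x LOD, so only the
  first-blank behaviour is anchored;
* first-order degradation per analyte, form and temperature; because the
  SIL standard is spiked once at baseline, a faster SIL decay inflates
  apparent concentration (a 26% overestimate at 24 h is reproduced by a
  SIL rate of ln(1.26)/24 per hour).

Method-level truth concentrations for the replicate study default to the
values observed in the validated assay (ExoQuick albumin at ~28,000
pmol/ml versus 34 in qEV70, TSG101 below the LLOQ in both SEC matrices),
so the default simulated study reproduces the qualitative structure of a
real serum-EV comparison: high-recovery/low-purity precipitation versus
cleaner but lower-yield size exclusion.

The simulator does *not* model co-eluting interference peaks, isotope
patterns, charge states, detector saturation, or retention-time drift
within a run; matrix effects enter only through the scalar suppression
factor. Passing tests therefore demonstrate that the statistical
machinery is correct under the stated noise model, not that the assay
will behave on any particular instrument.

## Numerical choices

* Peak apex: maximum of a 5-point moving average inside the +/- 0.5 min
  search window; earliest time wins ties. Peak width: half-width at
  60.65% (the 1-sigma level) of the baseline-subtracted apex;
  integration over apex +/- 4 sigma (99.99% of a Gaussian), clipped to
  the window, trapezoid rule, floored at zero.
* Noise: 1.4826 x MAD of residuals from a linear baseline fitted over the
  first and last 15% of the window -- the median resists peak leakage
  into the flanks. Window-membership comparisons carry a 1e-9 epsilon so
  that results are invariant to a uniform time shift of the grid.
* Identity confirmation: light-versus-SIL quantifier RT delta within
  +/- 0.3 min and qualifier/quantifier ratios within +/- 30% relative of
  the SIL reference (common bioanalytical defaults; both exposed as
  arguments). A light qualifier missing while the light quantifier S/N
  is at least 45 (three times the LLOQ-equivalent S/N of 15) vetoes
  confirmation; at weaker signal a missing qualifier is expected and
  ignored. Identity failure flags the result but never zeroes it.
* Calibration: unweighted OLS with fitted intercept (1/x weighting behind
  a flag); censoring bins are half-open with the LLOQ and ULOQ inclusive
  on the quantifiable side, and the ULOQ is the top calibrator of the
  validated range.
* Lognormal CV parameterisation: `meanlog = -log(1 + cv^2)/2`,
  `sdlog = sqrt(log(1 + cv^2))`, giving mean exactly 1 at any CV.
* Reported folds: three significant figures at or above 10-fold, two
  below (so 27984/34 prints 823 and 122/34 prints 3.6).

## Problem sizes used in the checks

The packaged tests run the full signal path (trace simulation, peak
detection, S/N estimation) on single injections, and use the
pre-integrated results-table route -- an explicitly supported input
format -- for the Monte-Carlo suites: 200-seed recovery and linearity
experiments, 500-seed CV-recovery and unbiasedness experiments, all on
desk-scale designs (one analyte, 3-9 levels, 9-18 injections). These
sizes give sub-percent Monte-Carlo error on the recovered parameters
while keeping the whole suite around a minute on one core.

## Known limitations

* Real chromatograms with overlapping peaks need external deconvolution;
  the integrator assumes one dominant peak per search window.
* The LOD estimator assumes S/N is linear through the origin at the low
  calibrators; saturating detectors violate this.
* Percent-of-serum depletion figures require the analyte concentration in
  neat serum, which the package accepts as user input
  (`serum_conc` in `render_misev_report()`) and never assumes.
* The published CD81 LLOQ (0.230 for LOD 0.050) and TSG101 LLOQ (0.031
  for LOD 0.006) are rounded inconsistently with the exact 5 x rule; the
  package enforces the rule exactly, so those two printed LLOQs differ
  from `estimate_lod_lloq()` output in the third decimal.
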