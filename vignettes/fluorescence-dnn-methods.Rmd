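---
title: "Methods: dense-network classification of multispectral skin fluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dense-network classification of multispectral skin fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Basal cell carcinoma (BCC) and surrounding normal skin differ in their
endogenous fluorophore content: collagen cross-links, the metabolic
cofactors NADH and FAD, and porphyrins all fluoresce when excited by
lasers in the near-UV/visible range, and BCC tissue shows reduced
collagen-, NADH- and FAD-band intensities relative to intact skin. A
multispectral measurement — here, 88 emission channels recorded under each
of 4 excitation wavelengths — therefore carries a molecular signature that
a classifier can exploit without any feature engineering.

`fluordx` implements that analysis end to end: a synthetic cohort
generator with the statistical structure described above, a dense
feed-forward network trained from scratch, a case-level repeated
random-split evaluation protocol, and diagnostic summaries (sensitivity,
specificity, ROC/AUC) aggregated as order statistics over repeated runs.

## Data model

A cohort is a plain tibble with one row per (case, replicate, excitation)
and one `em_<nm>` column per emission channel; the emission grid lives in
the column names, so a CSV file is self-describing. A *case* is one
patient-and-site entity contributing several replicate spectra; it is the
unit of data splitting and of the majority-vote decision, which is what
prevents information leakage between training and evaluation.

Each spectrum is flattened excitation-major (channel block of the first
excitation, then the second, ...) into a feature vector of length
`n_excitations * n_channels` — 352 under the default 4 x 88 geometry. The
flattening order is arbitrary in principle; it is fixed so that trained
models are reproducible, and `unflatten_spectrum()` inverts it exactly.

## The synthetic generator

No patient spectra are publicly deposited, so the generator is the
package's source of test data. It emulates the features the analysis
relies on, with one Gaussian emission band per fluorophore:

| fluorophore | ex peak/width (nm) | em centre/width (nm) | amplitude (a.u.) | cancer multiplier |
|---|---|---|---|---|
| collagen  | 340 / 30 | 390 / 40 | 1.0 | 0.6 |
| NADH      | 360 / 30 | 460 / 50 | 0.9 | 0.7 |
| FAD       | 450 / 30 | 525 / 45 | 0.8 | 0.7 |
| porphyrin | 405 / 25 | 635 / 25 | 0.4 | 1.3 |

The clean spectrum under excitation $x$ is

$$ s(\lambda) = b + \sum_f A_f\, m_f(\text{label})\, g_f\,
   e^{-(x - \mu^{ex}_f)^2 / 2\sigma^{ex\,2}_f}
   e^{-(\lambda - \mu^{em}_f)^2 / 2\sigma^{em\,2}_f} $$

with baseline $b = 0.05$ a.u., $m_f = 1$ for normal tissue and the cancer
multiplier otherwise, and $g_f$ a per-case log-normal factor
(`case_effect_sd = 0.3` on the log scale) shared by all of a case's
replicates — this is what makes replicates of one case correlated and the
case, not the spectrum, the exchangeable unit. Replicate noise is additive
Gaussian with sd equal to `noise_sd = 0.1` times the case's maximum clean
intensity, and intensities are clamped at zero. Band positions and widths
are literature-flavoured values for skin autofluorescence; the direction
of the collagen/NADH/FAD reduction in cancer follows what has been
reported for BCC, and every value is configurable.

The defaults deliberately produce overlapping classes, so that the
classifier's error rates are non-trivial. What the generator does **not**
emulate: absorption and scattering (no radiative transfer), melanin and
pigmented-lesion classes, instrument artefacts (dark current, wavelength
calibration error), and any non-Gaussian band shape. Tests passing on
synthetic cohorts therefore establish that the pipeline is correct and
well calibrated, not that the published clinical error rates are
reproduced — those depend on the real spectra, which are unavailable.

Two cohort geometries are built in. The default gives every case 5
replicates (the measurement protocol prescribes five spots per site). The
`"published"` preset reproduces the published accounting instead: 137
cancer + 149 normal cases and 804 total spectra (486 cancer, 318 normal,
about 2.8 per case), allocated round-robin with the remainder on the first
cases so the totals are exact and deterministic. The two conventions are
mutually inconsistent in the source material; both are exposed rather than
reconciled.

## The network

`network_spec()` defaults to the diagnostic device's stack:

    dense(64, relu) -> dense(64, sigmoid) -> dropout(0.4)
    -> dense(128, tanh) -> dropout(0.5) -> dense(2, softmax)

giving 35,330 trainable parameters at input dimension 352. Two softmax
outputs (rather than one sigmoid) are kept: the loss is categorical
cross-entropy and the second output is read as the cancer probability.
Forward and backward passes are explicit matrix code:

* **Initialisation** — Glorot-uniform weights, zero biases, seeded. The
  source material does not state an initialiser; Glorot is the standard
  choice for mixed sigmoid/tanh stacks.
* **Dropout** — inverted scaling (`1/(1-r)` at train time), identity at
  evaluation; masks are cached so the backward pass replays them exactly.
* **Loss** — probabilities clipped to `[1e-7, 1 - 1e-7]` before the log.
* **Optimiser** — SGD with momentum 0.9, Nesterov acceleration, and the
  legacy inverse-time schedule `lr_t = lr0 / (1 + decay * t)` with `t`
  counting individual updates. The printed decay constant (1e-6) matches
  this convention; the alternative reading as a step-decay schedule is not
  implemented.
* **Early stopping / checkpointing** — monitor loss evaluated each epoch
  on the held-out monitor set; strict decrease counts as improvement
  (min_delta 0); training stops after `patience` epochs without
  improvement and the checkpointed (best-loss) parameters are returned.
  The experiment description names both "best by loss" and "best by
  accuracy on the test set" as the checkpoint criterion, which cannot both
  hold; loss is the default and accuracy is selectable via
  `train_config(checkpoint = "accuracy")`.
* The final partial mini-batch of each epoch is used; an epoch is one full
  pass over the shuffled training set.

Gradient correctness is enforced by test: central finite differences on
random 5-sample batches, every layer, with dropout masks replayed,
relative error below 1e-5.

### Training profiles

The published regimen (`train_config("published")`) is learning rate 1e-6,
decay 1e-6, batch 32, up to 15,000 epochs with patience 5,000. At 352
input features and ~640 training spectra this is minutes per run and
hours for 50 runs, so the package also defines `train_config("fast")`
(learning rate 1e-3, 300 epochs, patience 50, same optimiser and batch
size), which converges on the synthetic cohorts in a few seconds per run.
All simulation studies in the tests and the acceptance script use the
fast profile; the published profile remains available for users who want the
printed schedule.

## The evaluation protocol

Each experiment draws a uniformly random case-level partition — 229
training, 29 test, 28 validation cases by default — trains on the training
spectra with the test spectra as the early-stopping monitor, and evaluates
the checkpointed model on the validation cases only. Fifty independent
experiments are run, each from a seed derived deterministically from one
master seed (`master + 104729 * run`, reduced modulo 2^31 - 1), so the
whole study is reproducible from a single integer.

Splits are unstratified, as in the source protocol ("randomly"); a
stratified option exists but is off by default. A drawn partition that
leaves a part of size ≥ 2 with only one class is re-drawn (bounded
retries), because a single-class training set cannot be fitted and a
single-class validation set has no defined sensitivity/specificity pair;
singleton parts are exempt from this rule so that degenerate
one-case-per-part splits remain legal. With the default 286-case geometry
a redraw essentially never triggers.

A separately published fixed 692/112 train/validation spectra split does
not map onto the 229/29/28 case protocol; the package implements the case
protocol and notes the discrepancy here.

## Decision rules and metrics

* **Spectrum rule** — cancer iff the cancer-probability output is
  **greater than or equal to** 0.5; the boundary is inclusive.
* **Case rule** — strict majority: a case is counted correct iff strictly
  more than N/2 of its N spectra receive the true label, so an even split
  is incorrect. The case-level predicted label is the true label when
  correct and the opposite class otherwise, which is exactly the
  information the majority statement carries for a binary problem.
* **Rates** — sensitivity TP/(TP+FN), specificity TN/(TN+FP) with cancer
  positive, computed at case level (primary) and spectrum level
  (reported alongside, clearly labelled — the source does not state the
  unit). Zero denominators yield `NA` with a warning, never a silent 0.
* **ROC/AUC** — computed at spectrum level over the validation
  probabilities; one point per distinct threshold, trapezoidal area. The
  trapezoid equals the Mann–Whitney pair-counting estimator (ties one
  half), which the tests verify exhaustively on small instances and
  cross-check against pROC.
* **Summary** — per metric over runs: N, min, max, mean, median, sample
  sd (n−1), and 25th/75th percentiles with linear interpolation
  (`quantile type 7`); the rendering follows the published column order.

## Numerical and design choices

* Double precision throughout; no numerical libraries beyond base BLAS.
* CSV round trips are bit-exact: doubles are written with 17 significant
  digits and parsed with `strtod`.
* Softmax is computed with the row-max subtracted for stability.
* Ties in `max.col` accuracy are broken to the first class
  (deterministic).
* Non-finite training or monitor loss aborts with a diagnostic rather
  than continuing silently.
* The emission channel count is configurable: the source prints both
  "88 x 4" input data and an "Input (288 x 4)" layer line; the 88-channel
  reading is used (the 288 appears to be a typo) and nothing hard-codes
  it.
* Case counts follow the 286-case accounting (137 + 149) rather than the
  separately reported 287 healthy volunteers; the inconsistency is noted,
  not resolved.

## Simulation sizes used by the tests and the acceptance run

Unit tests run on a reduced geometry (2 excitations x 12 channels, 8–24
cases) chosen so the full suite completes in minutes. The end-to-end
checks use full-size published-geometry cohorts: a strong-effect cohort (all
cancer multipliers 0.3, `noise_sd = 0.05`) over 5 fast-profile runs, on
which mean case-level sensitivity and specificity are required to reach
0.90, and a null cohort (all multipliers 1) over 10 runs, on which the
mean spectrum-level AUC must stay within [0.4, 0.6]. The acceptance
script runs the full 50-experiment protocol on the default published-geometry
cohort with the fast profile.

## Known limitations

* The synthetic generator is a band model, not a tissue-optics model;
  absolute error rates on synthetic cohorts say nothing quantitative
  about clinical performance.
* The published-regimen profile is faithful but slow; no GPU or compiled path is
  provided (the field's argument for a dense architecture at this input
  size also removes the need for one).
* Binary labels only; the four-class extension mentioned in the source
  abstract has no corresponding method description and is out of scope.
* No confidence intervals for AUC and no calibration analysis.
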