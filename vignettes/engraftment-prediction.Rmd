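---
title: "Predicting AML xenograft engraftment from a one-week CFSE assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting AML xenograft engraftment from a one-week CFSE assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engraftr)
```

## The problem

Xenotransplantation into immunodeficient (NSG) mice is the reference assay
for the leukemia-initiating-cell activity of an acute myeloid leukemia (AML)
sample, but it takes twelve weeks and many animals, and a substantial
fraction of samples fail to engraft. engraftr implements a desk-scale
alternative: a one-week ex vivo co-culture readout that predicts engraftment
from two flow-cytometry quantities, wrapped in a reproducible pipeline with
a synthetic-data generator so that every stage can be validated without
patient material.

The two predictors are:

* **Day-7 viability** — the percentage of Annexin-V- and DAPI-negative
  events within the gated human hematopoietic population, on the 0-100
  percent scale.
* **FDF (fluorescence dilution factor)** — the ratio of the 18-hour CFSE
  median fluorescence intensity (MFI) to the day-7 CFSE MFI on the same
  gated population. CFSE halves at each division, so FDF = 2^k corresponds
  to a median of k divisions. AML samples are too heterogeneous for
  individual division peaks to resolve (large blasts stain brighter than
  small ones, so peaks overlap heavily); the MFI ratio deliberately avoids
  peak deconvolution and is the only contractual dilution statistic in this
  package.

## Gating model

Events pass through a fixed four-stage sequence, one intensity cut per
channel (`gating_config()`):

1. **Feeder exclusion** — drop events with feeder-marker intensity strictly
   above the cut (Sca-1, CD56 or CD31 depending on the feeder line; the
   channel is generically named `feeder_marker`).
2. **Human hematopoietic selection** — keep events with CD45 strictly above
   the positive cut.
3. **Lymphocyte exclusion** — drop residual normal lymphocytes, defined as
   CD45 strictly above a high cut *and* SSC strictly below a low cut.
4. **Viability** — viable events have Annexin-V *and* DAPI at or below
   their cuts (the boundary counts as negative, i.e. viable).

Tie handling at thresholds (strict for exclusions and the positive gate,
non-strict for the viability gate) is a package convention chosen for
determinism; marker-positive/negative logic does not dictate boundary
behaviour. Likewise the placement of lymphocyte exclusion *before* the
viability gate is a convention: the viability denominator is the
lymphocyte-excluded hematopoietic population, so viability means "viable
share of the cells whose MFI we measure". Both MFIs (18 h and day 7) are
taken on the viable stage, with the same configuration at both timepoints.

Thresholds live entirely in `gating_config()`; there is no automated gate
learning, no compensation and no spillover correction. Default cuts are in
arbitrary units matched to the synthetic generator's channel scales; real
data require instrument-specific cuts.

## The classifier

Engraftment status is modelled by a three-term logistic regression:

$$\theta = \mathrm{logit}^{-1}\!\big(\beta_0 + \beta_v \, v + \beta_{vf} \, v \cdot \mathrm{FDF}\big),$$

with $v$ the day-7 viability in percent. The shipped reference model
(`default_coefficients()`) has $\beta_{vf} = 3.96\times10^{-2}$ per
(percent × FDF unit), $\beta_v = -7.09\times10^{-2}$ per percent, and
$\beta_0 = -7.09\times10^{-2}$. Viability must enter on the percent scale:
with these magnitudes only 0-100 inputs produce $\theta$ values that cross
both decision thresholds over realistic assays. An FDF main effect is
deliberately absent — the model's structure is intercept + viability +
viability×FDF, nothing else — and `fit_engraftment_model()` refits exactly
those three terms by Newton scoring (relative log-likelihood tolerance
1e-10, at most 100 iterations, observed-information standard errors).
Complete separation raises an explicit error rather than returning runaway
coefficients.

The decision rule has a reject option (`default_thresholds()`):

* $\theta > 0.6363636$: predicted **engrafter**;
* $\theta < 0.3535354$: predicted **nonengrafter**;
* otherwise **no prediction** — both boundaries abstain (the abstention
  interval is closed).

Both thresholds are exact multiples of 1/99 (63/99 and 35/99), so the
default calibration grid (`threshold_grid()`) enumerates multiples of 1/99.
`fdr_sweep()` computes, for every candidate pair, the empirical false
discovery rate — false predictions over predictions made, with 0/0 defined
as 0 — and the abstention fraction; `calibrate_thresholds()` picks the pair
meeting an FDR target (default 5%) with minimal abstention, breaking ties
toward the narrower abstention interval and then the lower `t_low`, and
falls back (flagged) to the minimal-FDR pair when the target is
unattainable.

## Limiting-dilution analysis

The long-term culture assay plates cells at several doses, 20 replicate
wells per dose, and scores each well negative when no colonies appear.
Under the single-hit Poisson model a well with dose $d$ is negative with
probability $e^{-f d}$, where $f$ is the frequency of leukemic long-term
culture-initiating cells (L-LTC-IC). `fit_limiting_dilution()` maximizes
the binomial log-likelihood over $\log f$ (golden-section search polished
with Newton steps; positivity and conditioning across decades of frequency
motivate the log scale) and inverts the likelihood ratio for a 95%
confidence interval (profile bounds where the log-likelihood drops by
$\chi^2_{1,0.95}/2 = 1.9207$). Likelihood-ratio intervals were chosen over
Wald/Fisher-information intervals because they remain usable at extreme
negative fractions. Degenerate outcomes are flagged rather than fitted:
all-negative gives a boundary estimate of 0 with an exact upper bound, and
all-positive has no finite MLE. A single-dose experiment reproduces the
closed form $f = -\ln(\mathrm{neg}/\mathrm{wells})/d$ exactly, and the
multi-dose optimizer is tested against a dense grid-search oracle.
Multi-hit and heterogeneity models are out of scope.

## Survival stratification

`km_estimate()` implements the product-limit estimator over distinct
observed times; at a time carrying both events and censorings the events
are processed first (the standard convention — censored subjects remain in
the risk set for that time's events). `twogroup_test()` implements the
weighted log-rank family from the defining formulas: at each distinct event
time it accumulates $w\,(O_1 - E_1)$ and $w^2 V$ with the hypergeometric
variance $V$, and refers $(\sum w (O_1-E_1))^2 / \sum w^2 V$ to
$\chi^2_1$. Weight $w = 1$ gives the Mantel-Cox log-rank; $w$ = total at
risk gives the Gehan-Wilcoxon variant, the Wilcoxon-family test this
package uses for censored two-group comparisons. Cox regression and
multi-group trend tests are not provided.

## What the synthetic generator emulates

`simulate_flow_sample()` builds two event tables per sample (18 h, day 7)
as a mixture of hematopoietic blasts, feeder cells and residual
lymphocytes, with log-normal channel intensities separated so that the
default gates act as designed. Its key mechanism is the division model: at
day 7 each blast's CFSE value is a fresh log-normal draw divided by $2^k$,
with $k$ a *rounded normal* around $\log_2(\mathrm{FDF_{target}})$ (spread
`division_log2_sd`, default 0.7 divisions). The rounded normal is left
untruncated: symmetry around the target keeps the gated median ratio
unbiased even at a target of 1 (no division), where truncating at zero
would push the median up; the occasional negative $k$ stands in for
measurement-scale variability rather than genuine intensity gain. Only the
median ratio is contractual — the per-division peak structure is
intentionally unresolvable, as in real AML data. Apoptosis (Annexin-V
and/or DAPI positivity) is applied to day-7 hematopoietic events at rate
(100 − target viability)%; 18-hour acquisitions are generated fully viable
because the predictor uses day-7 viability only.

`simulate_cohort()` draws viability and FDF from uniform marginals
(defaults U(20, 100) and U(1, 6)) and engraftment as Bernoulli with the
logistic probability — uniform marginals maximize identifiability for
coefficient recovery; the true covariate distribution of AML cohorts is not
modelled. `simulate_survival()` uses exponential times with administrative
censoring (defaults: median overall survival 24 months for engrafters, 60
for nonengrafters, 60-month horizon — engrafting samples come from
patients with worse outcomes, and the defaults are field-realistic
conventions, not calibrated to any published cohort).

What the generator does **not** emulate: instrument artifacts (spectral
spillover, compensation, autofluorescence drift), doublets, debris,
non-exponential survival, informative censoring, or correlated
viability/FDF marginals. Passing round-trip tests therefore demonstrates
that the pipeline's arithmetic is correct under its stated model, not that
the model captures every feature of real cytometry data.

## Numerical and design choices

* $\theta$ is computed via a numerically stable logistic; linear predictors
  of any magnitude are safe.
* FDF below 1 is reported with `low_fdf_flag`, never clamped: the ratio's
  lower bound is a biological expectation, not an algorithmic constraint,
  and noisy medians may violate it.
* MFI uses the standard sample median (mean of central order statistics at
  even counts).
* The LDA optimizer targets relative precision 1e-12 on $f$; tests require
  agreement with a $10^6$-point grid oracle to 4 significant figures.
* An empty viable gate with a nonempty hematopoietic gate is 0% viability,
  not an error; an empty hematopoietic gate is flagged and makes MFI and
  viability undefined.
* Pipeline runs are deterministic: per-sample seeds derive from the master
  seed, logs omit timestamps, and identical configurations yield
  byte-identical result files.

## Problem sizes used in validation

The test-suite experiments are sized for desk-scale runs: coefficient
recovery refits cohorts of 2000 samples; FDF recovery uses 20,000 events
per timepoint at targets 1, 2, 4 and 8; limiting-dilution coverage fits
1000 simulated designs of 3 doses × 20 wells at a true frequency of 1/1000;
log-rank size is checked over 1000 null simulations of 200 subjects. These
sizes give sampling errors comfortably inside the asserted tolerances (for
example, the median sampling error of a 20,000-event FDF is well under 1%,
against a 5% recovery band).

## Known limitations

* Gating is fixed-threshold only; real instruments need per-panel cuts and
  possibly density-based gates.
* The shipped coefficients and thresholds are a reference model; refitting
  on local cohorts is expected, and `calibrate_thresholds()` exists for
  exactly that purpose.
* The LDA estimator assumes the single-hit model; departures (cooperative
  effects, heterogeneous frequencies) bias the frequency estimate.
* Survival utilities cover two-group comparison only.
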