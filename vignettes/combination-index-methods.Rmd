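---
title: "Quantifying drug-combination synergy with the median-effect method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drug-combination synergy with the median-effect method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergyci)
```

## The model

A cytotoxicity dose-response is summarized by the median-effect equation

$$\frac{f_a}{f_u} = \left(\frac{D}{D_m}\right)^m,$$

where $f_a$ is the fraction of cells affected at dose $D$, $f_u = 1 - f_a$,
$D_m$ is the median-effect dose (the dose giving 50% effect, i.e. the model
IC50) and $m$ controls the sigmoidicity of the curve ($m = 1$ hyperbolic,
$m > 1$ sigmoidal). Taking logs gives a straight line,

$$\log_{10}\frac{f_a}{f_u} = m \log_{10} D - m \log_{10} D_m,$$

which `fit_median_effect()` fits by ordinary least squares. The reported
linearity $r$ is the Pearson correlation of the linearized points. The base
of the logarithm cancels between slope and intercept, so $m$ and $D_m$ do
not depend on it, and multiplying all doses by a constant multiplies $D_m$
by that constant while leaving $m$ and $r$ unchanged (both properties are
tested).

Fraction affected comes from plate-reader data through the viability chain:
relative viability (%) is the mean treated absorbance over the mean
untreated-control absorbance times 100, and $f_a = 1 - \text{viability}/100$.

### Synergy quantification

For a combination whose components are kept at a fixed dose ratio
$w_1 : \dots : w_k$ (weights summing to 1, conventionally the ratio of the
single-agent IC50s so that each drug contributes comparably), the mixture is
treated as a composite single agent and fitted on total dose. At an effect
level $f_a$, the mixture needs total dose $D_{tot}(f_a)$ and each component
contributes $D_i = w_i D_{tot}$. The combination index is

$$\mathrm{CI}(f_a) = \sum_{i=1}^{k} \frac{D_i}{D_{x,i}(f_a)},$$

with $D_{x,i}$ the dose of drug $i$ alone producing the same effect — the
mutually-exclusive form, without a cross-product term. CI < 1 indicates
synergism, CI = 1 additivity (the Loewe-consistency reference: a drug
"combined" with itself always yields CI = 1), CI > 1 antagonism. The
dose-reduction index of drug $i$ is $\mathrm{DRI}_i = D_{x,i}/D_i$, the fold
reduction achievable at equal effect, and the two are algebraically linked:

$$\mathrm{CI} = \sum_i \frac{1}{\mathrm{DRI}_i}.$$

Every CI row the package reports is audited against this identity (to
1e-9) before it is written; `ci_from_dri()` exposes the identity directly.
This reciprocal form is also how published CI/DRI tables can be checked for
internal consistency — rows that fail it (transcription or rounding
artifacts) should not be used to validate an implementation.

## Parameters that matter

- **Exclusion rule** (`fit_median_effect`): points with $f_a \le 0$ or
  $\ge 1$ — which arise when absorbance noise pushes viability above 100% —
  carry infinite log-odds and are excluded with a warning. `clamp = TRUE`
  instead shrinks them to $[\varepsilon, 1-\varepsilon]$,
  $\varepsilon = 10^{-4}$, which trades bias for retention when few doses
  are available. Excluded counts are logged by the report runner.
- **Effect levels** (`fa_levels`): reporting defaults to 0.50/0.75/0.90
  (IC50/IC75/IC90), the levels at which combination tables are customarily
  printed; any grid inside (0, 1) is accepted.
- **Rounding**: report CSVs round CI to 3 decimals and DRI to 2, matching
  table conventions; returned objects keep full precision.
- **Classification band** (`classify_ci`): strict thresholding at 1 by
  default; an optional symmetric band treats near-1 values as additive.

## What the synthetic generator emulates

The generators stand in for raw plate and cytometry files so that every
stage of the pipeline is testable end to end:

- `simulate_plate()` — an MTT titration: control wells at OD 1.0, treated
  wells at OD $(1 - f_a(D))$, both under multiplicative log-normal noise
  (plate-reader noise scales with signal), default $\sigma = 0.02$,
  triplicate wells. The default dose grid (`dose_grid()`) places 8
  log-spaced doses spanning $D_m/4$ to $4 D_m$. This span keeps simulated
  effects within roughly 6–94% (at $m = 2$), the window a titration is
  designed to cover: the linearized estimator weights each point by its
  log-odds, so wells driven to ~1% or ~99% effect contribute noise-dominated
  leverage points and degrade $D_m$ recovery sharply.
- `simulate_combination()` — the generative inverse of the CI definition:
  at each target effect level the total dose is set to
  $D_{tot}(f_a) = \mathrm{CI}_{true}(f_a) / \sum_i (w_i / D_{x,i}(f_a))$,
  so the constructed mixture has exactly the requested CI profile.
- `simulate_flow_events()` — four bivariate log-normal clusters (viable,
  early apoptotic, late apoptotic, necrotic) on the Annexin-V/PI plane with
  multinomial sizes; `simulate_dna_content()` — 2N and 4N Gaussian peaks
  with a uniform S-phase plateau between their 3-sigma edges.
- `simulate_growth()` — exponential counts $n_0 2^{t/t_d}$ under
  multiplicative noise.

Every generator is a deterministic function of its `seed` and restores the
caller's RNG state.

What the generators deliberately do **not** emulate: plate-layout spatial
effects (edge evaporation), absorbance saturation, deviations from the
median-effect law (e.g. biphasic responses), spectral spillover between
cytometry channels, debris continua, or lag/plateau phases of growth beyond
a simple lag trim. Passing recovery tests therefore demonstrates
correctness of the estimators under the model's own assumptions, not
robustness to every artifact of real data.

## Numerical choices and degenerate inputs

- **Noiseless invertibility and slopes.** A constant-ratio mixture of drugs
  sharing the same slope $m$ is itself exactly median-effect (the
  $\left(f_a/f_u\right)^{1/m}$ factor is common to all $D_{x,i}$), so
  noiseless constructed combinations are recovered to 1e-6 through the
  composite fit. With unequal slopes the composite curve deviates from the
  law and the fitted route carries a small model error; exactness tests
  therefore use equal-slope truths, and the pre-fit identity is verified
  pointwise for unequal slopes.
- **Varying interaction profiles.** When the true CI changes with $f_a$, a
  single fitted line cannot represent the mixture (systematic error ~0.06
  for a profile rising 0.3 to 0.6, even without noise). For that situation
  `ci_at_observations()` evaluates CI directly at each observed
  (total dose, $f_a$) pair, with no interpolation; the fitted Fa-CI curve
  remains the default for constant-ratio reporting at standard levels.
- **Ties and gates.** Quadrant gating calls an intensity positive only when
  strictly greater than its threshold, so an event exactly on a gate is
  negative — a documented, tested tie rule. Scatter (singlet) gating is
  accepted as a logical column, not recomputed geometrically.
  `suggest_gate_threshold()` proposes a gate at the KDE valley between the
  two dominant modes of a control sample on the log scale.
- **Cell-cycle windows** are user-supplied inclusive intensity intervals;
  events between the windows are S phase, events outside both tails are
  debris/doublets, excluded from the phase denominators and reported
  separately. Overlapping or reversed windows are configuration errors.
- **Doubling time** is $\ln 2 / k$ from the OLS slope $k$ of
  $\ln(\text{count})$ on time. The window defaults to all points since
  published growth curves rarely state their fitting range; an optional
  lag-phase trim drops leading points below a fold-change threshold. A
  non-positive slope is reported as a no-growth error rather than a
  negative doubling time.
- **Degenerate fits.** Fewer than 2 usable points, identical doses, or a
  slope of 0 within machine tolerance each raise a distinct error rather
  than returning unusable estimates.

## Problem sizes

The test and acceptance workloads use the scales the methods are designed
for: 8-dose x 3-replicate plates, 10,000-event cytometry samples, 5-9-point
growth curves, and fa grids of up to 19 levels. All suites run in seconds.

## Known limitations

- Only constant-ratio combination designs are analyzed; non-constant-ratio
  checkerboards are rejected explicitly rather than approximated.
- No confidence intervals on $m$, $D_m$ or CI; $r$ is the only fit
  diagnostic, matching the classical reporting convention.
- Alternative synergy frameworks (Bliss independence, HSA, ZIP,
  response-surface models) and Hill variants with non-unit asymptotes are
  out of scope.
- Cell-cycle quantification is window-based; no Dean-Jett-Fox or Watson
  model deconvolution of the S-phase overlap.
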