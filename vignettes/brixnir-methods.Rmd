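---
title: "brixnir: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{brixnir: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What this package computes

`brixnir` implements an end-to-end calibration pipeline for predicting the
soluble solids content (SSC, °Brix) of tomatoes from online full-transmission
Vis-NIR spectra (560–1072 nm, 2047 channels), together with a forward
simulator used to validate every stage:

1. **Multi-point aggregation** (`aggregate_scan`). A fruit moving past the
   detector yields 17–31 spectra of very unequal quality. Incomplete end
   points are trimmed, saturated points dropped, and the rest combined by a
   signal-to-noise-weighted average.
2. **Pretreatment** (`apply_pretreatment`): RAW (none), 13-point
   Savitzky–Golay smoothing, or the standard normal variate transform.
   These are alternatives, never chained.
3. **PLSR** (`fit_plsr`): single-response NIPALS partial least squares, with
   the latent-variable count chosen by 5-fold cross-validation
   (`select_lvs_cv`, minimum RMSECV).
4. **Wavelength selection** (`select_wavelengths`): a least angle regression
   path with the lasso modification, under an L1 penalty (sparse selection
   at a penalty `lambda`) or an L2 penalty (ridge-augmented path, see below).
5. **Study design** (`run_repeats`, `run_grid`): 7:3 random
   calibration/prediction splits repeated 100 times, evaluated with
   `R = 1 - SS_res/SS_tot` and `RMSE`, reported as an orientation ×
   pretreatment × model grid of means and SDs.

## Model details and numerical choices

**SNR and point weights.** The source description of the weighting is
contradictory as worded ("an inverse relationship where the weight factor
increases with a higher quality assessment metric"); we implement the only
self-consistent reading: weights are *proportional* to SNR, so high-quality
points dominate. SNR itself is never defined there; we use
`mean(max(point − background, 0)) / max(background_noise_sd, 1e-12)`, a
linear-scale, background-anchored quantity (only the ordering matters for
proportional weights). Weights are normalized to sum to one; if every
retained SNR is zero the weights fall back to uniform with a warning.

**Trimming.** Only the maximal leading and trailing runs whose total
intensity falls below `rel_threshold` (default 0.5) times the median point
total are removed; interior points never are. Saturation flagging uses a
strict threshold: a point is dropped when *more than* `max_frac` (default
0.01) of its channels sit at the detector cap.

**Savitzky–Golay.** The polynomial order is unstated in the source; we use
the standard chemometric default, degree 2. Edge channels are fit on the
truncated one-sided window and the polynomial evaluated at the edge channel,
which keeps reproduction of degree-≤2 polynomials exact everywhere — a
testable contract, unlike padding. SNV uses the sample (n−1) SD.

**NIPALS.** X and y are centered; columns are not variance-scaled (spectral
channels share units). Deflation of both X and y; for single-response data
this is equivalent to SIMPLS. The regression vector is
`b = W (PᵀW)⁻¹ q`, and one fit yields the whole 1..A coefficient path, which
makes LV cross-validation a 5-fit operation. Ties in RMSECV (within
numerical dust, `1e-10` relative) break toward the smaller LV count.

**Goodness-of-fit modes.** The study's Eq. 1 computes `1 − SS_res/SS_tot`
but is *named* a correlation coefficient; whether a square root was taken is
indeterminate. `compute_metrics` offers both (`mode = "paper"`, the printed
form, is the default; `mode = "sqrt"` its clipped square root). Any
comparison against study-style numbers must state the mode.

**LARS penalty scale.** The path is parameterized for the objective
`(1/(2n))‖y − Xb‖² + λ‖b‖₁` on centered, unit-SD columns, so λ is
scale-free; knot penalties are `max|Xᵀ(residual)|/n`. The source never
defines its λ scale, so numeric λ agreement with its tables is not claimed.
Solutions between knots are exact linear interpolations (lasso paths are
piecewise linear in λ); every reported solution satisfies the KKT
stationarity conditions to ~1e-8. Simultaneous entries break ties toward
the lowest column index. When the active set reaches the design rank the
path ends quietly with `saturated = TRUE` — the recorded knots are exact.

**LARS-L2.** Ridge regression never zeroes a coefficient, yet the emulated
study reports finite variable counts for "LARS-L2". We resolve this with an
elastic-net-style interpretation: run the lasso-modified LARS path on the
ridge-augmented design `[X; √(nλ) I]`, `[y; 0]` (whose λ=0 endpoint is
exactly ridge with penalty λ — a tested contract), and stop at the path knot
whose active-set PLSR refit minimizes 5-fold RMSECV. This is a documented
interpretation, not the source authors' verified procedure. The augmented
path is computed implicitly (the identity block only adds `nλ` to the active
Gram), and is capped at `2n` steps by default.

**λ choice and the stability protocol.** `select_lambda_cv` scores a
30-point geometric grid under `lambda_max` by 5-fold CV of the lasso
solutions themselves. In `run_grid`, LARS-L1 cells default to
`l1_lambda = "cv_once"` and `selection_protocol = "once"`: the penalty *and
the wavelength set* are chosen a single time per cell and carried through
the 100 split repeats — mirroring the study's stability analysis, which ran
its 100 iterations under the optimal λ with the optimal selection
incorporated. Be aware of what this measures: selecting before splitting
lets the selection see every sample, so the selected-model Rp under this
protocol is optimistic relative to a strictly nested analysis, and the
dramatic full-spectrum → selected improvement it produces (about 0.93 →
0.99 mean Rp on the default world, as measured by the acceptance grid)
partly reflects that protocol — plausibly, so did the analogous jump in the
emulated study. The strictly leakage-free alternatives remain available:
`selection_protocol = "per_repeat"` in `run_repeats`/`run_grid`, and
`run_single`, where selection, λ and LV choices see calibration rows only
(verified by an ablation test that poisons the prediction responses and
checks the fitted model is bit-identical).

**Split bookkeeping.** `floor(0.7 n)` calibration samples (92 → 64/28);
repeat *i* uses seed `base_seed + i`; plain random splits without
stratification. Whether the source re-selected LVs inside each repeat is
unstated; we re-select per repeat (leakage-safe).

**Indices.** Selected channels are reported 1-based (R convention), always
alongside their wavelengths in nm.

## The synthetic world: what it emulates, and why it looks the way it does

No spectra were deposited with the source study, so all validation runs on a
simulator whose *defaults are the package's stated world*:

* SSC references are truncated-normal draws matching the published cohorts
  (Provence: 3.8–8.7 °Brix, mean 5.8, SD 1.1, n = 92, 17–31 points/scan;
  Jingcai No.8: 4.5–9.8, 7.4, 1.2, n = 96, 20–29).
* Each acquisition point is Beer–Lambert transmission:
  `gain · atten · source(λ) · exp(−path · A(λ))` plus noise, clipped at the
  detector cap, where `A` combines a flat bulk-flesh term (1.2), Gaussian
  SSC bands, and two interferent bands (650, 1020 nm) with random per-fruit
  concentrations. The first and last points are attenuated ("incomplete"),
  and occasional interior points are scaled into saturation.
* Orientations differ only through the optical path multiplier
  (O1 = 1.3 > O2 = 0.8), so O2 intensity dominates O1 channel-for-channel
  under matched randomness — as observed in the study.
* Scatter is one multiplicative gain per scan, drawn from (0.7, 1.4). A
  *per-point* gain spread would contradict the exact end-attenuation
  property the trimming tests rely on, and physically the scatter is a
  property of the fruit, not of the conveyor position.
* Noise has two parts per point: i.i.d. channel noise (SD 2000 counts) and
  a spectrally smooth drift (SD 300, ~80-channel correlation, realized as
  spline-interpolated coarse white noise).

Two default choices deserve justification because they were *design
decisions about which regime to emulate*, made once, up front:

* **The SSC bands are narrow** (SDs 3/4/3.5 nm at 730/840/960 nm) and
  **channel noise is heavy and independent**. In a world with broad smooth
  bands and smooth noise, a full-spectrum PLSR is provably near-optimal —
  off-band channels act as baseline references — and sparse wavelength
  selection *cannot* outperform it, contradicting the central qualitative
  finding this package must reproduce (selected-wavelength PLSR beating the
  full spectrum). Narrow informative features plus channel-independent
  noise is the regime in which sparsity genuinely pays, and it is also a
  fair cartoon of photon-starved full-transmission acquisition ("low SNR"
  in the source's own words).
* **The noiseless variant** (`noiseless_config()`) switches off every
  stochastic nuisance *including interferent concentrations*, leaving a
  deterministic Beer–Lambert response to SSC alone. In that limit the
  pipeline attains Rp = 1 to machine precision, which the tests assert at
  1e-6.

What the simulator does **not** model: optics (ray tracing, fruit geometry,
cavity structure), detector physics beyond hard clipping, conveyor timing,
maturity stages (the published 1:1:1 maturity mix appears only through the
SSC spread), or wavelength miscalibration. A green test on this world
establishes that the *algorithms* behave as specified — not that the
published accuracy figures are reproduced; those depend on undeposited data
and are explicitly out of scope.

The acceptance fixture for the qualitative-trend grid additionally makes the
noise orientation-dependent (O1: i.i.d. SD 3000, drift 600 — the harder
geometry; O2: the defaults), which is how the study describes O1 in
practice (longer, more complex optical path).

## Known limitations

* The λ values of the emulated study's tables are not comparable to ours
  (their scale is undefined); only qualitative λ-behavior is reproduced.
* `scan_lambda` flags empty selections instead of erroring so a grid
  containing `lambda_max` still yields a row per the interface contract; it
  warns when *every* λ comes back empty.
* The L2 selection rule is an interpretation (see above).
* Stochastic trend comparisons (SNV ≥ RAW, O2 ≥ O1, selected ≥ full) are
  paired across identical split schedules, which removes most split noise,
  but they remain properties of one simulated dataset per orientation at
  the acceptance seed, not theorems.
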