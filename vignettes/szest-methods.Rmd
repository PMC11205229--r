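---
title: "Methods: structurally enhanced Bayesian perimetry in szest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structurally enhanced Bayesian perimetry in szest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Standard automated perimetry estimates, at each of many visual field
locations, the stimulus attenuation (in dB) at which a light increment is
detected 50% of the time. The macula — the central 10 degrees — holds
almost half of all retinal ganglion cells and is tested with the dense
68-location 10-2 grid, but dense grids are slow. Macular OCT, routinely
collected in glaucoma care, measures the thickness of the ganglion cell
layer (GCL), a structural correlate of local sensitivity. `szest`
implements and evaluates, entirely in simulation, a Bayesian threshold
strategy (ZEST) and its structurally enhanced variant (S-ZEST) whose
prior beliefs are individualized from GCL thickness.

## The ZEST procedure

Each location carries a discrete probability distribution over candidate
thresholds 0–40 dB (1-dB bins by default; the range is what the
procedure prescribes, the 1-dB binning is our discretization choice,
matched to the 1-dB likelihood width and configurable via
`zest_domain()`). One adaptive step:

1. **Stimulus selection.** Present at the posterior mean, rounded to
   1 dB (round-half-even; device quantization is otherwise unspecified,
   so we chose the IEEE default) and clipped to [0, 40].
2. **Likelihood update.** The "seen" likelihood over candidate
   thresholds $t$ is the cdf of a Gaussian with 1-dB SD centered on the
   presented intensity $s$, with asymptotes:
   $L(t) = 0.03 + 0.94\,\Phi(t - s)$; "not seen" uses $1 - L$. The
   posterior is the renormalized product. The nonzero asymptotes encode
   false responses and guarantee no candidate is ever annihilated.
3. **Termination.** A location finishes when its posterior SD is
   ≤ 1.5 dB (boundary inclusive). A safety cap of 15 presentations per
   location guards against pathological response sequences; cap hits are
   flagged in the result and counted separately, because capped
   locations have *not* met the SD criterion.

Locations are scheduled uniformly at random among unterminated ones (the
procedure's source does not state an order; random scheduling avoids
systematic spatial drift and is fully seeded). Final estimates are
posterior means.

## Priors

**ZEST (standard).** A 4:1 mixture of a "normal" component peaked at the
location's normative sensitivity and an "abnormal" component peaked near
0 dB. The published population histograms behind these components are
not reproducible here, so both are discretized Gaussian bumps
(`normal_sd` 5 dB; abnormal peak 3 dB, SD 4 dB) behind the
`prior_config()` interface. A uniform floor (0.001 of total mass) is
added for numerical robustness; the 4:1 component ratio is exact before
flooring.

**S-ZEST (structural).** Identical construction, except (i) the normal
peak is moved to the sensitivity predicted from local GCL thickness and
(ii) the abnormal mixing fraction is no longer fixed at 0.2 but driven
by the predicted deficit.

## The structure–function model

The exact published model lives in an unavailable supplement, so the
package ships a documented stand-in behind `sf_params()`:

* **Prediction:** $S = \beta_0 + \beta_1 \log_{10}(T)$ clamped to
  [0, 40] dB, with $T$ the mean GCL thickness (µm) in a 2-degree square
  window centered on the *displaced* location. Linearity in
  $\log_{10}(T)$ mirrors how the structure–function correlation is
  analyzed in this literature. Defaults $\beta_0 = 0$,
  $\beta_1 = 20$ dB/log10(µm) are fixture values, overridable and
  fittable from data by `fit_sf_model()` (OLS; residual SD becomes
  `noise_sd`).
* **Mixing weight:** a logistic in the predicted deficit
  $d = \text{normative} - \text{predicted}$:
  $w(d) = 1/(1+e^{-(d - m)/s})$ with scale $s = 2$ dB and midpoint
  $m = s\ln 4 \approx 2.77$ dB, *calibrated so that zero deficit
  reproduces the standard 4:1 mixture* ($w(0) = 0.2$). The exact
  published rule is unknown; this calibration is the one constraint the
  design states, so it anchors the stand-in.

## Geometry

* The 10-2 pattern is generated as all odd-integer degree pairs with
  $x^2+y^2 \le 85$ — the standard 68 locations; the pattern source does
  not print coordinates, so this compact membership rule is documented
  as ours.
* The grid is centered on the fovea and rotated by the angle of the
  fovea–optic-disc axis. Rotation happens *before* ganglion-cell
  displacement (the order is unstated in the procedure's description;
  rotating first keeps displacement purely radial in the eye's own
  frame).
* Ganglion-cell displacement uses a pluggable radial curve
  (`drasdo_displacement()`): $d(r) = d_{max}(r/r_p)e^{1-r/r_p}$ with
  peak 2 degrees at 1.5 degrees eccentricity, identically zero beyond 17
  degrees. The published Drasdo parametrization is not printed in our
  sources; any alternative can be passed to `displace_locations()`.
* Neighbor graphs connect locations at nominal distance exactly
  2 degrees. Standard mode: weight 0.2, no edges across the horizontal
  midline. Structural mode: weight 0.4, edges cut where predicted
  sensitivities differ by more than 1 dB.

## Spatial enhancement

When a location is tested, each connected unterminated neighbor receives
a flattened likelihood $L_w = (1-w) + wL$. This convex flattening is our
chosen contract for the cited correlation strengths: it is the identity
at $w=0$, the full update at $w=1$, and never zeroes mass. Spatial
updates are not applied to already-terminated neighbors, which keeps
termination monotone (a finished location cannot be re-opened); the
source is silent on both points.

## Simulated observers

Responses are Bernoulli draws from
$p_{\text{seen}} = fp + (1 - fp - fn)\,\Phi\!\big((t - s)/\sigma(t)\big)$
with the Henson-type slope
$\sigma(t) = \min\!\big(6, e^{-0.081t + 3.27}\big)$ (canonical constants
as implemented in the OPI ecosystem; configurable). Presets: *reliable*
($fp = fn = 0.05$) and *unreliable* ($fp = fn = 0.20$) — the 20% figure
is applied to both rates simultaneously, matching how the reliability
conditions are described. Note the false-response rates enter the
*observer*; the strategy's likelihood asymptotes (0.03/0.97) are fixed
independently.

## The synthetic world

No patient data ship with the package; every input is generated, and the
generator's defaults are the stated world the tests exercise.

* **Normative map:** linear hill of vision, 31 dB foveal, −0.35 dB/deg.
  The mean eccentricity of the 10-2 grid is ≈ 6.2 degrees, so the grand
  mean is ≈ 28.8 dB, matching the healthy cohort mean (~28.9 dB) the
  simulations emulate.
* **Healthy eyes:** normative + between-eye offset $N(0, 1.5)$ dB (the
  emulated healthy cohort SD) + per-location noise $N(0, 1)$ dB, clipped
  to [0, 40].
* **Glaucomatous eyes:** a smooth defect field is subtracted. The field
  respects the horizontal raphe: one randomly signed hemifield carries a
  smooth loss (baseline plus a Gaussian bump of SD 4 degrees at a random
  within-hemifield center), scaled so its hemifield mean equals a depth
  drawn around the severity target — early ≈ 5, moderate ≈ 12,
  advanced ≈ 22 dB. Advanced eyes additionally damage the fellow
  hemifield at 0.85 of the drawn depth: a single-hemifield defect cannot
  produce the whole-eye mean loss (~14 dB under the 5/8/19 severity mix)
  that advanced-heavy glaucoma cohorts show, and diffuse bilateral-
  hemifield loss is the clinical picture of advanced disease. These
  depths were calibrated once against the emulated cohort means and are
  documented as calibration, not ground truth.
* **GCL maps:** 0.25 deg/pixel over ±15 degrees. Each pixel's retinal
  position is pulled *back* through the displacement model to its visual
  field position; the eye's sensitivity surface there is inverted
  through the structure–function model and 10% multiplicative lognormal
  noise is applied. Structure and function are therefore consistent by
  construction, and `sample_gcl()` + `predict_sensitivity()` recovers
  the true thresholds with RMSE below the model's `noise_sd` — this
  consistency loop is a tested invariant.
* Synthetic eyes use an ONH on the horizontal meridian (identity
  rotation), keeping the defect's raphe aligned with both the anatomy
  and the grid midline.

**What a green test does not establish.** The generator produces smooth,
hemifield-respecting defects with perfectly co-located structural
thinning, no media opacity, no fixation loss, no learning or fatigue,
and a structure–function model that is *exactly* the one the strategy
assumes. Green simulation tests therefore establish internal correctness
and the direction of strategy effects (S-ZEST faster in glaucoma;
spatially enhanced S-ZEST faster in healthy eyes), not clinical
performance; human test–retest quantities are out of scope by design.

## Fovea detection

Zero-normalized cross-correlation (Pearson correlation of pixel
windows — "normalized" is otherwise ambiguous) between a thickness map
and a pit template, restricted to a 12.5 x 12.5 degree search region
(half-width 6.25). Ties are broken toward the search center, then
row-major. The clinical template (an average of 30 healthy scans) cannot
be reproduced; `synthetic_pit_map()` builds labelled synthetic stand-ins
(radial Gaussian pit, depth 40 µm, SD 1 degree) for templates and test
maps. Flat windows raise an error rather than returning an arbitrary
score. The affine OCT-to-fundus transform is accepted as input
(`affine_transform()`, `apply_affine()`); estimating it is image
registration, which is delegated externally and out of scope.

## Analysis choices

* **MAE** summarizes per-test accuracy; presentation counts summarize
  speed, with a fixed 1.6 s/presentation constant available for a
  *modeled* duration only — no wall-clock claim.
* **Quantiles** are type-7 (linear interpolation), stated because the
  summary convention is otherwise undefined.
* **Bland–Altman**: bias ± 1.96 SD of paired differences (1.96, not a
  small-sample multiplier — documented choice), a least-squares bias
  equation against the pairwise mean, and percentile bootstrap CIs
  resampling *subjects* (default 1000 resamples; the count is
  unspecified in the source design).
* Group comparisons via mixed models are intentionally not provided;
  cluster-aware summaries (per-subject means, paired differences) are
  the supported route.

## Numerical notes and edge cases

* All pdfs renormalize after every update; with asymptotes inside
  (0, 1), mass can never collapse to zero (tested after 50 repeated
  extreme updates).
* `discrete_pdf()` enforces uniform domain spacing and nonnegative
  mass; moment functions reject unnormalized input beyond 1e-6.
* A coincident fovea and ONH center is a degenerate axis and errors.
* Thickness sampling errors name the offending location when a window
  leaves the raster.
* Priors whose SD already meets the termination bound terminate with
  zero presentations — a legitimate (if extreme) configuration.

## Known limitations

* The structure–function model, prior component shapes, displacement
  curve and mixing rule are documented stand-ins for unavailable
  published internals; all are pluggable.
* Simulated observers have independent trials: no response-time model,
  correlated lapses, or fatigue.
* One grid (10-2) is built in; other patterns can be loaded from text
  via `read_grid()` but have no normative model.
* Raster image import is limited to plain-text PGM (P2); binary formats
  are intentionally unsupported in this text-only distribution.
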